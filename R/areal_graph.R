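#' Build an areal contiguity graph
#'
#' Constructs the neighbourhood contiguity structure used by all intrinsic
#' conditional autoregressive (ICAR) computations: a symmetric 0--1
#' contiguity relation over a fixed, ordered set of areas.  The order of
#' `area_ids` is canonical: it is the vector index used by every downstream
#' field, table and sampler.
#'
#' @param area_ids Character vector of unique area identifiers, in canonical
#'   order.
#' @param edges A two-column matrix or data frame of area-id pairs (one
#'   unordered neighbour pair per row), or a list of length-2 vectors.
#'   Duplicate and reversed pairs are collapsed; self-loops are an error.
#'
#' @return An object of class `areal_graph` with components:
#'   \describe{
#'     \item{area_ids}{the canonical id order;}
#'     \item{edges}{an `|E| x 2` integer matrix of area indices with
#'       `edges[,1] < edges[,2]`, rows sorted lexicographically;}
#'     \item{n}{number of areas;}
#'     \item{m}{integer vector of neighbour counts per area;}
#'     \item{component}{integer component label per area;}
#'     \item{n_components}{number of connected components (isolated areas
#'       count as their own component).}
#'   }
#'   Areas with `m = 0` (islands) are permitted but flagged with a warning:
#'   their spatial effects are pinned to zero downstream and they contribute
#'   only through the unstructured terms.
#' @export
areal_graph <- function(area_ids, edges) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area id: ", area_ids[duplicated(area_ids)][1])
  }
  n <- length(area_ids)
  if (n < 1) stop("at least one area is required")

  em <- .as_edge_matrix(edges)
  idx1 <- match(em[, 1], area_ids)
  idx2 <- match(em[, 2], area_ids)
  bad <- c(em[, 1][is.na(idx1)], em[, 2][is.na(idx2)])
  if (length(bad)) stop("edge references unknown area id: ", bad[1])
  if (any(idx1 == idx2)) {
    stop("self-loop on area: ", em[idx1 == idx2, 1][1])
  }
  e <- cbind(pmin(idx1, idx2), pmax(idx1, idx2))
  e <- unique(e)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]

  m <- tabulate(c(e[, 1], e[, 2]), nbins = n)
  comp <- .connected_components(n, e)

  g <- structure(
    list(area_ids = area_ids,
         edges = e,
         n = n,
         m = as.integer(m),
         component = as.integer(comp),
         n_components = max(comp)),
    class = "areal_graph")
  if (any(m == 0L)) {
    warning("island area(s) with no neighbours: ",
            paste(area_ids[m == 0L], collapse = ", "),
            "; their spatial effects are pinned to 0")
  }
  g
}

.as_edge_matrix <- function(edges) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (is.list(edges) && !is.matrix(edges)) {
    edges <- do.call(rbind, lapply(edges, function(p) {
      if (length(p) != 2) stop("each edge must have exactly two endpoints")
      as.character(p)
    }))
  }
  if (is.null(edges) || length(edges) == 0) {
    return(matrix(character(0), ncol = 2))
  }
  if (!is.matrix(edges) || ncol(edges) != 2) {
    stop("edges must be a two-column matrix, data frame, or list of pairs")
  }
  mode(edges) <- "character"
  edges
}

#' @export
print.areal_graph <- function(x, ...) {
  cat("areal_graph:", x$n, "areas,", nrow(x$edges), "edges,",
      x$n_components, "component(s)\n")
  invisible(x)
}

#' Regular lattice contiguity graph
#'
#' A `rows x cols` lattice with rook (orthogonal) or queen (orthogonal plus
#' diagonal) contiguity, used as a stand-in for an urban neighbourhood
#' lattice in simulation studies.  Area ids are `"r<i>c<j>"` in row-major
#' order.
#'
#' @param rows,cols Positive integers; `rows * cols >= 2`.
#' @param contiguity `"rook"` or `"queen"`.
#' @return An [areal_graph].
#' @export
grid_graph <- function(rows, cols, contiguity = c("queen", "rook")) {
  contiguity <- match.arg(contiguity)
  if (rows < 1 || cols < 1) stop("rows and cols must be positive")
  if (rows * cols < 2) stop("need at least two areas")
  ids <- as.vector(t(outer(seq_len(rows), seq_len(cols),
                           function(r, c) paste0("r", r, "c", c))))
  at <- function(r, c) (r - 1L) * cols + c
  from <- integer(0); to <- integer(0)
  for (r in seq_len(rows)) for (c in seq_len(cols)) {
    if (c < cols) { from <- c(from, at(r, c)); to <- c(to, at(r, c + 1L)) }
    if (r < rows) { from <- c(from, at(r, c)); to <- c(to, at(r + 1L, c)) }
    if (contiguity == "queen") {
      if (r < rows && c < cols) {
        from <- c(from, at(r, c)); to <- c(to, at(r + 1L, c + 1L))
      }
      if (r < rows && c > 1L) {
        from <- c(from, at(r, c)); to <- c(to, at(r + 1L, c - 1L))
      }
    }
  }
  areal_graph(ids, cbind(ids[from], ids[to]))
}

#' Sparse contiguity matrix of a graph
#'
#' @param graph An [areal_graph].
#' @return A symmetric sparse 0--1 `Matrix` `W` with zero diagonal.
#' @export
adjacency_matrix <- function(graph) {
  e <- graph$edges
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(graph$n, graph$n),
                       dimnames = list(graph$area_ids, graph$area_ids))
}

#' Graph Laplacian of a contiguity graph
#'
#' `diag(m) - W`; the ICAR prior on a field `x` is proportional to
#' `exp(-tau/2 * t(x) %*% L %*% x)` with rank `n - n_components`.
#'
#' @param graph An [areal_graph].
#' @param dense Return a base dense matrix rather than a sparse `Matrix`.
#' @return The Laplacian matrix.
#' @export
graph_laplacian <- function(graph, dense = FALSE) {
  L <- Matrix::Diagonal(x = as.numeric(graph$m)) - adjacency_matrix(graph)
  if (dense) as.matrix(L) else L
}

# Union-find connected components; labels numbered 1..k in order of first
# appearance so the labelling is deterministic.
.connected_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges[k, 1]); rj <- find(edges[k, 2])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(match(roots, unique(roots)))
}

# Deterministic greedy colouring (vertices in index order, smallest free
# colour): within a colour class no two areas are neighbours, so
# single-site Metropolis updates of a class are mutually independent and
# can be vectorized.  List of index vectors per colour.
.graph_colour_classes <- function(graph) {
  nb <- .neighbour_list(graph)
  col <- integer(graph$n)
  for (i in seq_len(graph$n)) {
    used <- col[nb[[i]]]
    k <- 1L
    while (k %in% used) k <- k + 1L
    col[i] <- k
  }
  split(seq_len(graph$n), col)
}

.neighbour_list <- function(graph) {
  nb <- vector("list", graph$n)
  for (i in seq_len(graph$n)) nb[[i]] <- integer(0)
  e <- graph$edges
  for (k in seq_len(nrow(e))) {
    nb[[e[k, 1]]] <- c(nb[[e[k, 1]]], e[k, 2])
    nb[[e[k, 2]]] <- c(nb[[e[k, 2]]], e[k, 1])
  }
  nb
}

#' Read an areal adjacency file
#'
#' Three text dialects are supported:
#' \describe{
#'   \item{`gal`}{legacy spatial-weights format: a header line with the
#'     number of areas, then per area a line `id m` followed by a line of
#'     `m` neighbour ids;}
#'   \item{`edge_list`}{one `id1 id2` pair per line, with an optional
#'     leading comment `# areas: id1 id2 ...` fixing the id order and
#'     carrying isolated areas;}
#'   \item{`winbugs_adj`}{BUGS-style adjacency vectors `num = c(...)` and
#'     `adj = c(...)` (optionally `sumNumNeigh`), areas indexed 1..n, with
#'     an optional `# areas:` comment carrying identifiers.}
#' }
#' Equivalent content yields an identical graph regardless of dialect.
#' GAL and BUGS dialects list each area's neighbours explicitly; an
#' asymmetric listing is rejected naming both areas involved.
#'
#' @param path File path.
#' @param dialect One of `"gal"`, `"edge_list"`, `"winbugs_adj"`.
#' @return An [areal_graph].
#' @export
read_adjacency <- function(path, dialect = c("gal", "edge_list", "winbugs_adj")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  switch(dialect,
         gal = .parse_gal(lines),
         edge_list = .parse_edge_list(lines),
         winbugs_adj = .parse_winbugs_adj(lines))
}

.check_symmetry <- function(area_ids, nbrs) {
  n <- length(area_ids)
  for (i in seq_len(n)) {
    for (j in nbrs[[i]]) {
      if (!(i %in% nbrs[[j]])) {
        stop("asymmetric neighbour listing: ", area_ids[i],
             " lists ", area_ids[j], " but not vice versa")
      }
    }
  }
  invisible(NULL)
}

.nbrs_to_graph <- function(area_ids, nbrs) {
  .check_symmetry(area_ids, nbrs)
  from <- rep(seq_along(nbrs), lengths(nbrs))
  to <- unlist(nbrs)
  keep <- from < to
  areal_graph(area_ids, cbind(area_ids[from[keep]], area_ids[to[keep]]))
}

.parse_gal <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  # plain "n" header, or the 4-field "0 n shapefile id" variant
  n <- as.integer(if (length(hdr) >= 2 && hdr[1] == "0") hdr[2] else hdr[1])
  if (is.na(n) || n < 1) stop("malformed GAL header")
  ids <- character(n); nbrs <- vector("list", n)
  pos <- 2L
  for (k in seq_len(n)) {
    rec <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
    if (length(rec) != 2) stop("malformed GAL record line: ", lines[pos])
    ids[k] <- rec[1]
    mk <- as.integer(rec[2])
    pos <- pos + 1L
    if (mk > 0) {
      nb <- strsplit(trimws(lines[pos]), "\\s+")[[1]]
      if (length(nb) != mk) {
        stop("GAL area ", ids[k], " declares ", mk, " neighbours, found ",
             length(nb))
      }
      nbrs[[k]] <- nb
      pos <- pos + 1L
    } else {
      nbrs[[k]] <- character(0)
    }
  }
  idx <- lapply(nbrs, function(nb) {
    j <- match(nb, ids)
    if (anyNA(j)) stop("GAL neighbour id not declared: ", nb[is.na(j)][1])
    j
  })
  .nbrs_to_graph(ids, idx)
}

.parse_edge_list <- function(lines) {
  area_line <- grep("^#\\s*areas:", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  pairs <- do.call(rbind, lapply(body, function(l) {
    p <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(p) != 2) stop("malformed edge-list line: ", l)
    p
  }))
  ids <- if (length(area_line)) {
    strsplit(trimws(sub("^#\\s*areas:", "", area_line[1])), "\\s+")[[1]]
  } else {
    unique(as.vector(t(pairs)))
  }
  areal_graph(ids, if (is.null(pairs)) matrix(character(0), ncol = 2) else pairs)
}

.extract_bugs_vector <- function(text, name) {
  m <- regmatches(text, regexpr(paste0(name, "\\s*=\\s*c\\(([^)]*)\\)"), text))
  if (!length(m)) return(NULL)
  inner <- sub(paste0(name, "\\s*=\\s*c\\("), "", m)
  inner <- sub("\\)$", "", inner)
  as.numeric(strsplit(inner, "[,\\s]+")[[1]][nzchar(strsplit(inner, "[,\\s]+")[[1]])])
}

.parse_winbugs_adj <- function(lines) {
  area_line <- grep("^#\\s*areas:", lines, value = TRUE)
  text <- paste(lines[!grepl("^#", lines)], collapse = " ")
  num <- .extract_bugs_vector(text, "num")
  adj <- .extract_bugs_vector(text, "adj")
  if (is.null(num) || (is.null(adj) && sum(num) > 0)) {
    stop("winbugs_adj file must define num = c(...) and adj = c(...)")
  }
  if (is.null(adj)) adj <- numeric(0)
  if (sum(num) != length(adj)) {
    stop("winbugs_adj: sum(num) = ", sum(num), " but length(adj) = ",
         length(adj))
  }
  n <- length(num)
  ids <- if (length(area_line)) {
    strsplit(trimws(sub("^#\\s*areas:", "", area_line[1])), "\\s+")[[1]]
  } else {
    as.character(seq_len(n))
  }
  if (length(ids) != n) stop("winbugs_adj: ", n, " areas but ",
                             length(ids), " ids in '# areas:' comment")
  ends <- cumsum(num)
  starts <- ends - num + 1
  nbrs <- lapply(seq_len(n), function(i) {
    if (num[i] == 0) integer(0) else as.integer(adj[starts[i]:ends[i]])
  })
  .nbrs_to_graph(ids, nbrs)
}

#' Write an areal adjacency file
#'
#' Emits a canonical text representation in any dialect [read_adjacency]
#' reads; `read_adjacency(write_adjacency(g, ...))` reproduces `g` exactly,
#' and re-writing the result is byte-identical.
#'
#' @param graph An [areal_graph].
#' @param path Output file path.
#' @param dialect One of `"gal"`, `"edge_list"`, `"winbugs_adj"`.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(graph, path,
                            dialect = c("gal", "edge_list", "winbugs_adj")) {
  dialect <- match.arg(dialect)
  nb <- .neighbour_list(graph)
  nb <- lapply(nb, sort)
  lines <- switch(dialect,
    gal = {
      out <- as.character(graph$n)
      for (i in seq_len(graph$n)) {
        out <- c(out, paste(graph$area_ids[i], graph$m[i]))
        if (graph$m[i] > 0) {
          out <- c(out, paste(graph$area_ids[nb[[i]]], collapse = " "))
        }
      }
      out
    },
    edge_list = {
      out <- paste("# areas:", paste(graph$area_ids, collapse = " "))
      e <- graph$edges
      c(out, if (nrow(e)) paste(graph$area_ids[e[, 1]], graph$area_ids[e[, 2]]))
    },
    winbugs_adj = {
      c(paste("# areas:", paste(graph$area_ids, collapse = " ")),
        paste0("num = c(", paste(graph$m, collapse = ", "), ")"),
        paste0("adj = c(", paste(unlist(nb), collapse = ", "), ")"),
        paste0("sumNumNeigh = ", sum(graph$m)))
    })
  writeLines(lines, path)
  invisible(path)
}
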