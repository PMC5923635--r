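#' Per-area outcome table
#'
#' Holds the observed counts of the two outcomes (e.g. doctor visits and
#' hospital admissions) and the at-risk population per area, in the same
#' canonical order as the contiguity graph.  The two outcomes may cover
#' different observation spans (`period_years`); [annualize_counts] converts
#' both to annual averages before standardization.
#'
#' @param area_ids Character vector of area identifiers.
#' @param O1,O2 Non-negative per-area event counts for outcomes 1 and 2.
#' @param N Positive per-area at-risk populations.
#' @param period_years Length-2 positive numeric: observation span in years
#'   for each outcome.
#' @return An object of class `outcome_table`: a data frame with columns
#'   `area_id`, `O1`, `O2`, `N` and attribute `period_years`.
#' @export
outcome_table <- function(area_ids, O1, O2, N, period_years = c(1, 1)) {
  area_ids <- as.character(area_ids)
  n <- length(area_ids)
  stopifnot(length(O1) == n, length(O2) == n, length(N) == n,
            length(period_years) == 2)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area id: ", area_ids[duplicated(area_ids)][1])
  }
  if (any(O1 < 0) || any(O2 < 0)) {
    stop("negative count in area: ",
         area_ids[which(O1 < 0 | O2 < 0)[1]])
  }
  if (any(N <= 0)) {
    stop("non-positive population in area: ", area_ids[which(N <= 0)[1]])
  }
  if (any(period_years <= 0)) stop("period_years must be positive")
  structure(
    data.frame(area_id = area_ids, O1 = as.numeric(O1), O2 = as.numeric(O2),
               N = as.numeric(N), stringsAsFactors = FALSE),
    period_years = as.numeric(period_years),
    class = c("outcome_table", "data.frame"))
}

#' Observation spans of an outcome table
#' @param table An [outcome_table].
#' @return Length-2 numeric vector of years per outcome.
#' @export
period_years <- function(table) attr(table, "period_years")

#' Read a per-area counts table
#'
#' Expects a CSV with header columns `area_id`, `O1`, `O2`, `N` (extra
#' columns are ignored).  When a graph is supplied the rows are reordered to
#' the graph's canonical area order and every graph area must be present.
#'
#' @param path CSV file path.
#' @param graph Optional [areal_graph] giving the canonical area order.
#' @param period_years Observation span in years per outcome (length 2).
#' @return An [outcome_table].
#' @export
read_counts <- function(path, graph = NULL, period_years = c(1, 1)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("area_id", "O1", "O2", "N")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("counts file lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$area_id <- as.character(df$area_id)
  if (anyDuplicated(df$area_id)) {
    stop("duplicate area_id in row ",
         which(duplicated(df$area_id))[1], ": ",
         df$area_id[duplicated(df$area_id)][1])
  }
  bad <- which(df$O1 < 0 | df$O2 < 0)
  if (length(bad)) stop("negative count in row ", bad[1])
  bad <- which(df$N <= 0)
  if (length(bad)) stop("non-positive population in row ", bad[1])
  if (!is.null(graph)) {
    idx <- match(graph$area_ids, df$area_id)
    if (anyNA(idx)) {
      stop("counts file missing graph area(s): ",
           paste(graph$area_ids[is.na(idx)], collapse = ", "))
    }
    extra <- setdiff(df$area_id, graph$area_ids)
    if (length(extra)) {
      stop("counts file has area(s) not in graph: ",
           paste(extra, collapse = ", "))
    }
    df <- df[idx, , drop = FALSE]
  }
  outcome_table(df$area_id, df$O1, df$O2, df$N, period_years)
}

#' Write a per-area counts table (optionally with derived columns)
#'
#' @param table An [outcome_table].
#' @param path Output CSV path.
#' @param expected Optional [compute_expected] result; adds `e1`, `e2`,
#'   `spr1`, `spr2` columns.
#' @return `path`, invisibly.
#' @export
write_counts <- function(table, path, expected = NULL) {
  df <- as.data.frame(table)
  if (!is.null(expected)) {
    spr <- standardized_prevalence_ratio(table, expected)
    df$e1 <- expected$e[, 1]; df$e2 <- expected$e[, 2]
    df$spr1 <- spr[, 1]; df$spr2 <- spr[, 2]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert multi-year counts to annual averages
#'
#' Divides each outcome's counts by its observation span in years (e.g. a
#' two-year count is halved) and sets both spans to 1.  Halved counts are
#' retained unrounded; the Poisson log-density downstream uses the
#' log-gamma function so non-integral counts are handled continuously.
#' Idempotent once both spans are 1.
#'
#' @param table An [outcome_table].
#' @return An annualized [outcome_table].
#' @export
annualize_counts <- function(table) {
  py <- period_years(table)
  if (any(py <= 0)) stop("period_years must be positive")
  outcome_table(table$area_id, table$O1 / py[1], table$O2 / py[2],
                table$N, c(1, 1))
}

#' Expected counts by internal standardization
#'
#' The expected count of each outcome in each area is the overall (whole
#' region) rate of that outcome multiplied by the area's population:
#' `e[i,k] = (sum(O[,k]) / sum(N)) * N[i]`.  By construction the expected
#' counts sum to the observed counts per outcome.
#'
#' @param table An annualized [outcome_table].
#' @return An object of class `expected_counts`: list with matrix `e`
#'   (`n x 2`) and the overall `rates` (length 2).
#' @export
compute_expected <- function(table) {
  O <- cbind(table$O1, table$O2)
  tot <- colSums(O)
  if (any(tot <= 0)) {
    stop("all-zero counts for outcome ", which(tot <= 0)[1],
         ": overall rate undefined")
  }
  rates <- tot / sum(table$N)
  e <- outer(table$N, rates)
  dimnames(e) <- list(table$area_id, c("e1", "e2"))
  structure(list(e = e, rates = rates), class = "expected_counts")
}

#' Standardized prevalence ratios
#'
#' Observed over expected counts per area and outcome -- the raw map
#' analogue of the model's relative risk.  Under internal standardization
#' the expected-count-weighted mean ratio is exactly 1 per outcome.
#'
#' @param table An [outcome_table].
#' @param expected Matching [compute_expected] result.
#' @return An `n x 2` matrix of ratios (columns `spr1`, `spr2`).
#' @export
standardized_prevalence_ratio <- function(table, expected) {
  e <- expected$e
  if (nrow(e) != nrow(table)) stop("dimension mismatch: table vs expected")
  if (any(e <= 0)) {
    stop("zero expected count for area ",
         table$area_id[which(rowSums(e <= 0) > 0)[1]])
  }
  r <- cbind(table$O1, table$O2) / e
  dimnames(r) <- list(table$area_id, c("spr1", "spr2"))
  r
}
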