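#include <Rcpp.h>
using namespace Rcpp;

// Single-site random-walk Metropolis sweep over one latent field.
//
// field codes: 0 = theta (shared, enters both outcomes via delta and
// 1/delta), 1 = s1, 2 = s2 (outcome-specific ICAR surfaces), 3 = u1,
// 4 = u2 (unstructured).  Spatial fields are updated colour class by
// colour class (within a class no two areas are adjacent, so the
// element-wise accept/reject equals sequential single-site updating);
// unstructured fields in one pass.  The Poisson means lam1/lam2 are
// maintained incrementally.  Draw order (a block of normals, then a
// block of uniforms per class) matches the package's documented sweep
// so runs are reproducible from the R seed alone.
//
// [[Rcpp::export]]
List cpp_field_sweep(NumericVector x_in, int field, double tau,
                     double delta, double scale, bool use_lik,
                     NumericVector lam1_in, NumericVector lam2_in,
                     NumericVector O1, NumericVector O2,
                     IntegerVector m, IntegerVector nbr_ptr,
                     IntegerVector nbr_idx, List colours,
                     LogicalVector island) {
  NumericVector x = clone(x_in);
  NumericVector lam1 = clone(lam1_in);
  NumericVector lam2 = clone(lam2_in);
  int n = x.size();
  LogicalVector accept(n, NA_LOGICAL);

  if (field >= 3) {  // unstructured: all sites conditionally independent
    std::vector<double> dx(n);
    for (int i = 0; i < n; ++i) dx[i] = R::rnorm(0.0, scale);
    std::vector<double> lr(n);
    for (int i = 0; i < n; ++i) {
      double xo = x[i], xp = xo + dx[i];
      double dpr = -tau / 2.0 * (xp * xp - xo * xo);
      double dll = 0.0;
      if (use_lik) {
        if (field == 3) dll = O1[i] * dx[i] - lam1[i] * expm1(dx[i]);
        else            dll = O2[i] * dx[i] - lam2[i] * expm1(dx[i]);
      }
      lr[i] = dpr + dll;
    }
    for (int i = 0; i < n; ++i) {
      bool acc = log(R::runif(0.0, 1.0)) < lr[i];
      accept[i] = acc;
      if (acc) {
        x[i] += dx[i];
        if (field == 3) lam1[i] *= exp(dx[i]);
        else            lam2[i] *= exp(dx[i]);
      }
    }
    return List::create(_["x"] = x, _["lam1"] = lam1, _["lam2"] = lam2,
                        _["accept"] = accept);
  }

  int ncol = colours.size();
  for (int c = 0; c < ncol; ++c) {
    IntegerVector idx = colours[c];  // 1-based area indices
    int len = idx.size();
    std::vector<double> dx(len), lr(len);
    for (int j = 0; j < len; ++j) dx[j] = R::rnorm(0.0, scale);
    for (int j = 0; j < len; ++j) {
      int i = idx[j] - 1;
      double Wx = 0.0;
      for (int p = nbr_ptr[i]; p < nbr_ptr[i + 1]; ++p) Wx += x[nbr_idx[p]];
      double xo = x[i], xp = xo + dx[j];
      double dpr = -tau / 2.0 *
        (m[i] * (xp * xp - xo * xo) - 2.0 * (xp - xo) * Wx);
      double dll = 0.0;
      if (use_lik) {
        if (field == 0) {
          double d1 = delta * dx[j], d2 = dx[j] / delta;
          dll = O1[i] * d1 - lam1[i] * expm1(d1) +
                O2[i] * d2 - lam2[i] * expm1(d2);
        } else if (field == 1) {
          dll = O1[i] * dx[j] - lam1[i] * expm1(dx[j]);
        } else {
          dll = O2[i] * dx[j] - lam2[i] * expm1(dx[j]);
        }
      }
      lr[j] = dpr + dll;
    }
    for (int j = 0; j < len; ++j) {
      int i = idx[j] - 1;
      bool acc = log(R::runif(0.0, 1.0)) < lr[j];
      accept[i] = acc;
      if (acc) {
        x[i] += dx[j];
        if (field == 0) {
          lam1[i] *= exp(delta * dx[j]);
          lam2[i] *= exp(dx[j] / delta);
        } else if (field == 1) {
          lam1[i] *= exp(dx[j]);
        } else {
          lam2[i] *= exp(dx[j]);
        }
      }
    }
  }
  return List::create(_["x"] = x, _["lam1"] = lam1, _["lam2"] = lam2,
                      _["accept"] = accept);
}
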