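#include <Rcpp.h>
using namespace Rcpp;

// Full Metropolis-within-Gibbs iteration for the shared-component model.
//
// Layout of the proposal-scale / acceptance-count vectors (fixed order):
//   0 theta   1 s1   2 s2   3 u1   4 u2            (single-site field RW)
//   5 alpha1  6 alpha2  7 log_delta                (scalar RW)
//   8 shared_scale  9 theta_scale  10 shared_transfer
//   11 transfer_s1  12 transfer_s2  13 mix_s1  14 mix_s2
//   15 s1_scale  16 s2_scale  17 u1_scale  18 u2_scale
//
// One iteration = `field_sweeps` scans of (all five fields + scalars),
// then `substeps` repetitions of the hyperparameter block (conjugate
// precision draws + the joint scale/transfer/mixing kernels).  The
// recentering projection stays on the R side (no RNG involved).

struct State {
  NumericVector th, s1, s2, u1, u2, lam1, lam2, tau;
  double a1, a2, ld, delta;
};

static inline double pair_quad(const NumericVector& x,
                               const IntegerVector& ei,
                               const IntegerVector& ej) {
  double q = 0.0;
  for (int k = 0; k < ei.size(); ++k) {
    double d = x[ei[k]] - x[ej[k]];
    q += d * d;
  }
  return q;
}

static inline double pair_bilin(const NumericVector& x,
                                const NumericVector& y,
                                const IntegerVector& ei,
                                const IntegerVector& ej) {
  double q = 0.0;
  for (int k = 0; k < ei.size(); ++k) {
    q += (x[ei[k]] - x[ej[k]]) * (y[ei[k]] - y[ej[k]]);
  }
  return q;
}

static void field_sweep(State& S, int field, double scale, bool use_lik,
                        const NumericVector& O1, const NumericVector& O2,
                        const IntegerVector& m, const IntegerVector& nbr_ptr,
                        const IntegerVector& nbr_idx, const List& colours,
                        double* acc, double* att) {
  NumericVector x = (field == 0) ? S.th : (field == 1) ? S.s1 :
                    (field == 2) ? S.s2 : (field == 3) ? S.u1 : S.u2;
  double tau = S.tau[field];
  int n = x.size();
  if (field >= 3) {
    std::vector<double> dx(n), lr(n);
    for (int i = 0; i < n; ++i) dx[i] = R::rnorm(0.0, scale);
    for (int i = 0; i < n; ++i) {
      double xo = x[i], xp = xo + dx[i];
      double dpr = -tau / 2.0 * (xp * xp - xo * xo);
      double dll = 0.0;
      if (use_lik) {
        if (field == 3) dll = O1[i] * dx[i] - S.lam1[i] * expm1(dx[i]);
        else            dll = O2[i] * dx[i] - S.lam2[i] * expm1(dx[i]);
      }
      lr[i] = dpr + dll;
    }
    for (int i = 0; i < n; ++i) {
      att[field] += 1.0;
      if (log(R::runif(0.0, 1.0)) < lr[i]) {
        acc[field] += 1.0;
        x[i] += dx[i];
        if (field == 3) S.lam1[i] *= exp(dx[i]);
        else            S.lam2[i] *= exp(dx[i]);
      }
    }
    return;
  }
  for (int c = 0; c < colours.size(); ++c) {
    IntegerVector idx = colours[c];
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
          double d1 = S.delta * dx[j], d2 = dx[j] / S.delta;
          dll = O1[i] * d1 - S.lam1[i] * expm1(d1) +
                O2[i] * d2 - S.lam2[i] * expm1(d2);
        } else if (field == 1) {
          dll = O1[i] * dx[j] - S.lam1[i] * expm1(dx[j]);
        } else {
          dll = O2[i] * dx[j] - S.lam2[i] * expm1(dx[j]);
        }
      }
      lr[j] = dpr + dll;
    }
    for (int j = 0; j < len; ++j) {
      int i = idx[j] - 1;
      att[field] += 1.0;
      if (log(R::runif(0.0, 1.0)) < lr[j]) {
        acc[field] += 1.0;
        x[i] += dx[j];
        if (field == 0) {
          S.lam1[i] *= exp(S.delta * dx[j]);
          S.lam2[i] *= exp(dx[j] / S.delta);
        } else if (field == 1) {
          S.lam1[i] *= exp(dx[j]);
        } else {
          S.lam2[i] *= exp(dx[j]);
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_scsm_iterate(NumericVector th, NumericVector s1, NumericVector s2,
                      NumericVector u1, NumericVector u2,
                      double a1, double a2, double ld,
                      NumericVector tau, NumericVector lam1,
                      NumericVector lam2, NumericVector O1,
                      NumericVector O2, IntegerVector m,
                      IntegerVector nbr_ptr, IntegerVector nbr_idx,
                      List colours, IntegerVector edge_i,
                      IntegerVector edge_j, LogicalVector island,
                      bool use_lik, bool shared, int field_sweeps,
                      int substeps, NumericVector scales,
                      double alpha_sd, double ld_mean, double ld_prec,
                      NumericMatrix hyper, int rank, int n_free) {
  State S{clone(th), clone(s1), clone(s2), clone(u1), clone(u2),
          clone(lam1), clone(lam2), clone(tau), a1, a2, ld, exp(ld)};
  int n = th.size();
  double sumO1 = 0.0, sumO2 = 0.0;
  for (int i = 0; i < n; ++i) { sumO1 += O1[i]; sumO2 += O2[i]; }
  NumericVector accv(19), attv(19);
  double* acc = accv.begin();
  double* att = attv.begin();

  for (int scan = 0; scan < std::max(1, field_sweeps); ++scan) {
    // latent fields
    for (int f = 0; f < 5; ++f) {
      if (f == 0 && !shared) continue;
      field_sweep(S, f, scales[f], use_lik, O1, O2, m, nbr_ptr, nbr_idx,
                  colours, acc, att);
    }
    // alpha1
    {
      double da = R::rnorm(0.0, scales[5]);
      double dpr = -((S.a1 + da) * (S.a1 + da) - S.a1 * S.a1) /
        (2.0 * alpha_sd * alpha_sd);
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += S.lam1[i];
      double dll = use_lik ? sumO1 * da - s * expm1(da) : 0.0;
      att[5] += 1.0;
      if (log(R::runif(0.0, 1.0)) < dpr + dll) {
        acc[5] += 1.0;
        S.a1 += da;
        for (int i = 0; i < n; ++i) S.lam1[i] *= exp(da);
      }
    }
    // alpha2
    {
      double da = R::rnorm(0.0, scales[6]);
      double dpr = -((S.a2 + da) * (S.a2 + da) - S.a2 * S.a2) /
        (2.0 * alpha_sd * alpha_sd);
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += S.lam2[i];
      double dll = use_lik ? sumO2 * da - s * expm1(da) : 0.0;
      att[6] += 1.0;
      if (log(R::runif(0.0, 1.0)) < dpr + dll) {
        acc[6] += 1.0;
        S.a2 += da;
        for (int i = 0; i < n; ++i) S.lam2[i] *= exp(da);
      }
    }
    // log delta random walk (theta held fixed)
    if (shared) {
      double dl = R::rnorm(0.0, scales[7]);
      double ldp = S.ld + dl, deltap = exp(ldp);
      double dpr = -ld_prec / 2.0 *
        ((ldp - ld_mean) * (ldp - ld_mean) -
         (S.ld - ld_mean) * (S.ld - ld_mean));
      double dll = 0.0;
      if (use_lik) {
        for (int i = 0; i < n; ++i) {
          double d1 = (deltap - S.delta) * S.th[i];
          double d2 = (1.0 / deltap - 1.0 / S.delta) * S.th[i];
          dll += O1[i] * d1 - S.lam1[i] * expm1(d1) +
                 O2[i] * d2 - S.lam2[i] * expm1(d2);
        }
      }
      att[7] += 1.0;
      if (std::isfinite(dll) && log(R::runif(0.0, 1.0)) < dpr + dll) {
        acc[7] += 1.0;
        if (use_lik) {
          for (int i = 0; i < n; ++i) {
            S.lam1[i] *= exp((deltap - S.delta) * S.th[i]);
            S.lam2[i] *= exp((1.0 / deltap - 1.0 / S.delta) * S.th[i]);
          }
        }
        S.ld = ldp;
        S.delta = deltap;
      }
    }
  }

  // hyperparameter block
  for (int sub = 0; sub < std::max(1, substeps); ++sub) {
    // conjugate precision draws (shape/rate Gamma)
    if (shared) {
      double q = pair_quad(S.th, edge_i, edge_j);
      S.tau[0] = R::rgamma(hyper(0, 0) + rank / 2.0,
                           1.0 / (hyper(0, 1) + q / 2.0));
    }
    {
      double q = pair_quad(S.s1, edge_i, edge_j);
      S.tau[1] = R::rgamma(hyper(1, 0) + rank / 2.0,
                           1.0 / (hyper(1, 1) + q / 2.0));
      q = pair_quad(S.s2, edge_i, edge_j);
      S.tau[2] = R::rgamma(hyper(2, 0) + rank / 2.0,
                           1.0 / (hyper(2, 1) + q / 2.0));
      double q1 = 0.0, q2 = 0.0;
      for (int i = 0; i < n; ++i) {
        q1 += S.u1[i] * S.u1[i];
        q2 += S.u2[i] * S.u2[i];
      }
      S.tau[3] = R::rgamma(hyper(3, 0) + n / 2.0,
                           1.0 / (hyper(3, 1) + q1 / 2.0));
      S.tau[4] = R::rgamma(hyper(4, 0) + n / 2.0,
                           1.0 / (hyper(4, 1) + q2 / 2.0));
    }
    if (shared) {
      // log delta random walk (as above)
      {
        double dl = R::rnorm(0.0, scales[7]);
        double ldp = S.ld + dl, deltap = exp(ldp);
        double dpr = -ld_prec / 2.0 *
          ((ldp - ld_mean) * (ldp - ld_mean) -
           (S.ld - ld_mean) * (S.ld - ld_mean));
        double dll = 0.0;
        if (use_lik) {
          for (int i = 0; i < n; ++i) {
            double d1 = (deltap - S.delta) * S.th[i];
            double d2 = (1.0 / deltap - 1.0 / S.delta) * S.th[i];
            dll += O1[i] * d1 - S.lam1[i] * expm1(d1) +
                   O2[i] * d2 - S.lam2[i] * expm1(d2);
          }
        }
        att[7] += 1.0;
        if (std::isfinite(dll) && log(R::runif(0.0, 1.0)) < dpr + dll) {
          acc[7] += 1.0;
          if (use_lik) {
            for (int i = 0; i < n; ++i) {
              S.lam1[i] *= exp((deltap - S.delta) * S.th[i]);
              S.lam2[i] *= exp((1.0 / deltap - 1.0 / S.delta) * S.th[i]);
            }
          }
          S.ld = ldp;
          S.delta = deltap;
        }
      }
      // shared_scale: (ld + dl, theta * exp(-dl)); outcome 1 invariant
      {
        double dl = R::rnorm(0.0, scales[8]);
        double E = pair_quad(S.th, edge_i, edge_j);
        double fac = expm1(-2.0 * dl);
        double d_quad = -S.tau[0] / 2.0 * E * fac;
        double d_ld = -ld_prec / 2.0 *
          ((S.ld + dl - ld_mean) * (S.ld + dl - ld_mean) -
           (S.ld - ld_mean) * (S.ld - ld_mean));
        double dll = 0.0;
        std::vector<double> d2(n);
        for (int i = 0; i < n; ++i) d2[i] = (S.th[i] / S.delta) * fac;
        if (use_lik) {
          for (int i = 0; i < n; ++i)
            dll += O2[i] * d2[i] - S.lam2[i] * expm1(d2[i]);
        }
        att[8] += 1.0;
        if (log(R::runif(0.0, 1.0)) < d_quad + d_ld + dll - n_free * dl) {
          acc[8] += 1.0;
          for (int i = 0; i < n; ++i) {
            if (!island[i]) S.th[i] *= exp(-dl);
            S.lam2[i] *= exp(d2[i]);
          }
          S.ld += dl;
          S.delta = exp(S.ld);
        }
      }
      // theta_scale: (theta * exp(c), tau_theta * exp(-2c))
      {
        double c = R::rnorm(0.0, scales[9]);
        double d_norm = -rank * c;
        double d_gam = (hyper(0, 0) - 1.0) * (-2.0 * c) -
          hyper(0, 1) * S.tau[0] * expm1(-2.0 * c);
        double g = expm1(c);
        double dll = 0.0;
        std::vector<double> d1(n), d2(n);
        for (int i = 0; i < n; ++i) {
          d1[i] = S.delta * S.th[i] * g;
          d2[i] = S.th[i] * g / S.delta;
        }
        if (use_lik) {
          for (int i = 0; i < n; ++i)
            dll += O1[i] * d1[i] - S.lam1[i] * expm1(d1[i]) +
                   O2[i] * d2[i] - S.lam2[i] * expm1(d2[i]);
        }
        att[9] += 1.0;
        if (std::isfinite(dll) &&
            log(R::runif(0.0, 1.0)) <
              d_norm + d_gam + dll + n_free * c - 2.0 * c) {
          acc[9] += 1.0;
          for (int i = 0; i < n; ++i) {
            if (!island[i]) S.th[i] *= exp(c);
            if (use_lik) {
              S.lam1[i] *= exp(d1[i]);
              S.lam2[i] *= exp(d2[i]);
            }
          }
          S.tau[0] *= exp(-2.0 * c);
        }
      }
      // shared_transfer: delta moves, s1 and s2 absorb both outcomes
      {
        double dl = R::rnorm(0.0, scales[10]);
        double a = S.delta * expm1(dl);
        double b = expm1(-dl) / S.delta;
        double Qt = pair_quad(S.th, edge_i, edge_j);
        double B1 = pair_bilin(S.s1, S.th, edge_i, edge_j);
        double B2 = pair_bilin(S.s2, S.th, edge_i, edge_j);
        double dQ1 = -2.0 * a * B1 + a * a * Qt;
        double dQ2 = -2.0 * b * B2 + b * b * Qt;
        double d_ld = -ld_prec / 2.0 *
          ((S.ld + dl - ld_mean) * (S.ld + dl - ld_mean) -
           (S.ld - ld_mean) * (S.ld - ld_mean));
        double lr = -S.tau[1] / 2.0 * dQ1 - S.tau[2] / 2.0 * dQ2 + d_ld;
        att[10] += 1.0;
        if (log(R::runif(0.0, 1.0)) < lr) {
          acc[10] += 1.0;
          for (int i = 0; i < n; ++i) {
            S.s1[i] -= a * S.th[i];
            S.s2[i] -= b * S.th[i];
          }
          S.ld += dl;
          S.delta = exp(S.ld);
        }
      }
      // transfer_s1 / transfer_s2: delta and the shared surface's scale
      // move together, one specific surface absorbing the change
      for (int t = 0; t < 2; ++t) {
        int bi = 11 + t;
        double dl = R::rnorm(0.0, scales[bi]);
        double Qt = pair_quad(S.th, edge_i, edge_j);
        double d_tau = (hyper(0, 0) - 1.0) * (-2.0 * dl) -
          hyper(0, 1) * S.tau[0] * expm1(-2.0 * dl);
        double sgn = (t == 0) ? 1.0 : -1.0;
        double d_ld = -ld_prec / 2.0 *
          ((S.ld + sgn * dl - ld_mean) * (S.ld + sgn * dl - ld_mean) -
           (S.ld - ld_mean) * (S.ld - ld_mean));
        double k, B, tau_s;
        if (t == 0) {
          k = S.delta * expm1(2.0 * dl);
          B = pair_bilin(S.s1, S.th, edge_i, edge_j);
          tau_s = S.tau[1];
        } else {
          k = expm1(2.0 * dl) / S.delta;
          B = pair_bilin(S.s2, S.th, edge_i, edge_j);
          tau_s = S.tau[2];
        }
        double d_s = -tau_s / 2.0 * (-2.0 * k * B + k * k * Qt);
        double lr = -rank * dl + d_tau + d_ld + d_s + (n_free - 2.0) * dl;
        att[bi] += 1.0;
        if (log(R::runif(0.0, 1.0)) < lr) {
          acc[bi] += 1.0;
          for (int i = 0; i < n; ++i) {
            double th_old = S.th[i];
            if (!island[i]) S.th[i] = th_old * exp(dl);
            if (t == 0) S.s1[i] -= k * th_old;
            else        S.s2[i] -= k * th_old;
          }
          S.tau[0] *= exp(-2.0 * dl);
          S.ld += sgn * dl;
          S.delta = exp(S.ld);
        }
      }
      // mix_s1 / mix_s2: shear a specific surface's pattern into theta,
      // both outcomes exactly compensated
      for (int t = 0; t < 2; ++t) {
        int bi = 13 + t;
        double g = R::rnorm(0.0, scales[bi]);
        const NumericVector& w = (t == 0) ? S.s1 : S.s2;
        double Qw = pair_quad(w, edge_i, edge_j);
        if (Qw == 0.0) continue;
        double Bt = pair_bilin(S.th, w, edge_i, edge_j);
        double B1 = pair_bilin(S.s1, w, edge_i, edge_j);
        double B2 = pair_bilin(S.s2, w, edge_i, edge_j);
        double c1 = -S.delta * g;
        double c2 = -g / S.delta;
        double lr = -S.tau[0] / 2.0 * (2.0 * g * Bt + g * g * Qw) -
          S.tau[1] / 2.0 * (2.0 * c1 * B1 + c1 * c1 * Qw) -
          S.tau[2] / 2.0 * (2.0 * c2 * B2 + c2 * c2 * Qw);
        att[bi] += 1.0;
        if (log(R::runif(0.0, 1.0)) < lr) {
          acc[bi] += 1.0;
          // w aliases s1 or s2: update via a copy
          std::vector<double> wc(w.begin(), w.end());
          for (int i = 0; i < n; ++i) {
            S.th[i] += g * wc[i];
            S.s1[i] += c1 * wc[i];
            S.s2[i] += c2 * wc[i];
          }
        }
      }
    }
    // per-field scale moves: s1, s2 (ICAR) then u1, u2 (unstructured)
    for (int t = 0; t < 4; ++t) {
      int bi = 15 + t;
      int f = t + 1;  // tau index: 1 = s1, 2 = s2, 3 = u1, 4 = u2
      double c = R::rnorm(0.0, scales[bi]);
      bool spatial = t < 2;
      NumericVector x = (f == 1) ? S.s1 : (f == 2) ? S.s2 :
                        (f == 3) ? S.u1 : S.u2;
      int rk = spatial ? rank : n;
      int nf = spatial ? n_free : n;
      double d_norm = -rk * c;
      double d_gam = (hyper(f, 0) - 1.0) * (-2.0 * c) -
        hyper(f, 1) * S.tau[f] * expm1(-2.0 * c);
      double g = expm1(c);
      double dll = 0.0;
      std::vector<double> d(n);
      for (int i = 0; i < n; ++i) d[i] = x[i] * g;
      if (use_lik) {
        if (f == 1 || f == 3) {
          for (int i = 0; i < n; ++i)
            dll += O1[i] * d[i] - S.lam1[i] * expm1(d[i]);
        } else {
          for (int i = 0; i < n; ++i)
            dll += O2[i] * d[i] - S.lam2[i] * expm1(d[i]);
        }
      }
      att[bi] += 1.0;
      if (std::isfinite(dll) &&
          log(R::runif(0.0, 1.0)) < d_norm + d_gam + dll + nf * c - 2.0 * c) {
        acc[bi] += 1.0;
        for (int i = 0; i < n; ++i) {
          if (!spatial || !island[i]) x[i] *= exp(c);
          if (use_lik) {
            if (f == 1 || f == 3) S.lam1[i] *= exp(d[i]);
            else                  S.lam2[i] *= exp(d[i]);
          }
        }
      }
    }
  }

  return List::create(_["th"] = S.th, _["s1"] = S.s1, _["s2"] = S.s2,
                      _["u1"] = S.u1, _["u2"] = S.u2,
                      _["a1"] = S.a1, _["a2"] = S.a2, _["ld"] = S.ld,
                      _["tau"] = S.tau, _["lam1"] = S.lam1,
                      _["lam2"] = S.lam2, _["acc"] = accv,
                      _["att"] = attv);
}
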