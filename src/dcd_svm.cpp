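#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for the L1-hinge linear SVM with per-example
// costs (Hsieh et al. style solver, the standard approach for large sparse
// text problems).  Primal:
//   min_w 0.5 ||w||^2 + sum_i C_i max(0, 1 - y_i w'x_i)
// The bias is handled by an augmented constant feature appended by the R
// wrapper.  Examples arrive as columns of a CSC matrix (i.e. t(X)), all
// values included so arbitrary real features work, though in this package
// they are binary indicators.

// Deterministic LCG so shuffling is reproducible independent of R's RNG.
static inline uint32_t lcg_next(uint32_t &s) {
  s = s * 1664525u + 1013904223u;
  return s;
}

// [[Rcpp::export(name = ".dcd_svm_fit")]]
NumericVector dcd_svm_fit(IntegerVector Xi, IntegerVector Xp, NumericVector Xx,
                          int n_features, NumericVector y, NumericVector C,
                          double eps, int max_iter, int seed) {
  const int n = Xp.size() - 1;  // number of examples (columns)
  std::vector<double> w(n_features, 0.0);
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qd(n);            // diagonal of Q: x_i'x_i
  std::vector<int> index(n);

  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = Xp[i]; k < Xp[i + 1]; ++k) s += Xx[k] * Xx[k];
    qd[i] = s;
    index[i] = i;
  }

  uint32_t rng = (uint32_t)seed;
  int active = n;
  double pg_max_old = R_PosInf, pg_min_old = R_NegInf;

  for (int iter = 0; iter < max_iter; ++iter) {
    double pg_max = R_NegInf, pg_min = R_PosInf;
    // shuffle active set
    for (int i = 0; i < active; ++i) {
      int j = i + (int)(lcg_next(rng) % (uint32_t)(active - i));
      std::swap(index[i], index[j]);
    }
    for (int s = 0; s < active; ++s) {
      int i = index[s];
      double yi = y[i];
      double g = -1.0;
      for (int k = Xp[i]; k < Xp[i + 1]; ++k) g += w[Xi[k]] * Xx[k] * yi;
      double Ci = C[i];
      // projected gradient with shrinking
      double pg = g;
      if (alpha[i] == 0.0) {
        if (g > pg_max_old) {  // shrink
          std::swap(index[s], index[active - 1]);
          --active; --s;
          continue;
        }
        if (g >= 0.0) pg = 0.0;
      } else if (alpha[i] == Ci) {
        if (g < pg_min_old) {
          std::swap(index[s], index[active - 1]);
          --active; --s;
          continue;
        }
        if (g <= 0.0) pg = 0.0;
      }
      pg_max = std::max(pg_max, pg);
      pg_min = std::min(pg_min, pg);
      if (pg != 0.0) {
        double a_old = alpha[i];
        double a_new = std::min(std::max(a_old - g / qd[i], 0.0), Ci);
        alpha[i] = a_new;
        double d = (a_new - a_old) * yi;
        if (d != 0.0)
          for (int k = Xp[i]; k < Xp[i + 1]; ++k) w[Xi[k]] += d * Xx[k];
      }
    }
    if (pg_max - pg_min <= eps) {
      if (active == n) break;
      // converged on active set: restart with full set
      active = n;
      pg_max_old = R_PosInf;
      pg_min_old = R_NegInf;
      continue;
    }
    pg_max_old = (pg_max <= 0.0) ? R_PosInf : pg_max;
    pg_min_old = (pg_min >= 0.0) ? R_NegInf : pg_min;
  }

  NumericVector out(n_features);
  for (int j = 0; j < n_features; ++j) out[j] = w[j];
  return out;
}
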