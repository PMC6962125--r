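// Inner kernel of the simulated likelihood for the mixed best-worst logit.
//
// Rows are alternatives ordered by occasion; occasions are contiguous with
// row ranges occ_ptr[o] .. occ_ptr[o+1]-1 (0-based, C style). For each
// draw the kernel evaluates every occasion's conditional-logit
// log-probability (max-subtraction guarded) and accumulates the
// per-cluster per-draw log-likelihood; the gradient pass returns the
// per-row weighted residual factors from which the R side assembles the
// analytic gradient and per-cluster scores.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List mixed_kernel(NumericVector base, NumericMatrix bM, NumericMatrix EM,
                  IntegerVector emrow, NumericVector sgn,
                  IntegerVector occ_ptr, IntegerVector chosen_row,
                  LogicalVector is_chosen,
                  IntegerVector cluster_occ, IntegerVector cluster_row,
                  int n_cluster, bool lognormal, bool want_grad) {
  const int n = base.size();
  const int R = bM.ncol();
  const int n_occ = occ_ptr.size() - 1;

  NumericMatrix l_cr(n_cluster, R);
  std::vector<double> V(n);
  const int nbm = bM.nrow();

  for (int r = 0; r < R; ++r) {
    const double* bMr = &bM[(R_xlen_t)r * nbm];
    double* lcr = &l_cr[(R_xlen_t)r * n_cluster];
    for (int i = 0; i < n; ++i) {
      double v = base[i];
      if (emrow[i] >= 0) v += sgn[i] * bMr[emrow[i]];
      V[i] = v;
    }
    for (int o = 0; o < n_occ; ++o) {
      const int s = occ_ptr[o], e = occ_ptr[o + 1];
      double m = V[s];
      for (int i = s + 1; i < e; ++i) if (V[i] > m) m = V[i];
      double den = 0.0;
      for (int i = s; i < e; ++i) den += std::exp(V[i] - m);
      lcr[cluster_occ[o]] += V[chosen_row[o]] - m - std::log(den);
    }
  }

  double ll = 0.0;
  NumericMatrix W(n_cluster, R);
  for (int c = 0; c < n_cluster; ++c) {
    double a = l_cr(c, 0);
    for (int r = 1; r < R; ++r) if (l_cr(c, r) > a) a = l_cr(c, r);
    double sw = 0.0;
    for (int r = 0; r < R; ++r) {
      double w = std::exp(l_cr(c, r) - a);
      W(c, r) = w;
      sw += w;
    }
    for (int r = 0; r < R; ++r) W(c, r) /= sw;
    ll += a + std::log(sw / R);
  }
  if (!want_grad)
    return List::create(_["ll"] = ll);

  // A: sum_r w (chosen - P); Bm / Bs carry the chain-rule factors of the
  // mixing location and scale (lognormal: beta; scale: beta * eta or eta)
  NumericVector A(n), Bm(n), Bs(n);
  std::vector<double> ex(16);
  for (int r = 0; r < R; ++r) {
    const double* bMr = &bM[(R_xlen_t)r * nbm];
    const double* EMr = &EM[(R_xlen_t)r * nbm];
    const double* Wr = &W[(R_xlen_t)r * n_cluster];
    for (int i = 0; i < n; ++i) {
      double v = base[i];
      if (emrow[i] >= 0) v += sgn[i] * bMr[emrow[i]];
      V[i] = v;
    }
    for (int o = 0; o < n_occ; ++o) {
      const int s = occ_ptr[o], e = occ_ptr[o + 1];
      double m = V[s];
      for (int i = s + 1; i < e; ++i) if (V[i] > m) m = V[i];
      double den = 0.0;
      for (int i = s; i < e; ++i) {
        ex[i - s] = std::exp(V[i] - m);
        den += ex[i - s];
      }
      for (int i = s; i < e; ++i) {
        const double P = ex[i - s] / den;
        const double wr = Wr[cluster_row[i]];
        const double resid = (is_chosen[i] ? 1.0 : 0.0) - P;
        const double wres = wr * resid;
        A[i] += wres;
        if (emrow[i] >= 0) {
          const double eta = EMr[emrow[i]];
          if (lognormal) {
            const double b = bMr[emrow[i]];
            Bm[i] += wres * b;
            Bs[i] += wres * b * eta;
          } else {
            Bs[i] += wres * eta;
          }
        }
      }
    }
  }
  return List::create(_["ll"] = ll, _["A"] = A, _["Bm"] = Bm, _["Bs"] = Bs);
}
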