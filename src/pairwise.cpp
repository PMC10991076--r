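#include <Rcpp.h>
using namespace Rcpp;

// Linear interpolation of a force profile tabulated on [0, r].
// The table must be fine enough that interpolation error is negligible
// relative to the integrator error; constant profiles are exact.
static inline double force_at(const NumericVector &ftab, double dist, double r) {
  int nf = ftab.size();
  double t = dist / r * (nf - 1);
  int k = (int)std::floor(t);
  if (k >= nf - 1) return ftab[nf - 1];
  if (k < 0) return ftab[0];
  double w = t - k;
  return (1.0 - w) * ftab[k] + w * ftab[k + 1];
}

// Mean-field pairwise adhesion acceleration:
//   accel_i = chi_i * y_i * (1/N) * sum_{j != i} gradH(x_i - x_j)
// with gradH(z) = -(1/(r|B_r|)) z/|z| F(|z|) for 0 < |z| <= r, else 0.
// Coincident pairs (|z| = 0) contribute zero; at |z| = r the one-sided
// value F(r) is used.
// [[Rcpp::export]]
NumericMatrix pairwise_accel_cpp(const NumericMatrix &x,
                                 const Nullable<NumericVector> &yfrac,
                                 const NumericVector &chi,
                                 const NumericVector &ftab,
                                 double r, double inv_rB) {
  int N = x.nrow(), d = x.ncol();
  NumericMatrix raw(N, d);
  std::vector<double> z(d);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double dist2 = 0.0;
      for (int k = 0; k < d; ++k) {
        z[k] = x(i, k) - x(j, k);
        dist2 += z[k] * z[k];
      }
      double dist = std::sqrt(dist2);
      if (dist <= 0.0 || dist > r) continue;
      double w = -inv_rB * force_at(ftab, dist, r) / dist;
      for (int k = 0; k < d; ++k) {
        double g = w * z[k];    // gradH(x_i - x_j), odd in z
        raw(i, k) += g;
        raw(j, k) -= g;
      }
    }
  }
  NumericVector y = yfrac.isNotNull() ? NumericVector(yfrac) :
    NumericVector(N, 1.0);
  for (int i = 0; i < N; ++i) {
    double s = chi[i] * y[i] / N;
    for (int k = 0; k < d; ++k) raw(i, k) *= s;
  }
  return raw;
}
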