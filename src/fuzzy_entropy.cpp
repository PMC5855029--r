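#include <Rcpp.h>
using namespace Rcpp;

// Average pairwise fuzzy similarity of mean-centred embedding templates at
// dimensions m and m+1, in a single pass over template pairs.
// A template is x[i..i+m-1] minus its own mean; the distance is Chebyshev;
// the membership is exp(-(d/r)^n). Returns c(phi_m, phi_{m+1}).
// Memberships below ~1e-22 are skipped (exp argument > 50) -- they cannot
// affect the average at double precision.
// [[Rcpp::export]]
NumericVector fe_phi_pair(NumericVector x, int m, double r, double n) {
  const int N = x.size();
  const int nt_m = N - m + 1;    // templates of length m
  const int nt_m1 = N - m;       // templates of length m + 1
  if (nt_m1 < 2) stop("signal too short for embedding dimension m");
  if (r <= 0) stop("tolerance r must be positive");

  // window means via prefix sums
  std::vector<double> cs(N + 1, 0.0);
  for (int i = 0; i < N; ++i) cs[i + 1] = cs[i] + x[i];
  std::vector<double> mu_m(nt_m), mu_m1(nt_m1);
  for (int i = 0; i < nt_m; ++i) mu_m[i] = (cs[i + m] - cs[i]) / m;
  for (int i = 0; i < nt_m1; ++i)
    mu_m1[i] = (cs[i + m + 1] - cs[i]) / (m + 1);

  const bool quad = (n == 2.0);
  const double inv_r = 1.0 / r;
  double acc_m = 0.0, acc_m1 = 0.0;
  for (int i = 0; i < nt_m - 1; ++i) {
    for (int j = i + 1; j < nt_m; ++j) {
      const double dm_shift = mu_m[i] - mu_m[j];
      double d_m = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k] - dm_shift);
        if (dk > d_m) d_m = dk;
      }
      double u = d_m * inv_r;
      double a = quad ? u * u : std::pow(u, n);
      if (a < 50.0) acc_m += std::exp(-a);
      if (j < nt_m1) {           // both are valid (m+1)-templates
        const double d1_shift = mu_m1[i] - mu_m1[j];
        double d_m1 = 0.0;
        for (int k = 0; k <= m; ++k) {
          double dk = std::fabs(x[i + k] - x[j + k] - d1_shift);
          if (dk > d_m1) d_m1 = dk;
        }
        double u1 = d_m1 * inv_r;
        double a1 = quad ? u1 * u1 : std::pow(u1, n);
        if (a1 < 50.0) acc_m1 += std::exp(-a1);
      }
    }
  }
  NumericVector out(2);
  out[0] = 2.0 * acc_m / ((double)nt_m * (nt_m - 1));
  out[1] = 2.0 * acc_m1 / ((double)nt_m1 * (nt_m1 - 1));
  return out;
}
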