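#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo (1992) style recursion for pedigree inbreeding
// coefficients.  Individuals are 1..n with parents preceding offspring and
// 0 for an unknown parent.  For each individual the generation-by-
// generation contribution vector L over its ancestors is traced and
// F_i = sum_j L_j^2 D_j - 1, with D_j the Mendelian sampling variance of j
// on the relationship scale (unknown-parent F treated as -1 so base
// animals get D = 1).
//
// `f_known` supplies already-computed coefficients for individuals
// 1..(start-1), so a growing pedigree only pays for its newest cohort.

// [[Rcpp::export]]
NumericVector ml_inbreeding_cpp(IntegerVector sire, IntegerVector dam,
                                NumericVector f_known, int start) {
  int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n + 1);
  std::vector<double> L(n + 1, 0.0);

  for (int i = 1; i < start; ++i) F[i - 1] = f_known[i - 1];
  for (int i = 1; i <= n; ++i) {
    int s = sire[i - 1], d = dam[i - 1];
    if (s >= i || d >= i)
      stop("pedigree not ordered: parent id >= individual id at %d", i);
    double Fs = s > 0 ? F[s - 1] : -1.0;
    double Fd = d > 0 ? F[d - 1] : -1.0;
    D[i] = 0.5 - 0.25 * (Fs + Fd);
    if (i < start) continue;
    if (s == 0 && d == 0) { F[i - 1] = 0.0; continue; }
    L[i] = 1.0;
    double a = 0.0;
    for (int j = i; j >= 1; --j) {
      double Lj = L[j];
      if (Lj != 0.0) {
        int sj = sire[j - 1], dj = dam[j - 1];
        if (sj > 0) L[sj] += 0.5 * Lj;
        if (dj > 0) L[dj] += 0.5 * Lj;
        a += Lj * Lj * D[j];
        L[j] = 0.0;
      }
    }
    F[i - 1] = a - 1.0;
  }
  return F;
}
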