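#include <Rcpp.h>
using namespace Rcpp;

// Pedigree kernels. Animals must be in topological order (parents before
// offspring); sire/dam are 1-based indices into the same ordering, 0 = unknown.

// Tabular (recursive) numerator relationship matrix.
// [[Rcpp::export]]
NumericMatrix cpp_tabular_A(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("pedigree not in topological order");
    double asd = (s >= 0 && d >= 0) ? A(s, d) : 0.0;
    A(i, i) = 1.0 + 0.5 * asd;
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(i, j) = v;
      A(j, i) = v;
    }
  }
  return A;
}

// Within-family variance D_j given parental inbreeding (F of unknown parent
// treated as absent, not -1).
static inline double d_coef(int js, int jd, const NumericVector &F) {
  if (js >= 0 && jd >= 0) return 0.5 - 0.25 * (F[js] + F[jd]);
  if (js >= 0) return 0.75 - 0.25 * F[js];
  if (jd >= 0) return 0.75 - 0.25 * F[jd];
  return 1.0;
}

// Inbreeding coefficients without forming A, using the A = L D L'
// decomposition (Meuwissen & Luo style): F_i = 0.5 * a_sd with
// a_sd = sum_j L_sj * L_dj * D_j, where the L rows are accumulated by
// walking ancestors from the parents downward.
// [[Rcpp::export]]
NumericVector cpp_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  for (int i = 0; i < n; ++i) {
    int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("pedigree not in topological order");
    if (s < 0 || d < 0) { F[i] = 0.0; continue; }
    if (i > 0 && sire[i] == sire[i - 1] && dam[i] == dam[i - 1]) {
      F[i] = F[i - 1];  // full sibs share F
      continue;
    }
    int top = std::max(s, d);
    std::vector<double> Ls(top + 1, 0.0), Ld(top + 1, 0.0);
    Ls[s] = 1.0;
    Ld[d] = 1.0;
    double asd = 0.0;
    for (int j = top; j >= 0; --j) {
      double ls = Ls[j], ld = Ld[j];
      if (ls == 0.0 && ld == 0.0) continue;
      int js = sire[j] - 1, jd = dam[j] - 1;
      if (ls != 0.0 && ld != 0.0) asd += ls * ld * d_coef(js, jd, F);
      if (js >= 0) { Ls[js] += 0.5 * ls; Ld[js] += 0.5 * ld; }
      if (jd >= 0) { Ls[jd] += 0.5 * ls; Ld[jd] += 0.5 * ld; }
    }
    F[i] = 0.5 * asd;
  }
  return F;
}
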