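#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Numerator relationship matrix by the tabular method.  sire/dam are 1-based
// row indices into the pedigree (0 = unknown); parents must precede offspring.
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_A_tabular(const IntegerVector &sire, const IntegerVector &dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("parents must precede offspring in the pedigree");
    for (int j = 0; j < i; ++j) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(j, s);
      if (d >= 0) v += 0.5 * A(j, d);
      A(j, i) = v;
      A(i, j) = v;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}

// Inbreeding coefficients (Meuwissen & Luo style ancestor walk) and the
// sparse inverse of A assembled from Henderson's rules.  Returns COO triplets
// (1-based) plus F and the Mendelian sampling variances D.
//' @noRd
// [[Rcpp::export]]
List cpp_ainv(const IntegerVector &sire, const IntegerVector &dam) {
  const int n = sire.size();
  std::vector<double> F(n, 0.0), D(n, 1.0), Lv(n, 0.0);

  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    if (s >= i || d >= i) stop("parents must precede offspring in the pedigree");
    if (s < 0 && d < 0) {
      F[i] = 0.0; D[i] = 1.0;
    } else if (s < 0 || d < 0) {
      const int p = (s >= 0) ? s : d;
      F[i] = 0.0; D[i] = 0.75 - 0.25 * F[p];
    } else {
      D[i] = 0.5 - 0.25 * (F[s] + F[d]);
      // A_ii = sum_k L_k^2 D_k over the ancestor closure of i
      Lv[i] = 1.0;
      double acc = 0.0;
      for (int k = i; k >= 0; --k) {
        const double lk = Lv[k];
        if (lk == 0.0) continue;
        acc += lk * lk * D[k];
        const int ks = sire[k] - 1, kd = dam[k] - 1;
        if (ks >= 0) Lv[ks] += 0.5 * lk;
        if (kd >= 0) Lv[kd] += 0.5 * lk;
        Lv[k] = 0.0;
      }
      F[i] = acc - 1.0;
    }
  }

  std::vector<int> ii, jj;
  std::vector<double> xx;
  ii.reserve(9 * n); jj.reserve(9 * n); xx.reserve(9 * n);
  auto push = [&](int a, int b, double v) {
    ii.push_back(a + 1); jj.push_back(b + 1); xx.push_back(v);
  };
  for (int i = 0; i < n; ++i) {
    const int s = sire[i] - 1, d = dam[i] - 1;
    const double al = 1.0 / D[i];
    push(i, i, al);
    if (s >= 0) {
      push(i, s, -0.5 * al); push(s, i, -0.5 * al); push(s, s, 0.25 * al);
    }
    if (d >= 0) {
      push(i, d, -0.5 * al); push(d, i, -0.5 * al); push(d, d, 0.25 * al);
    }
    if (s >= 0 && d >= 0) {
      push(s, d, 0.25 * al); push(d, s, 0.25 * al);
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["x"] = wrap(xx),
                      _["F"] = wrap(F), _["D"] = wrap(D));
}
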