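#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

// Crossover positions on one chromosome of length `len` Morgans, drawn from a
// stationary gamma renewal process with the given shape (interference) and
// unit mean spacing, so E[count] = len.  For integer shape the first arrival
// uses the exact Erlang-mixture forward-recurrence distribution; otherwise the
// process is burnt in from 20 mean spacings before the origin.
static void sample_xovers(double len, double shape, std::vector<double> &out) {
  out.clear();
  const double scale = 1.0 / shape; // rate = shape => mean spacing 1 Morgan
  double t;
  int k = (int)std::lround(shape);
  if (std::fabs(shape - (double)k) < 1e-9 && k >= 1) {
    int j = 1 + (int)(unif_rand() * k);
    if (j > k) j = k;
    t = R::rgamma((double)j, scale);
  } else {
    t = -20.0;
    while (t < 0.0) t += R::rgamma(shape, scale);
  }
  while (t < len) {
    out.push_back(t);
    t += R::rgamma(shape, scale);
  }
}

// Flip exactly nm distinct loci (Floyd's sampling), matching per-locus
// independent mutation: the flip count is Binomial(L, mu) and the flipped set
// is uniform given the count.
static void mutate_gamete(int *o, int L, int nm) {
  if (nm <= 0) return;
  std::unordered_set<int> chosen;
  for (int j = L - nm; j < L; ++j) {
    int t = (int)(unif_rand() * (j + 1));
    if (t > j) t = j;
    if (chosen.count(t)) chosen.insert(j); else chosen.insert(t);
  }
  for (int idx : chosen) o[idx] = 1 - o[idx];
}

//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_drop_gametes(const IntegerMatrix &haps,
                               const IntegerVector &colA,
                               const IntegerVector &colB,
                               const IntegerVector &chromFirst,
                               const IntegerVector &chromCount,
                               const NumericVector &posM,
                               const NumericVector &chromLenM,
                               double interference,
                               double mutRate) {
  const int L = haps.nrow();
  const int G = colA.size();
  const int C = chromLenM.size();
  if (interference <= 0) stop("interference must be > 0");
  if (mutRate < 0 || mutRate > 1) stop("mutation rate must be in [0, 1]");
  IntegerMatrix out(L, G);
  std::vector<double> xo;
  for (int g = 0; g < G; ++g) {
    const int ca = colA[g] - 1, cb = colB[g] - 1;
    if (ca < 0 || cb < 0 || ca >= haps.ncol() || cb >= haps.ncol())
      stop("haplotype column index out of range");
    const int *a = &haps(0, ca);
    const int *b = &haps(0, cb);
    int *o = &out(0, g);
    for (int c = 0; c < C; ++c) {
      sample_xovers(chromLenM[c], interference, xo);
      const int nxo = (int)xo.size();
      int cur = (unif_rand() < 0.5) ? 0 : 1;
      int k = 0;
      const int i0 = chromFirst[c], n = chromCount[c];
      for (int i = i0; i < i0 + n; ++i) {
        const double p = posM[i];
        while (k < nxo && xo[k] <= p) { cur ^= 1; ++k; }
        o[i] = cur ? b[i] : a[i];
      }
    }
    if (mutRate > 0) {
      int nm = (int)R::rbinom((double)L, mutRate);
      mutate_gamete(o, L, nm);
    }
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
List cpp_sample_xover_positions(int n, double len, double shape) {
  // diagnostic access to the renewal process itself (per-meiosis positions)
  List res(n);
  std::vector<double> xo;
  for (int i = 0; i < n; ++i) {
    sample_xovers(len, shape, xo);
    res[i] = NumericVector(xo.begin(), xo.end());
  }
  return res;
}
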