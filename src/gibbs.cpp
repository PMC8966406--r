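#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Single-site Gibbs samplers for whole-genome regression with four marker
// priors: Bayesian ridge regression (common marker variance), BayesA
// (per-marker scaled-inverse-chi-square variances), BayesB (point mass pi at
// zero plus scaled-inverse-chi-square slab) and the Bayesian LASSO
// (double-exponential via the normal/exponential scale mixture of Park &
// Casella).  The model is y = 1 mu + Z b + e with Z column-centred.

static double rscinvchisq(double df, double S) {
  // scaled inverse chi-square: df * S / chisq(df)
  return df * S / R::rchisq(df);
}

static double rinvgauss(double mu, double lambda) {
  double v = norm_rand();
  double y = v * v;
  double x = mu + mu * mu * y / (2.0 * lambda) -
             mu / (2.0 * lambda) * std::sqrt(4.0 * mu * lambda * y + mu * mu * y * y);
  if (x <= 0) x = 1e-12;
  if (unif_rand() <= mu / (mu + x)) return x;
  return mu * mu / x;
}

//' @noRd
// [[Rcpp::export]]
List cpp_bayes_gibbs(const NumericMatrix &Z, const NumericVector &y,
                     int method, int niter, int burnin, int thin,
                     double dfMarker, double Smarker,
                     double dfB, double Sb,
                     double pi0,
                     double blShape, double blRate, double lambda2Init,
                     double dfE, double Se) {
  const int n = Z.nrow(), p = Z.ncol();
  if (niter <= 0) stop("chain length must be positive");
  if (burnin < 0 || burnin >= niter) stop("burn-in must lie in [0, niter)");
  if (thin < 1) stop("thinning interval must be >= 1");

  std::vector<double> zz(p);
  for (int j = 0; j < p; ++j) {
    const double *z = &Z(0, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += z[i] * z[i];
    zz[j] = s;
  }

  double mu = 0.0;
  for (int i = 0; i < n; ++i) mu += y[i];
  mu /= n;

  std::vector<double> b(p, 0.0), varb(p), tau2(p, 1.0), e(n);
  std::vector<int> del(p, 1);
  const double s2bInit = (Sb > 0) ? Sb : 0.01;
  double s2b = s2bInit;            // BRR common marker variance
  double lambda2 = lambda2Init;    // BL
  double s2e = 0.0;
  for (int i = 0; i < n; ++i) { e[i] = y[i] - mu; s2e += e[i] * e[i]; }
  s2e = std::max(s2e / n * 0.5, 1e-8);
  for (int j = 0; j < p; ++j) varb[j] = (method == 1 || method == 2) ? Smarker : s2b;

  std::vector<double> bSum(p, 0.0), varbSum(p, 0.0), pipSum(p, 0.0);
  double muSum = 0.0, lambda2Sum = 0.0;
  std::vector<double> s2eKeep;
  int nKeep = 0;

  for (int it = 0; it < niter; ++it) {
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
    // intercept
    double mean_e = 0.0;
    for (int i = 0; i < n; ++i) mean_e += e[i];
    mean_e /= n;
    const double muNew = mu + mean_e + std::sqrt(s2e / n) * norm_rand();
    const double dmu = muNew - mu;
    for (int i = 0; i < n; ++i) e[i] -= dmu;
    mu = muNew;

    double ssb = 0.0; // sum b^2 (BRR)

    for (int j = 0; j < p; ++j) {
      const double *z = &Z(0, j);
      const double bOld = b[j];
      double rhs = 0.0;
      for (int i = 0; i < n; ++i) rhs += z[i] * e[i];
      rhs += zz[j] * bOld; // z' (residual excluding marker j)

      double bNew = 0.0;
      if (method == 2) {
        // BayesB: sample indicator with b integrated out given varb[j]
        const double s2j = varb[j];
        const double v1 = s2e + zz[j] * s2j;
        const double logBF = 0.5 * std::log(s2e / v1) +
                             rhs * rhs * s2j / (2.0 * s2e * v1);
        const double logOdds = std::log((1.0 - pi0) / pi0) + logBF;
        const double pIn = 1.0 / (1.0 + std::exp(-logOdds));
        del[j] = (unif_rand() < pIn) ? 1 : 0;
        if (del[j]) {
          const double C = zz[j] + s2e / s2j;
          bNew = rhs / C + std::sqrt(s2e / C) * norm_rand();
        }
        // slab variance update (prior draw when excluded)
        varb[j] = del[j]
          ? (dfMarker * Smarker + bNew * bNew) / R::rchisq(dfMarker + 1.0)
          : rscinvchisq(dfMarker, Smarker);
      } else if (method == 3) {
        // Bayesian LASSO: b_j ~ N(0, s2e * tau2_j)
        const double C = zz[j] + 1.0 / tau2[j];
        bNew = rhs / C + std::sqrt(s2e / C) * norm_rand();
        const double babs = std::fabs(bNew);
        const double muIG = std::sqrt(lambda2 * s2e) / std::max(babs, 1e-10);
        const double invTau2 = rinvgauss(muIG, lambda2);
        tau2[j] = 1.0 / std::max(invTau2, 1e-12);
      } else {
        // BRR (common variance) or BayesA (per-marker variance)
        const double s2j = (method == 1) ? varb[j] : s2b;
        const double C = zz[j] + s2e / s2j;
        bNew = rhs / C + std::sqrt(s2e / C) * norm_rand();
        if (method == 1)
          varb[j] = (dfMarker * Smarker + bNew * bNew) / R::rchisq(dfMarker + 1.0);
        else
          ssb += bNew * bNew;
      }

      const double db = bNew - bOld;
      if (db != 0.0) for (int i = 0; i < n; ++i) e[i] -= z[i] * db;
      b[j] = bNew;
    }

    if (method == 0) {
      s2b = (dfB * Sb + ssb) / R::rchisq(dfB + p);
      for (int j = 0; j < p; ++j) varb[j] = s2b;
    }
    if (method == 3) {
      double sumTau2 = 0.0;
      for (int j = 0; j < p; ++j) sumTau2 += tau2[j];
      lambda2 = R::rgamma(blShape + p, 1.0 / (blRate + 0.5 * sumTau2));
      for (int j = 0; j < p; ++j) varb[j] = s2e * tau2[j];
    }

    double sse = 0.0;
    for (int i = 0; i < n; ++i) sse += e[i] * e[i];
    s2e = (dfE * Se + sse) / R::rchisq(dfE + n);

    if (it >= burnin && ((it - burnin) % thin == 0)) {
      ++nKeep;
      muSum += mu;
      lambda2Sum += lambda2;
      s2eKeep.push_back(s2e);
      for (int j = 0; j < p; ++j) {
        bSum[j] += b[j];
        varbSum[j] += varb[j];
        pipSum[j] += del[j];
      }
    }
  }

  NumericVector bMean(p), varbMean(p), pip(p);
  for (int j = 0; j < p; ++j) {
    bMean[j] = bSum[j] / nKeep;
    varbMean[j] = varbSum[j] / nKeep;
    pip[j] = pipSum[j] / nKeep;
  }
  return List::create(
    _["b"] = bMean, _["mu"] = muSum / nKeep,
    _["varb"] = varbMean, _["pip"] = pip,
    _["lambda2"] = lambda2Sum / nKeep,
    _["s2e_samples"] = wrap(s2eKeep), _["n_samples"] = nKeep);
}
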