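// Sparse Bayesian regression inner loop (Tipping-style re-estimation).
// The R wrapper owns all input validation and basis construction; this
// routine only iterates the posterior / hyperparameter updates.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export(name = ".rvrCore")]]
Rcpp::List rvrCore(const arma::mat& Phi, const arma::vec& y,
                   arma::vec alpha, int biasIndex,
                   double noiseVar, bool updateAlpha, bool updateNoise,
                   double pruneThreshold, double tol, int maxIter,
                   double noiseVarFloor, int noiseUpdateStart) {
  // biasIndex is 0-based; pass -1 when no bias column is present
  const uword n = Phi.n_rows;
  uvec active = regspace<uvec>(0, Phi.n_cols - 1);
  vec alphaAct = alpha;
  vec mu; mat Sigma;
  bool converged = false;
  int iter = 0;
  const double s2floor = (noiseVarFloor > 1e-12) ? noiseVarFloor : 1e-12;

  for (iter = 1; iter <= maxIter; ++iter) {
    mat PhiA = Phi.cols(active);
    mat H = PhiA.t() * PhiA / noiseVar;
    H.diag() += alphaAct;
    mat Hs = symmatu(H);
    bool ok = inv_sympd(Sigma, Hs);
    if (!ok) Sigma = pinv(Hs);
    mu = Sigma * (PhiA.t() * y) / noiseVar;

    vec gamma = 1.0 - alphaAct % Sigma.diag();
    gamma = clamp(gamma, 1e-12, 1.0);

    vec newAlpha = alphaAct;
    if (updateAlpha) {
      for (uword i = 0; i < active.n_elem; ++i) {
        if ((int)active(i) == biasIndex) continue;
        double m2 = mu(i) * mu(i);
        newAlpha(i) = (m2 > 0) ? gamma(i) / m2 : 2.0 * pruneThreshold;
      }
    }
    if (updateNoise && iter > noiseUpdateStart) {
      vec resid = y - PhiA * mu;
      double denom = (double)n - accu(gamma);
      if (denom < 1e-6) denom = 1e-6;
      noiseVar = dot(resid, resid) / denom;
      if (noiseVar < s2floor) noiseVar = s2floor;
    }

    // convergence on surviving, non-bias precisions
    double maxDelta = 0.0;
    uvec keep(active.n_elem);
    uword nKeep = 0;
    for (uword i = 0; i < active.n_elem; ++i) {
      bool isBias = ((int)active(i) == biasIndex);
      if (!isBias && newAlpha(i) > pruneThreshold) continue;
      if (!isBias) {
        double d = std::fabs(std::log(newAlpha(i)) - std::log(alphaAct(i)));
        if (d > maxDelta) maxDelta = d;
      }
      keep(nKeep++) = i;
    }
    keep.resize(nKeep);
    bool pruned = (nKeep < active.n_elem);
    active = active(keep);
    alphaAct = newAlpha(keep);
    if (active.n_elem == 0) break;
    // never declare convergence while the noise update is still frozen
    if (!updateAlpha ||
        (maxDelta < tol && !pruned &&
         (!updateNoise || iter > noiseUpdateStart))) {
      converged = true;
      break;
    }
  }
  if (iter > maxIter) iter = maxIter;

  // final posterior at the converged hyperparameters
  if (active.n_elem > 0) {
    mat PhiA = Phi.cols(active);
    mat H = PhiA.t() * PhiA / noiseVar;
    H.diag() += alphaAct;
    mat Hs = symmatu(H);
    if (!inv_sympd(Sigma, Hs)) Sigma = pinv(Hs);
    mu = Sigma * (PhiA.t() * y) / noiseVar;
  } else {
    Sigma.set_size(0, 0);
    mu.set_size(0);
  }

  return Rcpp::List::create(
    Rcpp::Named("mu") = mu,
    Rcpp::Named("sigma") = Sigma,
    Rcpp::Named("alpha") = alphaAct,
    Rcpp::Named("active") = active + 1, // back to 1-based
    Rcpp::Named("noiseVar") = noiseVar,
    Rcpp::Named("iterations") = iter,
    Rcpp::Named("converged") = converged);
}
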