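#include <Rcpp.h>
using namespace Rcpp;

// Partial log-likelihood, score and observed information for a Cox
// proportional-hazards model with right-censored data and tied event
// times handled by the Efron or Breslow approximation.
//
// Inputs must be pre-sorted by time in *increasing* order; rows with
// equal times may appear in any order.  The risk set at time t is all
// rows with time >= t, so accumulation runs from the largest time down.
//
// method: 0 = Breslow, 1 = Efron.
// [[Rcpp::export(name = ".cox_derivs_cpp")]]
List cox_derivs_cpp(NumericVector time, IntegerVector event,
                    NumericMatrix X, NumericVector beta, int method) {
  const int n = time.size();
  const int p = X.ncol();
  if (event.size() != n || X.nrow() != n || beta.size() != p)
    stop("dimension mismatch");

  std::vector<double> eta(n), w(n);
  double emax = 0.0;
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
    if (e > emax) emax = e;
  }
  // guard exp() overflow during line search excursions
  for (int i = 0; i < n; ++i) w[i] = std::exp(eta[i] - emax);

  double loglik = 0.0;
  NumericVector grad(p);
  NumericMatrix hess(p, p);

  // risk-set accumulators
  double sR = 0.0;
  std::vector<double> uR(p, 0.0), vR(p * p, 0.0);
  // tied-event (death-set) accumulators
  std::vector<double> uD(p), vD(p * p);

  int i = n - 1;
  while (i >= 0) {
    const double t = time[i];
    int d = 0;
    double sD = 0.0, etaD = 0.0;
    std::fill(uD.begin(), uD.end(), 0.0);
    std::fill(vD.begin(), vD.end(), 0.0);
    // absorb the whole tie block at time t into the risk set
    while (i >= 0 && time[i] == t) {
      const double wi = w[i];
      sR += wi;
      for (int j = 0; j < p; ++j) {
        uR[j] += wi * X(i, j);
        for (int k = 0; k <= j; ++k) vR[j * p + k] += wi * X(i, j) * X(i, k);
      }
      if (event[i] == 1) {
        ++d;
        sD += wi;
        etaD += eta[i];
        for (int j = 0; j < p; ++j) {
          uD[j] += wi * X(i, j);
          for (int k = 0; k <= j; ++k) vD[j * p + k] += wi * X(i, j) * X(i, k);
          grad[j] += X(i, j);
        }
      }
      --i;
    }
    if (d == 0) continue;
    loglik += etaD - d * (emax);  // eta sum, shift restored below per term
    for (int r = 0; r < d; ++r) {
      const double f = (method == 1) ? (double)r / d : 0.0;
      const double s = sR - f * sD;
      loglik -= std::log(s);
      for (int j = 0; j < p; ++j) {
        const double uj = uR[j] - f * uD[j];
        grad[j] -= uj / s;
        for (int k = 0; k <= j; ++k) {
          const double ujk = vR[j * p + k] - f * vD[j * p + k];
          const double uk = uR[k] - f * uD[k];
          hess(j, k) -= ujk / s - (uj * uk) / (s * s);
        }
      }
    }
  }
  // the emax shift cancels between the eta sum and log-denominators:
  // log(sum w) = log(sum exp(eta)) - emax, and we subtracted d*emax above.
  for (int j = 0; j < p; ++j)
    for (int k = j + 1; k < p; ++k) hess(j, k) = hess(k, j);

  return List::create(_["loglik"] = loglik, _["gradient"] = grad,
                      _["hessian"] = hess);
}
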