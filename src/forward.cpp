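#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward recursion for a multi-animal HMM.
// allProbs: T x N matrix of per-interval emission probabilities (product over
//   data streams, missing streams contributing 1).
// gamma: N x N row-stochastic transition matrix; delta: length-N initial
//   distribution, re-applied at the first interval of each animal.
// aInd: 1-based row indices where a new animal's series starts (first must be 1).
// [[Rcpp::export]]
double forwardLogLikC(NumericMatrix allProbs, NumericMatrix gamma,
                      NumericVector delta, IntegerVector aInd) {
  int T = allProbs.nrow(), N = allProbs.ncol();
  double ll = 0.0;
  std::vector<double> v(N), u(N);
  int ai = 0;
  for (int t = 0; t < T; t++) {
    if (ai < aInd.size() && t == aInd[ai] - 1) {
      for (int j = 0; j < N; j++) v[j] = delta[j] * allProbs(t, j);
      ai++;
    } else {
      for (int j = 0; j < N; j++) {
        double s = 0.0;
        for (int i = 0; i < N; i++) s += v[i] * gamma(i, j);
        u[j] = s * allProbs(t, j);
      }
      v = u;
    }
    double c = 0.0;
    for (int j = 0; j < N; j++) c += v[j];
    if (!(c > 0.0) || !R_finite(c)) return R_NegInf;
    for (int j = 0; j < N; j++) v[j] /= c;
    ll += std::log(c);
  }
  return ll;
}

// Negative forward log-likelihood with the Gamma / von Mises / Poisson
// emission densities computed in place (NA observation = missing stream,
// contributing likelihood 1). The caller precomputes the data transforms
// logStep = log(step), turnCos/turnSin = cos/sin(turn), lgamNd =
// lgamma(ndives + 1), so each (interval, state) cell costs a single exp().
// Used by the optimizer; the R-level hmmAllProbs()/forwardLoglik() path
// remains the reference implementation.
// [[Rcpp::export]]
double nLogLikC(NumericVector step, NumericVector logStep,
                NumericVector turnCos, NumericVector turnSin,
                NumericVector ndives, NumericVector lgamNd,
                NumericVector stepShape, NumericVector stepScale,
                NumericVector turnMean, NumericVector turnKappa,
                NumericVector diveRate, NumericMatrix gamma,
                NumericVector delta, IntegerVector aInd) {
  int T = step.size(), N = stepShape.size();
  std::vector<double> vmLogNorm(N), cosMu(N), sinMu(N), gamConst(N),
      invScale(N), logRate(N);
  for (int k = 0; k < N; k++) {
    vmLogNorm[k] = std::log(2.0 * M_PI * Rf_bessel_i(turnKappa[k], 0.0, 2.0)) +
                   turnKappa[k];
    cosMu[k] = std::cos(turnMean[k]);
    sinMu[k] = std::sin(turnMean[k]);
    gamConst[k] = -stepShape[k] * std::log(stepScale[k]) -
                  Rf_lgammafn(stepShape[k]);
    invScale[k] = 1.0 / stepScale[k];
    logRate[k] = std::log(diveRate[k]);
  }
  double ll = 0.0;
  std::vector<double> v(N), u(N), p(N);
  int ai = 0;
  for (int t = 0; t < T; t++) {
    for (int k = 0; k < N; k++) {
      double a = 0.0;
      if (!ISNAN(step[t]))
        a += (stepShape[k] - 1.0) * logStep[t] - step[t] * invScale[k] +
             gamConst[k];
      if (!ISNAN(turnCos[t]))
        a += turnKappa[k] * (turnCos[t] * cosMu[k] + turnSin[t] * sinMu[k]) -
             vmLogNorm[k];
      if (!ISNAN(ndives[t]))
        a += ndives[t] * logRate[k] - diveRate[k] - lgamNd[t];
      double pk = std::exp(a);
      if (!R_finite(pk)) return R_PosInf;
      p[k] = pk;
    }
    if (ai < aInd.size() && t == aInd[ai] - 1) {
      for (int j = 0; j < N; j++) v[j] = delta[j] * p[j];
      ai++;
    } else {
      for (int j = 0; j < N; j++) {
        double s = 0.0;
        for (int i = 0; i < N; i++) s += v[i] * gamma(i, j);
        u[j] = s * p[j];
      }
      v = u;
    }
    double c = 0.0;
    for (int j = 0; j < N; j++) c += v[j];
    if (!(c > 0.0) || !R_finite(c)) return R_PosInf;
    for (int j = 0; j < N; j++) v[j] /= c;
    ll += std::log(c);
  }
  return -ll;
}
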