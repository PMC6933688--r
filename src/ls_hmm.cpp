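#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for the haploid Li-Stephens copying model on one
// chromosome.
//
// H        : K x M reference haplotype alleles (0/1)
// typedIdx : 0-based column indices of the typed markers (strictly increasing)
// obs      : observed target alleles at the typed markers (0/1, NA = missing)
// s        : per-interval copying-switch probability; stay = (1-s) + s/K,
//            move to each other state = s/K
// e        : emission mismatch probability (match 1-e, mismatch e,
//            missing observation emits 1 for every state)
//
// Returns the state posteriors gamma (T x K, rows normalized) and the
// posterior alternate-allele dosage at every column of H. Untyped columns
// use the left-flank rule: the state posterior at the nearest typed marker
// to the left (the first typed marker for the leftmost interval) weights
// the reference alleles.
// [[Rcpp::export(name = ".lsForwardBackward")]]
List lsForwardBackward(const IntegerMatrix& H, const IntegerVector& typedIdx,
                       const IntegerVector& obs, double s, double e) {
  const int K = H.nrow();
  const int M = H.ncol();
  const int T = typedIdx.size();
  if (K < 2) stop("reference must contain at least 2 haplotypes");

  NumericVector dos(M);
  if (T == 0) {
    // no typed markers on this chromosome: posterior is the copying prior,
    // i.e. the reference allele frequency
    for (int m = 0; m < M; ++m) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += H(k, m);
      dos[m] = tot / K;
    }
    return List::create(_["gamma"] = NumericMatrix(0, K), _["dosage"] = dos);
  }

  // emission matrix, T x K
  NumericMatrix em(T, K);
  for (int t = 0; t < T; ++t) {
    const int m = typedIdx[t];
    if (m < 0 || m >= M) stop("typed index out of range");
    if (IntegerVector::is_na(obs[t])) {
      for (int k = 0; k < K; ++k) em(t, k) = 1.0;
    } else {
      const int o = obs[t];
      if (o != 0 && o != 1) stop("target allele codes must be 0, 1 or NA");
      for (int k = 0; k < K; ++k) em(t, k) = (H(k, m) == o) ? (1.0 - e) : e;
    }
  }

  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);

  // forward (scaled so each row sums to 1)
  double tot = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = em(0, k) / K; tot += alpha(0, k); }
  if (tot <= 0.0) stop("forward underflow at first typed marker");
  for (int k = 0; k < K; ++k) alpha(0, k) /= tot;
  for (int t = 1; t < T; ++t) {
    const double moveMass = s / K; // previous row sums to 1
    tot = 0.0;
    for (int k = 0; k < K; ++k) {
      const double v = em(t, k) * ((1.0 - s) * alpha(t - 1, k) + moveMass);
      alpha(t, k) = v;
      tot += v;
    }
    if (tot <= 0.0) stop("forward underflow");
    for (int k = 0; k < K; ++k) alpha(t, k) /= tot;
  }

  // backward (scaled)
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  std::vector<double> b(K);
  for (int t = T - 2; t >= 0; --t) {
    double bsum = 0.0;
    for (int k = 0; k < K; ++k) {
      b[k] = em(t + 1, k) * beta(t + 1, k);
      bsum += b[k];
    }
    tot = 0.0;
    for (int k = 0; k < K; ++k) {
      const double v = (1.0 - s) * b[k] + (s / K) * bsum;
      beta(t, k) = v;
      tot += v;
    }
    if (tot <= 0.0) stop("backward underflow");
    for (int k = 0; k < K; ++k) beta(t, k) /= tot;
  }

  // posteriors
  for (int t = 0; t < T; ++t) {
    tot = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); tot += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= tot;
  }

  // allele dosage at every marker via the left-flank rule
  int tl = 0;
  for (int m = 0; m < M; ++m) {
    while (tl + 1 < T && typedIdx[tl + 1] <= m) ++tl;
    double d = 0.0;
    for (int k = 0; k < K; ++k) d += gamma(tl, k) * H(k, m);
    dos[m] = d;
  }

  return List::create(_["gamma"] = gamma, _["dosage"] = dos);
}
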