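# Independent oracles: exhaustive path-sum for the copying HMM, Cohen's
# kappa via e1071 for IQS, and a double-loop GRM. These deliberately share
# no code with the implementation they check.

# Exhaustive enumeration over all K^T copying paths of the Li-Stephens
# model. H: K x M reference alleles; typedIdx: 1-based typed columns;
# obs: target alleles at typed markers (0/1/NA). Returns per-typed-site
# state posteriors and the per-marker allele posterior under the
# left-flank interpolation rule.
pathSumPosterior <- function(H, typedIdx, obs, s, e) {
  K <- nrow(H); M <- ncol(H); T <- length(typedIdx)
  emis <- function(t, k) {
    if (is.na(obs[t])) return(1)
    if (H[k, typedIdx[t]] == obs[t]) 1 - e else e
  }
  trans <- function(from, to) if (from == to) (1 - s) + s / K else s / K
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  w <- apply(paths, 1L, function(z) {
    p <- (1 / K) * emis(1L, z[1L])
    if (T > 1L) for (t in 2:T) p <- p * trans(z[t - 1L], z[t]) * emis(t, z[t])
    p
  })
  tot <- sum(w)
  gamma <- matrix(0, T, K)
  for (t in seq_len(T)) for (k in seq_len(K))
    gamma[t, k] <- sum(w[paths[, t] == k]) / tot
  dosage <- numeric(M)
  for (m in seq_len(M)) {
    tl <- max(1L, findInterval(m, typedIdx))
    dosage[m] <- sum(gamma[tl, ] * H[, m])
  }
  list(gamma = gamma, dosage = dosage)
}

# Cohen's kappa from an independent implementation (e1071).
kappaOracle <- function(tab) {
  e1071::classAgreement(tab)$kappa
}

# Brute-force standardized GRM: explicit double loop over sample pairs,
# missing entries mean-imputed (zero contribution).
bruteGRM <- function(calls) {
  p <- colSums(calls, na.rm = TRUE) / (2 * colSums(!is.na(calls)))
  poly <- which(p > 0 & p < 1)
  n <- nrow(calls)
  G <- matrix(0, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0
    for (i in poly) {
      xj <- calls[j, i]; xk <- calls[k, i]
      if (is.na(xj)) xj <- 2 * p[i]
      if (is.na(xk)) xk <- 2 * p[i]
      acc <- acc + (xj - 2 * p[i]) * (xk - 2 * p[i]) / (2 * p[i] * (1 - p[i]))
    }
    G[j, k] <- acc / length(poly)
  }
  G
}

# Random 3x3 contingency table with strictly positive entries (margins
# guaranteed non-degenerate).
randomTable <- function(lambda = 4) {
  matrix(stats::rpois(9, lambda) + 1L, 3, 3)
}
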