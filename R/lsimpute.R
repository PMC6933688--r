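## Desk-scale haplotype-copying imputation engine (Li-Stephens model):
## forward-backward over K copying states on the typed-marker grid, scaled
## recursions, left-flank interpolation at untyped markers.

#' Construct Li-Stephens copying-model parameters
#'
#' @param switchRate per-interval copying-switch probability in (0,1)
#'   (default 0.01).
#' @param emissionError allele mismatch probability in (0,0.5)
#'   (default 0.002).
#' @param maxReferenceHaplotypes cap on reference haplotypes; larger panels
#'   are subsampled with a seed, stratified by breed (default 200).
#' @return a validated \linkS4class{HmmParams}.
#' @export
hmmParams <- function(switchRate = 0.01, emissionError = 0.002,
                      maxReferenceHaplotypes = 200L) {
  new("HmmParams", switchRate = switchRate, emissionError = emissionError,
      maxReferenceHaplotypes = as.integer(maxReferenceHaplotypes))
}

## Seeded, breed-stratified subsampling of reference samples so that at most
## `cap` haplotypes remain; whole samples are kept together and breed
## composition is preserved by largest-remainder apportionment.
.subsampleReference <- function(reference, cap, seed) {
  nHap <- nrow(reference@alleles)
  if (nHap <= cap) return(reference)
  nKeep <- cap %/% 2L
  b <- breedOf(reference)
  set.seed(seed)
  tab <- table(b)
  quota <- nKeep * as.numeric(tab) / length(b)
  take <- floor(quota)
  rem <- nKeep - sum(take)
  if (rem > 0) {
    ord <- order(quota - floor(quota), decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  keep <- character(0)
  for (i in seq_along(tab)) {
    members <- sort(reference@sampleIds[b == names(tab)[i]])
    n <- min(take[i], length(members))
    if (n > 0) keep <- c(keep, sort(sample(members, n)))
  }
  .subsetPanel(reference, samples = reference@sampleIds[reference@sampleIds %in% keep])
}

## Core per-haplotype engine over an already-subsampled reference.
## targetAlleles: named (marker id) integer vector at typed markers.
## Returns list(posterior = numeric over all reference markers,
##              gamma = list of per-chromosome state-posterior matrices).
.imputeHaploidCore <- function(targetAlleles, typedIds, reference, params,
                               wantGamma = FALSE) {
  map <- reference@markerMap
  midx <- match(typedIds, map$id)
  if (anyNA(midx))
    stop("typed marker(s) absent from the reference: ",
         paste(head(typedIds[is.na(midx)], 5), collapse = ", "))
  if (length(typedIds) == 0L) stop("target is typed at zero markers")
  bad <- !(is.na(targetAlleles) | targetAlleles %in% c(0L, 1L))
  if (any(bad)) stop("target allele codes must be 0, 1 or NA")

  post <- numeric(nrow(map))
  gammas <- list()
  for (ch in unique(map$chrom)) {
    cols <- which(map$chrom == ch)
    H <- reference@alleles[, cols, drop = FALSE]
    inCh <- which(midx %in% cols)
    tIdx <- match(midx[inCh], cols)
    ord <- order(tIdx)
    fb <- .lsForwardBackward(H, as.integer(tIdx[ord] - 1L),
                             as.integer(targetAlleles[inCh][ord]),
                             params@switchRate, params@emissionError)
    post[cols] <- fb$dosage
    if (wantGamma) gammas[[ch]] <- fb$gamma
  }
  names(post) <- map$id
  list(posterior = post, gamma = gammas)
}

#' Haploid Li-Stephens imputation of one target haplotype
#'
#' Runs the scaled forward-backward recursion over K copying states on the
#' typed-marker grid of each chromosome (transition: stay with
#' (1-s) + s/K, move to each other state with s/K; emission: 1-e on allele
#' match, e on mismatch, uninformative when the target allele is missing)
#' and interpolates untyped markers with the left-flank rule: the state
#' posterior at the nearest typed marker to the left weights the reference
#' alleles (the leftmost interval uses the first typed marker). A
#' chromosome carrying no typed markers falls back to the copying prior,
#' i.e. the reference allele frequency.
#'
#' @param targetAlleles integer vector of target alleles (0/1, NA missing)
#'   at the typed markers.
#' @param typedIds character, marker ids of the typed markers (must be a
#'   subset of the reference markers).
#' @param reference a \linkS4class{HaplotypePanel} (at least 2 haplotypes).
#' @param params a \linkS4class{HmmParams}.
#' @param seed seed for reference subsampling when the panel exceeds
#'   \code{maxReferenceHaplotypes}.
#' @param details if TRUE, also return the per-chromosome state-posterior
#'   matrices.
#' @return named numeric vector of posterior alternate-allele probabilities
#'   over all reference markers; with \code{details = TRUE}, a list with
#'   \code{posterior} and \code{gamma}.
#' @export
imputeHaploid <- function(targetAlleles, typedIds, reference, params = hmmParams(),
                          seed = 1L, details = FALSE) {
  validObject(params)
  if (nrow(reference@alleles) < 2L) stop("reference must contain at least 2 haplotypes")
  ref <- .subsampleReference(reference, params@maxReferenceHaplotypes, seed)
  res <- .imputeHaploidCore(targetAlleles, typedIds, ref, params,
                            wantGamma = details)
  if (details) res else res$posterior
}

## Best-guess hard call from a diploid dosage: round, ties at x.5 toward the
## heterozygote.
.bestGuessFromDosage <- function(d) {
  bg <- as.integer(floor(d + 0.5))
  tie <- abs(d %% 1 - 0.5) < 1e-12
  bg[tie] <- 1L
  bg[bg > 2L] <- 2L
  bg
}

## Inject phasing switch errors at heterozygous sites: with probability
## `rate` per het, swap the two haplotypes' alleles from that site onward.
.injectSwitchErrors <- function(h1, h2, rate) {
  het <- which(h1 != h2 & !is.na(h1) & !is.na(h2))
  if (!length(het)) return(list(h1 = h1, h2 = h2))
  sw <- rbinom(length(het), 1L, rate)
  parity <- cumsum(sw) %% 2L
  flip <- het[parity == 1L]
  if (length(flip)) {
    tmp <- h1[flip]; h1[flip] <- h2[flip]; h2[flip] <- tmp
  }
  list(h1 = h1, h2 = h2)
}

#' Impute a masked test set against a reference haplotype panel
#'
#' Each test haplotype is threaded through the reference with
#' \code{\link{imputeHaploid}}; the per-sample dosage is the sum of the two
#' haplotype posteriors; the best guess is the rounded dosage with ties at
#' x.5 resolved toward the heterozygote. Observed (assay) markers pass
#' through unchanged with provenance \code{"observed"}.
#'
#' @param test a \linkS4class{MaskedTestSet} with phased haplotypes
#'   attached (see \code{\link{maskToAssay}}).
#' @param reference a \linkS4class{HaplotypePanel} covering the target
#'   marker set; test assay markers must all be present.
#' @param params a \linkS4class{HmmParams}.
#' @param phaseMode "truth-phase" uses the attached simulator phase as-is;
#'   "switch-error" additionally injects Bernoulli switch errors at
#'   heterozygous sites to emulate imperfect statistical phasing.
#' @param switchErrorRate per-het switch probability for switch-error mode
#'   (default 0.02).
#' @param seed integer seed (reference subsampling and switch errors).
#' @return an \linkS4class{ImputationResult} over the reference marker set.
#' @export
imputeSamples <- function(test, reference, params = hmmParams(),
                          phaseMode = c("truth-phase", "switch-error"),
                          switchErrorRate = 0.02, seed = 1L) {
  phaseMode <- match.arg(phaseMode)
  validObject(params)
  if (nrow(test@haplotypes) == 0L)
    stop("test set carries no phased haplotypes; mask with panel= to attach phase")
  typedIds <- colnames(test@observed@calls)
  if (!all(typedIds %in% reference@markerMap$id))
    stop("reference/target marker-map mismatch: ",
         sum(!typedIds %in% reference@markerMap$id),
         " assay marker(s) absent from the reference")
  ref <- .subsampleReference(reference, params@maxReferenceHaplotypes,
                             stageSeed(seed, "reference-subsample"))
  map <- ref@markerMap
  n <- nrow(test@observed@calls)
  samples <- rownames(test@observed@calls)
  M <- nrow(map)
  dos <- matrix(NA_real_, n, M, dimnames = list(samples, map$id))
  set.seed(stageSeed(seed, "switch-error"))
  for (i in seq_len(n)) {
    h1 <- test@haplotypes[2L * i - 1L, ]
    h2 <- test@haplotypes[2L * i, ]
    if (phaseMode == "switch-error") {
      sw <- .injectSwitchErrors(h1, h2, switchErrorRate)
      h1 <- sw$h1; h2 <- sw$h2
    }
    p1 <- .imputeHaploidCore(h1, typedIds, ref, params)$posterior
    p2 <- .imputeHaploidCore(h2, typedIds, ref, params)$posterior
    dos[i, ] <- p1 + p2
  }
  bg <- matrix(.bestGuessFromDosage(dos), n, M, dimnames = dimnames(dos))
  prov <- matrix("imputed", n, M, dimnames = dimnames(dos))
  oidx <- match(typedIds, map$id)
  obs <- test@observed@calls
  ok <- !is.na(obs)
  for (j in seq_along(oidx)) {
    col <- oidx[j]
    rows <- which(ok[, j])
    dos[rows, col] <- obs[rows, j]
    bg[rows, col] <- obs[rows, j]
    prov[rows, col] <- "observed"
  }
  new("ImputationResult", dosage = dos, bestGuess = bg, provenance = prov,
      markerMap = map)
}
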