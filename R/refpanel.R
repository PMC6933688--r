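## Reference-panel construction: within-breed (BR) panels, the reciprocally
## cross-imputed multi-breed composite (CR) panel, and the one-round /
## two-round imputation strategies.

#' Assign reference samples to assay genotyping groups
#'
#' Emulates a reference in which most samples were genotyped on only one of
#' the two research assays: each sample is assigned to "A" (common-variant
#' assay only), "B" (rare-enriched assay only) or "AB" (both). Assignment
#' is seeded and stratified nothing more than proportionally (largest
#' remainder on the shuffled id list).
#'
#' @param sampleIds character vector of reference sample ids.
#' @param fractions named numeric (A, B, AB) summing to 1; the default
#'   mirrors a reference dominated by rare-enriched-assay genotypes with a
#'   small both-assays overlap.
#' @param seed integer seed.
#' @return named character vector, sample id -> group.
#' @export
assignAssayGroups <- function(sampleIds,
                              fractions = c(A = 0.20, B = 0.72, AB = 0.08),
                              seed = 1L) {
  stopifnot(setequal(names(fractions), c("A", "B", "AB")),
            abs(sum(fractions) - 1) < 1e-9)
  n <- length(sampleIds)
  quota <- n * fractions[c("A", "B", "AB")]
  take <- floor(quota)
  rem <- n - sum(take)
  if (rem > 0) {
    ord <- order(quota - floor(quota), decreasing = TRUE)
    take[ord[seq_len(rem)]] <- take[ord[seq_len(rem)]] + 1
  }
  set.seed(seed)
  shuffled <- sample(sort(sampleIds))
  setNames(rep(c("A", "B", "AB"), times = take), shuffled)[sampleIds]
}

#' Pair two assays with grouped reference samples
#'
#' @param reference a \linkS4class{HaplotypePanel} of reference samples.
#' @param assayA the common-variant \linkS4class{AssayDefinition}.
#' @param assayB the rare-enriched \linkS4class{AssayDefinition}.
#' @param groups named character (sample -> "A"/"B"/"AB"), e.g. from
#'   \code{\link{assignAssayGroups}}.
#' @return a \linkS4class{PanelPair}.
#' @export
panelPair <- function(reference, assayA, assayB, groups) {
  new("PanelPair", panel = reference, assayA = assayA, assayB = assayB,
      groups = groups[reference@sampleIds])
}

#' Union marker ids of a panel pair (panel marker order)
#' @param pp a \linkS4class{PanelPair}.
#' @return character vector of marker ids.
#' @export
unionMarkers <- function(pp) {
  u <- union(pp@assayA@markerIds, pp@assayB@markerIds)
  pp@panel@markerMap$id[pp@panel@markerMap$id %in% u]
}

#' Restrict a reference panel to one breed
#'
#' Samples carrying the breed label are kept, together with admixed samples
#' whose recorded ancestry proportion for that breed reaches
#' \code{minAncestry} -- within-breed panels of open-herdbook populations
#' are assembled from registry labels and therefore contain the breed's
#' admixed members.
#'
#' @param reference a \linkS4class{HaplotypePanel}.
#' @param breed breed label; must be present among the reference samples.
#' @param minAncestry ancestry proportion at which an admixed sample counts
#'   as a breed member (default 0.5; set above 1 to exclude admixed samples
#'   entirely).
#' @return the within-breed \linkS4class{HaplotypePanel}.
#' @export
buildBreedPanel <- function(reference, breed, minAncestry = 0.5) {
  b <- breedOf(reference)
  keep <- reference@sampleIds[b == breed]
  adm <- reference@admixture
  if (nrow(adm)) {
    members <- adm$sample[adm$breed == breed & adm$proportion >= minAncestry]
    keep <- union(keep, intersect(reference@sampleIds, members))
    keep <- reference@sampleIds[reference@sampleIds %in% keep]
  }
  if (!length(keep)) stop("breed '", breed, "' absent from the reference panel")
  out <- .subsetPanel(reference, samples = keep)
  prov <- provenance(reference)
  if (!is.null(prov))
    out@metadata$provenance <- prov[.hapRows(reference, keep), , drop = FALSE]
  out
}

## Hard-call a posterior allele probability: > 0.5 -> 1, < 0.5 -> 0, exactly
## 0.5 -> the panel major allele at that marker.
.hardCallAlleles <- function(post, majorAllele) {
  out <- as.integer(post > 0.5)
  tie <- abs(post - 0.5) < 1e-12
  out[tie] <- majorAllele[tie]
  out
}

#' Build the one-round composite reference panel by reciprocal cross-imputation
#'
#' Samples genotyped only on assay A are imputed at B-exclusive markers
#' using the B-genotyped samples (B-only plus overlap) as reference, and
#' vice versa; the shared A-and-B marker block bridges the two assays. The
#' result is a complete phased panel over the union marker set whose
#' entries are flagged \code{"observed"} or \code{"cross-imputed"} in
#' \code{metadata$provenance}. Cross-imputed posteriors are hard-called to
#' alleles (ties at 0.5 go to the panel major allele) because the copying
#' model consumes discrete reference alleles.
#'
#' @param pp a \linkS4class{PanelPair}; the overlap ("AB") group must be
#'   nonempty.
#' @param params a \linkS4class{HmmParams}.
#' @param seed integer seed (reference subsampling).
#' @return a \linkS4class{HaplotypePanel} over the union marker set.
#' @export
buildCompositeOneRound <- function(pp, params = hmmParams(), seed = 1L) {
  validObject(pp)
  if (!any(pp@groups == "AB"))
    stop("empty overlap: at least one sample genotyped on both assays is ",
         "required to bridge the two marker sets")
  u <- unionMarkers(pp)
  panel <- .subsetPanel(pp@panel, markers = u)
  aIds <- pp@assayA@markerIds
  bIds <- pp@assayB@markerIds
  shared <- intersect(aIds, bIds)
  if (!length(shared))
    stop("assays share no markers; the shared block is required for ",
         "cross-imputation targets")
  aExcl <- setdiff(aIds, bIds)
  bExcl <- setdiff(bIds, aIds)
  samplesA <- names(pp@groups)[pp@groups == "A"]
  samplesB <- names(pp@groups)[pp@groups == "B"]
  samplesAB <- names(pp@groups)[pp@groups == "AB"]

  al <- panel@alleles
  prov <- matrix("observed", nrow(al), ncol(al), dimnames = dimnames(al))
  mIdx <- setNames(seq_along(panel@markerMap$id), panel@markerMap$id)

  crossImpute <- function(targets, donors, donorMarkers, fillMarkers) {
    if (!length(targets) || !length(fillMarkers)) return()
    donorPanel <- .subsetPanel(pp@panel,
                               samples = donors, markers = donorMarkers)
    donorPanel <- .subsampleReference(donorPanel,
                                      params@maxReferenceHaplotypes,
                                      stageSeed(seed, "cross-impute"))
    major <- as.integer(colMeans(donorPanel@alleles) > 0.5)
    names(major) <- donorPanel@markerMap$id
    fillIdx <- mIdx[fillMarkers]
    for (smp in targets) {
      rows <- .hapRows(panel, smp)
      for (r in rows) {
        typed <- al[r, mIdx[shared]]
        post <- .imputeHaploidCore(typed, shared, donorPanel, params)$posterior
        al[r, fillIdx] <<- .hardCallAlleles(post[fillMarkers],
                                            major[fillMarkers])
        prov[r, fillIdx] <<- "cross-imputed"
      }
    }
  }

  ## A-only samples: impute B-exclusive markers from B-genotyped samples
  crossImpute(samplesA, c(samplesB, samplesAB), bIds, bExcl)
  ## B-only samples: impute A-exclusive markers from A-genotyped samples
  crossImpute(samplesB, c(samplesA, samplesAB), aIds, aExcl)

  panel@alleles <- al
  panel@metadata <- list(provenance = prov, groups = pp@groups)
  panel
}

## Per-haplotype two-step imputation used by runTwoRound.
.twoRoundHaplotype <- function(h, typedIds, refA, refB, params,
                               shared, aIds, bExcl) {
  stepA <- .imputeHaploidCore(h, typedIds, refA, params)$posterior
  majorB <- as.integer(colMeans(refB@alleles) > 0.5)
  names(majorB) <- refB@markerMap$id
  typedShared <- .hardCallAlleles(stepA[shared], majorB[shared])
  stepB <- .imputeHaploidCore(typedShared, shared, refB, params)$posterior
  list(a = stepA[aIds], b = stepB[bExcl])
}

#' Two-round imputation: test -> assay A density -> union density
#'
#' Step 1 imputes each test haplotype to the full A marker set against the
#' A-genotyped reference only; step 2 imputes the B-exclusive markers
#' against the B-genotyped reference, using the hard-called step-1 output
#' at the shared A-and-B markers as typed input. Only observed genotypes
#' ever serve as reference. The merged result covers the union marker set.
#'
#' @param test a \linkS4class{MaskedTestSet}; its assay markers must all
#'   lie on assay A.
#' @param pp a \linkS4class{PanelPair}.
#' @param params a \linkS4class{HmmParams}.
#' @param phaseMode,switchErrorRate as in \code{\link{imputeSamples}}.
#' @param seed integer seed.
#' @return an \linkS4class{ImputationResult} over the union marker set.
#' @export
runTwoRound <- function(test, pp, params = hmmParams(),
                        phaseMode = c("truth-phase", "switch-error"),
                        switchErrorRate = 0.02, seed = 1L) {
  phaseMode <- match.arg(phaseMode)
  validObject(pp)
  typedIds <- colnames(test@observed@calls)
  if (!all(typedIds %in% pp@assayA@markerIds))
    stop("test assay markers must be a subset of assay A")
  if (nrow(test@haplotypes) == 0L)
    stop("test set carries no phased haplotypes; mask with panel= to attach phase")
  aIds <- pp@assayA@markerIds
  bIds <- pp@assayB@markerIds
  shared <- intersect(aIds, bIds)
  bExcl <- setdiff(bIds, aIds)
  samplesA <- names(pp@groups)[pp@groups %in% c("A", "AB")]
  samplesB <- names(pp@groups)[pp@groups %in% c("B", "AB")]
  refA <- .subsampleReference(
    .subsetPanel(pp@panel, samples = samplesA, markers = aIds),
    params@maxReferenceHaplotypes, stageSeed(seed, "two-round-A"))
  if (length(bExcl)) {
    refB <- .subsampleReference(
      .subsetPanel(pp@panel, samples = samplesB, markers = bIds),
      params@maxReferenceHaplotypes, stageSeed(seed, "two-round-B"))
  } else refB <- NULL

  u <- unionMarkers(pp)
  umap <- pp@panel@markerMap[pp@panel@markerMap$id %in% u, , drop = FALSE]
  rownames(umap) <- NULL
  n <- nrow(test@observed@calls)
  samples <- rownames(test@observed@calls)
  dos <- matrix(NA_real_, n, nrow(umap), dimnames = list(samples, umap$id))
  set.seed(stageSeed(seed, "switch-error"))
  for (i in seq_len(n)) {
    h1 <- test@haplotypes[2L * i - 1L, ]
    h2 <- test@haplotypes[2L * i, ]
    if (phaseMode == "switch-error") {
      sw <- .injectSwitchErrors(h1, h2, switchErrorRate)
      h1 <- sw$h1; h2 <- sw$h2
    }
    d <- numeric(nrow(umap)); names(d) <- umap$id
    for (h in list(h1, h2)) {
      if (is.null(refB)) {
        step <- .imputeHaploidCore(h, typedIds, refA, params)$posterior
        d[aIds] <- d[aIds] + step[aIds]
      } else {
        hp <- .twoRoundHaplotype(h, typedIds, refA, refB, params,
                                 shared, aIds, bExcl)
        d[aIds] <- d[aIds] + hp$a
        d[bExcl] <- d[bExcl] + hp$b
      }
    }
    dos[i, ] <- d
  }
  bg <- matrix(.bestGuessFromDosage(dos), n, nrow(umap),
               dimnames = dimnames(dos))
  prov <- matrix("imputed", n, nrow(umap), dimnames = dimnames(dos))
  obs <- test@observed@calls
  oidx <- match(typedIds, umap$id)
  for (j in seq_along(oidx)) {
    rows <- which(!is.na(obs[, j]))
    dos[rows, oidx[j]] <- obs[rows, j]
    bg[rows, oidx[j]] <- obs[rows, j]
    prov[rows, oidx[j]] <- "observed"
  }
  new("ImputationResult", dosage = dos, bestGuess = bg, provenance = prov,
      markerMap = umap)
}

#' One-round imputation against a completed composite panel
#'
#' A single \code{\link{imputeSamples}} pass against the (cross-imputed)
#' composite reference covering the union marker set.
#'
#' @param test a \linkS4class{MaskedTestSet}.
#' @param composite a \linkS4class{HaplotypePanel} over the union marker
#'   set, e.g. from \code{\link{buildCompositeOneRound}} or
#'   \code{\link{buildBreedPanel}}.
#' @param params a \linkS4class{HmmParams}.
#' @param phaseMode,switchErrorRate,seed as in \code{\link{imputeSamples}}.
#' @return an \linkS4class{ImputationResult}.
#' @export
runOneRound <- function(test, composite, params = hmmParams(),
                        phaseMode = c("truth-phase", "switch-error"),
                        switchErrorRate = 0.02, seed = 1L) {
  imputeSamples(test, composite, params, phaseMode = phaseMode,
                switchErrorRate = switchErrorRate, seed = seed)
}

#' Write a composite panel's provenance sidecar
#'
#' Tab-separated (marker, sample, haplotype, flag) rows for every
#' cross-imputed entry, for auditability of one-round reference panels.
#'
#' @param composite a composite \linkS4class{HaplotypePanel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeProvenance <- function(composite, path) {
  prov <- provenance(composite)
  if (is.null(prov)) stop("panel carries no provenance metadata")
  ij <- which(prov == "cross-imputed", arr.ind = TRUE)
  df <- data.frame(marker = colnames(prov)[ij[, 2]],
                   haplotype = rownames(prov)[ij[, 1]],
                   flag = "cross-imputed", stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
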