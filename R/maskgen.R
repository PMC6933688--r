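## Test-set construction: breed-balanced sampling and assay masking.

#' Split samples into test and reference sets with per-breed caps
#'
#' Per breed, \code{min(maxPerBreed, floor(maxBreedFraction * breedSize))}
#' individuals are drawn uniformly at random into the test set; the
#' remainder become reference. Ids are sorted lexicographically before
#' drawing, so the split is invariant to input order and reproducible given
#' the seed. A breed of one individual contributes no test individuals (the
#' floor never empties a breed).
#'
#' @param g a \linkS4class{GenotypeMatrix} (or anything with sample ids via
#'   \code{sampleIds}).
#' @param breedOf named character, sample id -> breed.
#' @param maxPerBreed cap on test individuals per breed (default 50).
#' @param maxBreedFraction maximum fraction of a breed removed for testing
#'   (default 0.5).
#' @param seed integer seed.
#' @param eligible optional character vector of ids eligible for testing
#'   (e.g. samples with complete truth genotypes on both research assays);
#'   default: all samples.
#' @return list with character vectors \code{test} and \code{reference}.
#' @export
selectTestIndividuals <- function(g, breedOf, maxPerBreed = 50L,
                                  maxBreedFraction = 0.5, seed = 1L,
                                  eligible = NULL) {
  ids <- sort(sampleIds(g))
  if (!all(ids %in% names(breedOf))) stop("every sample needs a breed label")
  if (is.null(eligible)) eligible <- ids
  breeds <- sort(unique(breedOf[ids]))
  if (length(breeds) == 0L) stop("no breeds present")
  set.seed(seed)
  test <- character(0)
  for (b in breeds) {
    members <- ids[breedOf[ids] == b]
    pool <- intersect(members, eligible)
    n <- min(maxPerBreed, floor(maxBreedFraction * length(members)),
             length(pool))
    if (n > 0) test <- c(test, sort(sample(pool, n)))
  }
  list(test = test, reference = setdiff(ids, test))
}

#' Mask a genotype matrix down to one assay, retaining withheld truth
#'
#' The observed matrix is the input restricted to the assay markers; the
#' truth matrix is the full input; no genotype values are altered. When the
#' source \linkS4class{HaplotypePanel} is supplied, phased haplotypes at the
#' observed markers are attached, reconciled with the (possibly
#' error-containing) observed calls: where a call disagrees with the
#' simulator truth, a homozygous call sets both alleles and a heterozygous
#' call flips the second haplotype's allele.
#'
#' @param g a \linkS4class{GenotypeMatrix} for the test samples.
#' @param assay an \linkS4class{AssayDefinition}; markers must all be
#'   present in \code{g}.
#' @param panel optional \linkS4class{HaplotypePanel} providing simulator
#'   phase for the test samples.
#' @return a \linkS4class{MaskedTestSet}.
#' @export
maskToAssay <- function(g, assay, panel = NULL) {
  miss <- setdiff(assay@markerIds, colnames(g@calls))
  if (length(miss))
    stop("assay marker(s) absent from genotypes: ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (and %d more)", length(miss) - 5))
  midx <- match(assay@markerIds, colnames(g@calls))
  obsMap <- g@markerMap[midx, , drop = FALSE]
  rownames(obsMap) <- NULL
  obs <- .newGenotypeMatrix(g@calls[, midx, drop = FALSE], obsMap,
                            phased = g@phased)
  withheld <- setdiff(colnames(g@calls), assay@markerIds)

  haps <- matrix(integer(0), nrow = 0, ncol = 0)
  if (!is.null(panel)) {
    sub <- .subsetPanel(panel, samples = rownames(g@calls),
                        markers = assay@markerIds)
    haps <- sub@alleles
    n <- nrow(obs@calls)
    h1 <- seq(1L, 2L * n, 2L); h2 <- seq(2L, 2L * n, 2L)
    truthG <- haps[h1, , drop = FALSE] + haps[h2, , drop = FALSE]
    oc <- obs@calls
    ## reconcile phase with the observed (possibly errored) calls
    hom <- !is.na(oc) & oc != truthG & oc != 1L
    if (any(hom)) {
      a <- matrix(0L, n, ncol(oc)); a[hom] <- oc[hom] %/% 2L
      m1 <- haps[h1, , drop = FALSE]; m2 <- haps[h2, , drop = FALSE]
      m1[hom] <- a[hom]; m2[hom] <- a[hom]
      haps[h1, ] <- m1; haps[h2, ] <- m2
    }
    het <- !is.na(oc) & oc == 1L &
           (haps[h1, , drop = FALSE] + haps[h2, , drop = FALSE]) != 1L
    if (any(het)) {
      m1 <- haps[h1, , drop = FALSE]; m2 <- haps[h2, , drop = FALSE]
      m2[het] <- 1L - m1[het]
      haps[h2, ] <- m2
    }
  }
  new("MaskedTestSet", observed = obs, truth = g, assay = assay,
      withheldMarkerIds = withheld, haplotypes = haps)
}

#' Write test/reference id lists as plain text
#' @param split the list returned by \code{\link{selectTestIndividuals}}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeSampleSplit <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(split$test, file.path(dir, "test_ids.txt"))
  writeLines(split$reference, file.path(dir, "reference_ids.txt"))
  invisible(dir)
}
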