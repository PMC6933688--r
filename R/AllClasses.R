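#' @import methods
#' @importFrom stats rbinom runif rbeta setNames var sd cor pt pf
#' @importFrom utils write.table read.table head tail
#' @useDynLib ImputeEval, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## Marker map contract used by several classes: a data.frame with columns
##   chrom (character), pos (integer, 1-based), id (character, unique),
##   ref (character), alt (character)
## Positions must be strictly increasing within each chromosome.
## ---------------------------------------------------------------------------

.checkMarkerMap <- function(map) {
  msgs <- character()
  need <- c("chrom", "pos", "id", "ref", "alt")
  if (!is.data.frame(map) || !all(need %in% names(map))) {
    return(sprintf("markerMap must be a data.frame with columns %s",
                   paste(need, collapse = ", ")))
  }
  if (anyDuplicated(map$id)) msgs <- c(msgs, "marker ids must be unique")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0)) {
      msgs <- c(msgs, sprintf("positions not strictly increasing on chromosome %s", ch))
      break
    }
  }
  msgs
}

#' Simulation configuration for multi-breed haplotype panels
#'
#' Holds every parameter of the synthetic-panel generator: per-chromosome
#' marker counts, breed composition (reference haplotypes, test individuals,
#' and per-breed Fst under the Balding-Nichols model), the founder-mosaic
#' linkage-disequilibrium model, admixed samples, the ancestral site-frequency
#' spectrum, the per-genotype error rate, and the random seed.
#'
#' @slot nMarkers integer, biallelic sites per chromosome.
#' @slot nChromosomes integer, number of autosomes to simulate.
#' @slot breeds data.frame with columns \code{name}, \code{nRefHaplotypes}
#'   (even), \code{nTestIndividuals}, \code{fst} (in (0,1)).
#' @slot nFoundersPerBreed integer, founder haplotypes per breed (>= 2).
#' @slot mosaicSwitchRate numeric in (0,1), per-marker founder-switch
#'   probability; smaller values give longer shared haplotype segments
#'   (stronger LD).
#' @slot founderWeightRatio numeric in (0,1], geometric ratio of founder
#'   copying weights (1 = equal).
#' @slot migrationRate numeric in [0, 0.5), per-segment probability of
#'   copying a uniformly chosen breed's founder instead of the own breed's.
#' @slot admixedSamples data.frame with columns \code{name} and one numeric
#'   column per breed giving ancestry proportions (rows sum to 1), or a
#'   zero-row data.frame for none.
#' @slot sfsBounds numeric length 2, support of the 1/x-shaped ancestral
#'   allele-frequency density.
#' @slot genotypeErrorRate numeric in [0, 0.05], per-genotype call error.
#' @slot seed integer random seed.
#' @export
setClass("SimConfig",
  slots = c(
    nMarkers = "integer",
    nChromosomes = "integer",
    breeds = "data.frame",
    nFoundersPerBreed = "integer",
    mosaicSwitchRate = "numeric",
    founderWeightRatio = "numeric",
    migrationRate = "numeric",
    admixedSamples = "data.frame",
    sfsBounds = "numeric",
    genotypeErrorRate = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nMarkers < 1L) msgs <- c(msgs, "nMarkers must be positive")
  if (object@nChromosomes < 1L) msgs <- c(msgs, "nChromosomes must be positive")
  b <- object@breeds
  if (!all(c("name", "nRefHaplotypes", "nTestIndividuals", "fst") %in% names(b)))
    msgs <- c(msgs, "breeds needs columns name, nRefHaplotypes, nTestIndividuals, fst")
  else {
    if (any(b$nRefHaplotypes %% 2 != 0)) msgs <- c(msgs, "nRefHaplotypes must be even")
    if (any(b$nRefHaplotypes < 2)) msgs <- c(msgs, "each breed needs at least 2 reference haplotypes")
    if (any(b$nTestIndividuals < 0)) msgs <- c(msgs, "nTestIndividuals must be non-negative")
    if (any(b$fst <= 0 | b$fst >= 1)) msgs <- c(msgs, "fst must lie in (0,1)")
    if (anyDuplicated(b$name)) msgs <- c(msgs, "breed names must be unique")
  }
  if (object@nFoundersPerBreed < 2L) msgs <- c(msgs, "need at least 2 founders per breed")
  if (object@mosaicSwitchRate <= 0 || object@mosaicSwitchRate >= 1)
    msgs <- c(msgs, "mosaicSwitchRate must lie in (0,1)")
  if (object@founderWeightRatio <= 0 || object@founderWeightRatio > 1)
    msgs <- c(msgs, "founderWeightRatio must lie in (0,1]")
  if (object@migrationRate < 0 || object@migrationRate >= 0.5)
    msgs <- c(msgs, "migrationRate must lie in [0, 0.5)")
  if (object@genotypeErrorRate < 0 || object@genotypeErrorRate > 0.05)
    msgs <- c(msgs, "genotypeErrorRate must lie in [0, 0.05]")
  a <- object@admixedSamples
  if (nrow(a) > 0) {
    pcols <- setdiff(names(a), "name")
    if (!all(pcols %in% b$name))
      msgs <- c(msgs, "admixedSamples proportion columns must be breed names")
    else {
      s <- rowSums(as.matrix(a[, pcols, drop = FALSE]))
      if (any(abs(s - 1) > 1e-9))
        msgs <- c(msgs, "admixture proportions must sum to 1 (tolerance 1e-9)")
    }
  }
  if (length(object@sfsBounds) != 2 || object@sfsBounds[1] <= 0 ||
      object@sfsBounds[2] >= 1 || object@sfsBounds[1] >= object@sfsBounds[2])
    msgs <- c(msgs, "sfsBounds must be an increasing pair inside (0,1)")
  if (length(msgs)) msgs else TRUE
})

#' Phased multi-breed haplotype panel
#'
#' A haplotype-by-marker 0/1 allele matrix with its marker map, sample and
#' breed labels, and (for simulated panels) the generation-truth allele
#' frequencies. Haplotypes \code{2i-1} and \code{2i} belong to sample
#' \code{i}; the row order is phase-consistent.
#'
#' @slot alleles integer matrix (haplotypes x markers) of 0/1.
#' @slot markerMap data.frame (chrom, pos, id, ref, alt).
#' @slot sampleIds character, one per individual (half the haplotype count).
#' @slot breedOf named character, sample id -> breed label.
#' @slot founderFreqs numeric matrix (breeds x markers) of realized founder
#'   allele frequencies, or 0-row matrix when unknown.
#' @slot breedFreqs numeric matrix (breeds x markers) of Balding-Nichols
#'   breed frequencies, or 0-row matrix when unknown.
#' @slot ancestralFreqs numeric, per-marker ancestral frequency (may be empty).
#' @slot admixture data.frame of admixed-sample ancestry proportions (long
#'   format: sample, breed, proportion), possibly 0-row.
#' @slot metadata list of free-form annotations (e.g. cross-imputation
#'   provenance for composite panels).
#' @export
setClass("HaplotypePanel",
  slots = c(
    alleles = "matrix",
    markerMap = "data.frame",
    sampleIds = "character",
    breedOf = "character",
    founderFreqs = "matrix",
    breedFreqs = "matrix",
    ancestralFreqs = "numeric",
    admixture = "data.frame",
    metadata = "list"
  )
)

setValidity("HaplotypePanel", function(object) {
  msgs <- .checkMarkerMap(object@markerMap)
  al <- object@alleles
  if (nrow(al) %% 2 != 0) msgs <- c(msgs, "haplotype count must be even")
  if (nrow(al) != 2L * length(object@sampleIds))
    msgs <- c(msgs, "haplotype rows must be 2 x number of samples")
  if (ncol(al) != nrow(object@markerMap))
    msgs <- c(msgs, "allele columns must match marker map rows")
  if (!all(al %in% c(0L, 1L)))
    msgs <- c(msgs, "alleles must contain only 0/1 (no missing in phased truth)")
  if (anyDuplicated(object@sampleIds)) msgs <- c(msgs, "sample ids must be unique")
  if (!all(object@sampleIds %in% names(object@breedOf)))
    msgs <- c(msgs, "every sample needs a breed label")
  if (length(msgs)) msgs else TRUE
})

#' Assay definition: a named ordered marker subset
#'
#' Emulates a commercial genotyping chip as an ordered subset of panel
#' markers, with the selection rule and (for nested assays) the parent assay
#' recorded.
#'
#' @slot name character scalar.
#' @slot markerIds character, ordered marker ids on the assay.
#' @slot rule character, one of \code{"common-evenly-spaced"},
#'   \code{"rare-enriched"}, \code{"nested-subset-of"}, \code{"manual"}.
#' @slot parent character, parent assay name for nested assays
#'   (\code{NA} otherwise).
#' @export
setClass("AssayDefinition",
  slots = c(name = "character", markerIds = "character",
            rule = "character", parent = "character")
)

setValidity("AssayDefinition", function(object) {
  msgs <- character()
  if (length(object@name) != 1L) msgs <- c(msgs, "name must be a scalar")
  if (anyDuplicated(object@markerIds)) msgs <- c(msgs, "assay marker ids must be unique")
  if (length(object@markerIds) < 1L) msgs <- c(msgs, "assay must contain at least one marker")
  if (length(msgs)) msgs else TRUE
})

#' Unphased genotype matrix (alternate-allele counts)
#'
#' Samples by markers, entries in \{0,1,2\} with \code{NA} for missing calls.
#' Alternate-allele orientation follows the marker map's ref/alt columns.
#'
#' @slot calls integer matrix (samples x markers), values 0/1/2/NA, with
#'   sample ids as rownames and marker ids as colnames.
#' @slot markerMap data.frame (chrom, pos, id, ref, alt).
#' @slot phased logical scalar; TRUE when the source records phase for all
#'   genotypes (VCF "|" separators).
#' @slot metadata list (e.g. injected-error positions from the simulator).
#' @export
setClass("GenotypeMatrix",
  slots = c(calls = "matrix", markerMap = "data.frame",
            phased = "logical", metadata = "list")
)

setValidity("GenotypeMatrix", function(object) {
  msgs <- .checkMarkerMap(object@markerMap)
  cl <- object@calls
  if (is.null(rownames(cl))) msgs <- c(msgs, "calls must have sample ids as rownames")
  else if (anyDuplicated(rownames(cl))) msgs <- c(msgs, "sample ids must be unique")
  if (ncol(cl) != nrow(object@markerMap))
    msgs <- c(msgs, "call columns must match marker map rows")
  if (!identical(colnames(cl), object@markerMap$id))
    msgs <- c(msgs, "call colnames must equal marker map ids (same order)")
  v <- cl[!is.na(cl)]
  if (length(v) && !all(v %in% c(0L, 1L, 2L)))
    msgs <- c(msgs, "calls must lie in {0,1,2,NA}")
  if (length(msgs)) msgs else TRUE
})

#' Masked test set: observed assay genotypes plus withheld truth
#'
#' @slot observed GenotypeMatrix restricted to assay markers.
#' @slot truth GenotypeMatrix at the full marker set (same samples, same
#'   order).
#' @slot assay AssayDefinition used for masking.
#' @slot withheldMarkerIds character, truth markers not on the assay.
#' @slot haplotypes integer matrix (2 x samples rows) of phased alleles at
#'   the observed markers (simulator phase reconciled with the observed,
#'   possibly error-containing, genotype calls), or a 0-row matrix when
#'   phase is unavailable.
#' @export
setClass("MaskedTestSet",
  slots = c(observed = "GenotypeMatrix", truth = "GenotypeMatrix",
            assay = "AssayDefinition", withheldMarkerIds = "character",
            haplotypes = "matrix")
)

setValidity("MaskedTestSet", function(object) {
  msgs <- character()
  obs <- object@observed; tr <- object@truth
  if (!all(colnames(obs@calls) %in% colnames(tr@calls)))
    msgs <- c(msgs, "observed markers must be a subset of truth markers")
  if (!identical(rownames(obs@calls), rownames(tr@calls)))
    msgs <- c(msgs, "observed and truth must hold the same samples in the same order")
  wh <- setdiff(colnames(tr@calls), object@assay@markerIds)
  if (!identical(sort(object@withheldMarkerIds), sort(wh)))
    msgs <- c(msgs, "withheld markers must equal truth markers minus assay markers")
  if (nrow(object@haplotypes) > 0) {
    if (nrow(object@haplotypes) != 2L * nrow(obs@calls))
      msgs <- c(msgs, "haplotypes must have two rows per sample")
    if (ncol(object@haplotypes) != ncol(obs@calls))
      msgs <- c(msgs, "haplotypes must cover exactly the observed markers")
  }
  if (length(msgs)) msgs else TRUE
})

#' Li-Stephens copying-model parameters
#'
#' @slot switchRate numeric in (0,1), per-marker-interval probability of
#'   switching the copied reference haplotype (recombination analog).
#' @slot emissionError numeric in (0,0.5), allele mismatch probability
#'   (mutation/genotyping analog).
#' @slot maxReferenceHaplotypes integer, cap on the number of reference
#'   haplotypes used; larger panels are subsampled (seeded, stratified by
#'   breed, whole samples kept together).
#' @export
setClass("HmmParams",
  slots = c(switchRate = "numeric", emissionError = "numeric",
            maxReferenceHaplotypes = "integer")
)

setValidity("HmmParams", function(object) {
  msgs <- character()
  if (object@switchRate <= 0 || object@switchRate >= 1)
    msgs <- c(msgs, "switchRate must lie in (0,1)")
  if (object@emissionError <= 0 || object@emissionError >= 0.5)
    msgs <- c(msgs, "emissionError must lie in (0,0.5)")
  if (object@maxReferenceHaplotypes < 2L)
    msgs <- c(msgs, "maxReferenceHaplotypes must be at least 2")
  if (length(msgs)) msgs else TRUE
})

#' Imputation result: dosages, best-guess genotypes, provenance
#'
#' @slot dosage numeric matrix (samples x markers), expected alternate-allele
#'   count in [0,2].
#' @slot bestGuess integer matrix, 0/1/2 hard calls (ties at x.5 resolved
#'   toward the heterozygote).
#' @slot provenance character matrix, "observed" or "imputed" per entry.
#' @slot markerMap data.frame (chrom, pos, id, ref, alt).
#' @export
setClass("ImputationResult",
  slots = c(dosage = "matrix", bestGuess = "matrix",
            provenance = "matrix", markerMap = "data.frame")
)

setValidity("ImputationResult", function(object) {
  msgs <- .checkMarkerMap(object@markerMap)
  d <- object@dosage
  if (!identical(dim(d), dim(object@bestGuess)) ||
      !identical(dim(d), dim(object@provenance)))
    msgs <- c(msgs, "dosage, bestGuess and provenance must share dimensions")
  if (ncol(d) != nrow(object@markerMap))
    msgs <- c(msgs, "columns must match marker map rows")
  if (any(d < -1e-9 | d > 2 + 1e-9, na.rm = TRUE))
    msgs <- c(msgs, "dosage must lie in [0,2]")
  if (any(abs(d - object@bestGuess) > 1 + 1e-9, na.rm = TRUE))
    msgs <- c(msgs, "|dosage - bestGuess| must not exceed 1")
  if (!all(object@provenance %in% c("observed", "imputed")))
    msgs <- c(msgs, "provenance entries must be 'observed' or 'imputed'")
  if (length(msgs)) msgs else TRUE
})

#' Paired-assay reference panel for composite construction
#'
#' Reference samples split into three genotyping groups: assay A only
#' (common-variant chip), assay B only (rare-enriched chip), and the overlap
#' genotyped on both. The phased truth panel is retained; each group's
#' observed markers are those of its assay(s).
#'
#' @slot panel HaplotypePanel over (at least) the union marker set.
#' @slot assayA AssayDefinition (common-variant assay).
#' @slot assayB AssayDefinition (rare-enriched assay).
#' @slot groups named character, sample id -> "A", "B" or "AB".
#' @export
setClass("PanelPair",
  slots = c(panel = "HaplotypePanel", assayA = "AssayDefinition",
            assayB = "AssayDefinition", groups = "character")
)

setValidity("PanelPair", function(object) {
  msgs <- character()
  ids <- object@panel@sampleIds
  if (!setequal(names(object@groups), ids))
    msgs <- c(msgs, "groups must label exactly the panel samples")
  if (!all(object@groups %in% c("A", "B", "AB")))
    msgs <- c(msgs, "groups must be 'A', 'B' or 'AB'")
  mk <- object@panel@markerMap$id
  if (!all(object@assayA@markerIds %in% mk) || !all(object@assayB@markerIds %in% mk))
    msgs <- c(msgs, "assay markers must be present in the panel")
  if (length(msgs)) msgs else TRUE
})

#' Standardized genomic relationship matrix
#'
#' @slot values numeric symmetric matrix (samples x samples).
#' @slot sampleIds character.
#' @slot nMarkersUsed integer, polymorphic markers entering the sum.
#' @slot freqs numeric, per-marker allele frequencies used.
#' @export
setClass("GRMatrix",
  slots = c(values = "matrix", sampleIds = "character",
            nMarkersUsed = "integer", freqs = "numeric")
)

setValidity("GRMatrix", function(object) {
  msgs <- character()
  v <- object@values
  if (nrow(v) != ncol(v)) msgs <- c(msgs, "GRM must be square")
  if (nrow(v) != length(object@sampleIds))
    msgs <- c(msgs, "GRM dimension must match sample ids")
  if (max(abs(v - t(v))) > 1e-10) msgs <- c(msgs, "GRM must be symmetric (1e-10)")
  if (any(object@freqs <= 0 | object@freqs >= 1))
    msgs <- c(msgs, "GRM frequencies must be strictly inside (0,1)")
  if (length(msgs)) msgs else TRUE
})

#' End-to-end experiment configuration
#'
#' Bundles the simulation configuration, assay specifications, masking
#' parameters, HMM parameters, strategy list and global seed for
#' \code{\link{runExperiment}}.
#'
#' @slot sim SimConfig.
#' @slot assaySpec data.frame with columns \code{name}, \code{count},
#'   \code{rule}, \code{parent}, \code{overlap} (shared-block size for the
#'   rare-enriched assay; NA elsewhere).
#' @slot masking list with \code{maxPerBreed} and \code{maxBreedFraction}.
#' @slot hmm HmmParams.
#' @slot phaseMode character, "truth-phase" or "switch-error".
#' @slot switchErrorRate numeric, per-het switch probability in
#'   switch-error mode.
#' @slot strategies character subset of \code{c("one-round:CR",
#'   "one-round:BR", "two-round:CR")}.
#' @slot groupFractions named numeric (A, B, AB) reference genotyping-group
#'   fractions, summing to 1.
#' @slot maskAssay character, assay used for the panel/strategy comparisons.
#' @slot densityAssays character, nested assays for the density sweep
#'   (may be empty).
#' @slot brBreed character, breed for the within-breed (BR) panel.
#' @slot seed integer global seed (expanded into per-stage seeds).
#' @export
setClass("ExperimentConfig",
  slots = c(sim = "SimConfig", assaySpec = "data.frame", masking = "list",
            hmm = "HmmParams", phaseMode = "character",
            switchErrorRate = "numeric", strategies = "character",
            groupFractions = "numeric", maskAssay = "character",
            densityAssays = "character", brBreed = "character",
            seed = "integer")
)

setValidity("ExperimentConfig", function(object) {
  msgs <- character()
  if (length(object@strategies) < 1L) msgs <- c(msgs, "need at least one strategy")
  bad <- setdiff(object@strategies, c("one-round:CR", "one-round:BR", "two-round:CR"))
  if (length(bad)) msgs <- c(msgs, paste("unknown strategies:", paste(bad, collapse = ", ")))
  if (!setequal(names(object@groupFractions), c("A", "B", "AB")) ||
      abs(sum(object@groupFractions) - 1) > 1e-9)
    msgs <- c(msgs, "groupFractions must be named A/B/AB and sum to 1")
  if (!object@phaseMode %in% c("truth-phase", "switch-error"))
    msgs <- c(msgs, "phaseMode must be 'truth-phase' or 'switch-error'")
  if (length(msgs)) msgs else TRUE
})
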