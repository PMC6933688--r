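## Accessor generics and show methods.

#' Extract the haplotype allele matrix
#' @param x a HaplotypePanel
#' @return integer matrix, haplotypes by markers
#' @export
setGeneric("alleles", function(x) standardGeneric("alleles"))

#' @rdname alleles
setMethod("alleles", "HaplotypePanel", function(x) x@alleles)

#' Extract the marker map
#' @param x an object carrying a marker map
#' @return data.frame with columns chrom, pos, id, ref, alt
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname markerMap
setMethod("markerMap", "HaplotypePanel", function(x) x@markerMap)
#' @rdname markerMap
setMethod("markerMap", "GenotypeMatrix", function(x) x@markerMap)
#' @rdname markerMap
setMethod("markerMap", "ImputationResult", function(x) x@markerMap)

#' Extract sample identifiers
#' @param x an object holding samples
#' @return character vector of sample ids
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
setMethod("sampleIds", "HaplotypePanel", function(x) x@sampleIds)
#' @rdname sampleIds
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@calls))
#' @rdname sampleIds
setMethod("sampleIds", "GRMatrix", function(x) x@sampleIds)
#' @rdname sampleIds
setMethod("sampleIds", "ImputationResult", function(x) rownames(x@dosage))

#' Breed label per sample
#' @param x a HaplotypePanel
#' @return named character vector, sample id -> breed
#' @export
setGeneric("breedOf", function(x) standardGeneric("breedOf"))

#' @rdname breedOf
setMethod("breedOf", "HaplotypePanel", function(x) x@breedOf[x@sampleIds])

#' Genotype call matrix (alternate-allele counts)
#' @param x a GenotypeMatrix
#' @return integer matrix, samples by markers, values 0/1/2/NA
#' @export
setGeneric("calls", function(x) standardGeneric("calls"))

#' @rdname calls
setMethod("calls", "GenotypeMatrix", function(x) x@calls)

#' Assay marker ids
#' @param x an AssayDefinition
#' @return character vector of marker ids (assay order)
#' @export
setGeneric("assayMarkers", function(x) standardGeneric("assayMarkers"))

#' @rdname assayMarkers
setMethod("assayMarkers", "AssayDefinition", function(x) x@markerIds)

#' Posterior dosage matrix
#' @param x an ImputationResult
#' @return numeric matrix of expected alternate-allele counts in [0,2]
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname dosage
setMethod("dosage", "ImputationResult", function(x) x@dosage)

#' Best-guess genotype matrix
#' @param x an ImputationResult
#' @return integer matrix of hard calls in \{0,1,2\}
#' @export
setGeneric("bestGuess", function(x) standardGeneric("bestGuess"))

#' @rdname bestGuess
setMethod("bestGuess", "ImputationResult", function(x) x@bestGuess)

#' Per-entry provenance flags
#' @param x an ImputationResult or composite HaplotypePanel
#' @return character matrix of provenance labels
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname provenance
setMethod("provenance", "ImputationResult", function(x) x@provenance)
#' @rdname provenance
setMethod("provenance", "HaplotypePanel", function(x) x@metadata$provenance)

#' Relationship values of a GRM
#' @param x a GRMatrix
#' @return numeric symmetric matrix
#' @export
setGeneric("grmValues", function(x) standardGeneric("grmValues"))

#' @rdname grmValues
setMethod("grmValues", "GRMatrix", function(x) x@values)

## -- show methods ------------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChromosomes, "chromosome(s) x", object@nMarkers,
      "markers,", nrow(object@breeds), "breeds,",
      nrow(object@admixedSamples), "admixed sample(s)\n")
  cat("  founders/breed:", object@nFoundersPerBreed,
      " switch rate:", object@mosaicSwitchRate,
      " genotype error:", object@genotypeErrorRate,
      " seed:", object@seed, "\n")
})

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", nrow(object@alleles), "haplotypes (",
      length(object@sampleIds), "samples ) x", ncol(object@alleles), "markers\n")
  tb <- table(breedOf(object))
  cat("  breeds:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
  if (!is.null(object@metadata$provenance))
    cat("  composite panel:",
        sum(object@metadata$provenance == "cross-imputed"),
        "cross-imputed entries\n")
})

setMethod("show", "AssayDefinition", function(object) {
  cat(sprintf("AssayDefinition '%s': %d markers (rule: %s%s)\n",
              object@name, length(object@markerIds), object@rule,
              if (!is.na(object@parent)) paste0(", parent: ", object@parent) else ""))
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "samples x",
      ncol(object@calls), "markers;",
      if (object@phased) "phased" else "unphased", "\n")
  nm <- sum(is.na(object@calls))
  if (nm) cat("  missing calls:", nm, "\n")
})

setMethod("show", "MaskedTestSet", function(object) {
  cat(sprintf("MaskedTestSet: %d samples; assay '%s' (%d observed markers), %d withheld\n",
              nrow(object@observed@calls), object@assay@name,
              ncol(object@observed@calls), length(object@withheldMarkerIds)))
})

setMethod("show", "HmmParams", function(object) {
  cat(sprintf("HmmParams: switchRate=%g, emissionError=%g, maxReferenceHaplotypes=%d\n",
              object@switchRate, object@emissionError, object@maxReferenceHaplotypes))
})

setMethod("show", "ImputationResult", function(object) {
  cat("ImputationResult:", nrow(object@dosage), "samples x",
      ncol(object@dosage), "markers;",
      sum(object@provenance[1, ] == "imputed"), "imputed markers per sample\n")
})

setMethod("show", "PanelPair", function(object) {
  tb <- table(factor(object@groups, levels = c("A", "B", "AB")))
  cat(sprintf("PanelPair: %d samples (A-only=%d, B-only=%d, overlap=%d); assays '%s' (%d) / '%s' (%d)\n",
              length(object@groups), tb[["A"]], tb[["B"]], tb[["AB"]],
              object@assayA@name, length(object@assayA@markerIds),
              object@assayB@name, length(object@assayB@markerIds)))
})

setMethod("show", "GRMatrix", function(object) {
  cat("GRMatrix:", nrow(object@values), "samples,",
      object@nMarkersUsed, "polymorphic markers; mean diagonal =",
      signif(mean(diag(object@values)), 4), "\n")
})

setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig: seed", object@seed, "\n")
  cat("  strategies:", paste(object@strategies, collapse = ", "), "\n")
  cat("  mask assay:", object@maskAssay, "; density sweep:",
      if (length(object@densityAssays)) paste(object@densityAssays, collapse = ", ") else "none", "\n")
})
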