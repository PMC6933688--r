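## Internal helpers shared across modules.

#' Derive a per-stage seed from a global seed
#'
#' Expands one global integer seed into reproducible per-stage seeds by
#' hashing the stage name, so that individual pipeline stages can be re-run
#' in isolation with the same stream.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed in [0, 2^31).
#' @export
stageSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, length(stage) == 1L)
  cp <- utf8ToInt(stage)
  h <- sum(cp * (seq_along(cp) %% 97 + 1))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 131) %% 2147483647)
}

## MAF bin labels: a dedicated bin for fixed markers (MAF = 0), then ten
## half-open bins (0, 0.05], (0.05, 0.10], ..., (0.45, 0.50].
.mafBinBreaks <- seq(0, 0.5, by = 0.05)

.mafBinLabels <- function() {
  lo <- head(.mafBinBreaks, -1L)
  hi <- tail(.mafBinBreaks, -1L)
  c("fixed", sprintf(">%.2f-%.2f", lo, hi))
}

#' Assign minor-allele-frequency bins
#'
#' Markers with MAF = 0 go to a dedicated \code{"fixed"} bin; polymorphic
#' markers fall into half-open bins (0,0.05], (0.05,0.10], ..., (0.45,0.50].
#'
#' @param maf numeric vector of minor allele frequencies in [0, 0.5].
#' @return factor of bin labels.
#' @export
mafBin <- function(maf) {
  stopifnot(all(maf >= -1e-12 & maf <= 0.5 + 1e-12, na.rm = TRUE))
  labs <- .mafBinLabels()
  out <- as.character(cut(maf, breaks = .mafBinBreaks, labels = labs[-1L],
                          include.lowest = FALSE, right = TRUE))
  out[!is.na(maf) & maf == 0] <- "fixed"
  factor(out, levels = labs)
}

## Restrict a HaplotypePanel to samples and/or markers (id order preserved as
## given). Frequency matrices are subset on markers; breed rows kept.
.subsetPanel <- function(panel, samples = NULL, markers = NULL) {
  al <- panel@alleles
  map <- panel@markerMap
  sids <- panel@sampleIds
  if (!is.null(samples)) {
    idx <- match(samples, sids)
    if (anyNA(idx)) stop("unknown sample id(s): ",
                         paste(samples[is.na(idx)], collapse = ", "))
    hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
    al <- al[hrows, , drop = FALSE]
    sids <- samples
  }
  if (!is.null(markers)) {
    midx <- match(markers, map$id)
    if (anyNA(midx)) stop("unknown marker id(s): ",
                          paste(markers[is.na(midx)], collapse = ", "))
    al <- al[, midx, drop = FALSE]
    map <- map[midx, , drop = FALSE]
    rownames(map) <- NULL
  }
  ff <- panel@founderFreqs
  bf <- panel@breedFreqs
  af <- panel@ancestralFreqs
  if (!is.null(markers)) {
    midx <- match(markers, panel@markerMap$id)
    if (nrow(ff)) ff <- ff[, midx, drop = FALSE]
    if (nrow(bf)) bf <- bf[, midx, drop = FALSE]
    if (length(af)) af <- af[midx]
  }
  new("HaplotypePanel", alleles = al, markerMap = map, sampleIds = sids,
      breedOf = panel@breedOf[sids], founderFreqs = ff, breedFreqs = bf,
      ancestralFreqs = af, admixture = panel@admixture, metadata = list())
}

## Haplotype row indices of a set of samples within a panel.
.hapRows <- function(panel, samples) {
  idx <- match(samples, panel@sampleIds)
  as.vector(rbind(2L * idx - 1L, 2L * idx))
}

## Genotype matrix (samples x markers) collapsed from a panel's haplotypes.
.panelGenotypes <- function(panel) {
  al <- panel@alleles
  n <- nrow(al) %/% 2L
  g <- al[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
       al[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(g) <- panel@sampleIds
  colnames(g) <- panel@markerMap$id
  g
}

## Construct a GenotypeMatrix, deriving colnames from the map.
.newGenotypeMatrix <- function(callsMat, map, phased = FALSE, metadata = list()) {
  colnames(callsMat) <- map$id
  new("GenotypeMatrix", calls = callsMat, markerMap = map,
      phased = phased, metadata = metadata)
}
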