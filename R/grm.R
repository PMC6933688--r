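## Standardized genomic relationship matrix and reference-similarity
## diagnostics.

#' Standardized genomic relationship matrix
#'
#' G_jk = (1/m) * sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))
#' over the m polymorphic markers (0 < p < 1), with p_i the sample allele
#' frequency computed from the input; missing genotypes are mean-imputed to
#' 2 p_i and therefore contribute zero to their terms. Monomorphic markers
#' are excluded (and counted) since their term is undefined.
#'
#' @param g a \linkS4class{GenotypeMatrix} with at least two samples.
#' @return a \linkS4class{GRMatrix}.
#' @export
standardizedGRM <- function(g) {
  cl <- g@calls
  if (nrow(cl) < 2L) stop("need at least two samples")
  nObs <- colSums(!is.na(cl))
  if (any(nObs == 0L)) stop("all-missing marker(s) present; run QC first")
  p <- colSums(cl, na.rm = TRUE) / (2 * nObs)
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic markers")
  X <- cl[, poly, drop = FALSE]
  pp <- p[poly]
  Xc <- sweep(X, 2L, 2 * pp)
  Xc[is.na(Xc)] <- 0
  W <- sweep(Xc, 2L, sqrt(2 * pp * (1 - pp)), "/")
  G <- tcrossprod(W) / sum(poly)
  G <- (G + t(G)) / 2
  dimnames(G) <- list(rownames(cl), rownames(cl))
  new("GRMatrix", values = G, sampleIds = rownames(cl),
      nMarkersUsed = as.integer(sum(poly)), freqs = unname(pp))
}

#' Mean genomic relationship of test samples to a reference set
#'
#' For each test sample, the mean of its GRM entries against the reference
#' samples, optionally restricted to reference samples of one breed (by
#' label, or by ancestry proportion at least \code{minProportion} when a
#' proportion table is given). Larger values indicate closer relatedness to
#' the reference.
#'
#' @param G a \linkS4class{GRMatrix}.
#' @param testIds,referenceIds disjoint character vectors of sample ids
#'   present in \code{G}.
#' @param breed optional breed label to filter the reference by.
#' @param breedOf named character sample -> breed (required with
#'   \code{breed} unless \code{proportions} is given).
#' @param proportions optional data.frame (sample, breed, proportion) of
#'   ancestry estimates; reference samples with proportion >=
#'   \code{minProportion} for \code{breed} are kept.
#' @param minProportion ancestry threshold (default 0.5).
#' @return named numeric vector of per-test-sample mean relationships.
#' @export
similarityToReference <- function(G, testIds, referenceIds, breed = NULL,
                                  breedOf = NULL, proportions = NULL,
                                  minProportion = 0.5) {
  ids <- sampleIds(G)
  if (!all(c(testIds, referenceIds) %in% ids))
    stop("test/reference ids must be present in the GRM")
  if (length(intersect(testIds, referenceIds)))
    stop("test and reference id sets must be disjoint")
  refs <- referenceIds
  if (!is.null(breed)) {
    if (!is.null(proportions)) {
      keep <- proportions$sample[proportions$breed == breed &
                                 proportions$proportion >= minProportion]
      refs <- intersect(refs, keep)
    } else if (!is.null(breedOf)) {
      refs <- refs[breedOf[refs] == breed]
    } else stop("breed filtering needs breedOf or proportions")
    if (!length(refs)) stop("no reference samples left after breed filtering")
  }
  v <- grmValues(G)
  rowMeans(v[testIds, refs, drop = FALSE])
}

#' Write a GRM as GEMMA-style square text matrix plus id list
#' @param G a \linkS4class{GRMatrix}.
#' @param prefix output prefix (writes \code{prefix.cXX.txt}-style square
#'   matrix at \code{prefix.grm.txt} and ids at \code{prefix.ids.txt}).
#' @return the prefix, invisibly.
#' @export
writeGRM <- function(G, prefix) {
  write.table(grmValues(G), paste0(prefix, ".grm.txt"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(sampleIds(G), paste0(prefix, ".ids.txt"))
  invisible(prefix)
}
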