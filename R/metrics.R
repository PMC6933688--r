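## Accuracy statistics: error taxonomy, chance-corrected concordance (IQS),
## raw and MAF-centered Pearson r, per-variant/per-individual reports,
## MAF-binned summaries, low-accuracy region scans and panel comparisons.

#' Classify an imputed genotype against truth
#'
#' Taxonomy: \code{correct}; \code{false_het} (homozygous truth imputed
#' heterozygous); \code{false_hom} (heterozygous truth imputed homozygous);
#' \code{discordant} (opposite homozygotes).
#'
#' @param truth,imputed integer vectors over \{0,1,2\}; missing values are
#'   not allowed (exclude pairwise-missing entries upstream).
#' @return factor with levels correct, false_het, false_hom, discordant.
#' @export
classifyErrors <- function(truth, imputed) {
  if (length(truth) != length(imputed)) stop("length mismatch")
  if (anyNA(truth) || anyNA(imputed))
    stop("missing genotypes must be excluded before classification")
  if (!all(truth %in% 0:2) || !all(imputed %in% 0:2))
    stop("genotypes must be coded 0/1/2")
  out <- rep("correct", length(truth))
  out[truth != imputed] <- "discordant"
  out[truth != 1L & imputed == 1L] <- "false_het"
  out[truth == 1L & imputed != 1L] <- "false_hom"
  factor(out, levels = c("correct", "false_het", "false_hom", "discordant"))
}

#' Imputation quality score (chance-corrected concordance)
#'
#' Builds the 3x3 truth-by-imputed contingency table over pairwise
#' non-missing entries and computes the kappa-type statistic
#' IQS = (P0 - Pc) / (1 - Pc), with P0 the observed concordance and Pc the
#' chance agreement implied by the table margins. When both vectors are
#' constant and identical (P0 = Pc = 1) the score is defined as 1. If
#' exactly one side is constant the marginal algebra forces IQS = 0, which
#' is the statistic's defense against inflated concordance at rare and
#' fixed sites. IQS may be negative (agreement below chance).
#'
#' @param truth,imputed integer vectors over \{0,1,2\} (NA allowed; pairwise
#'   deleted).
#' @return numeric scalar in [-1, 1].
#' @export
iqs <- function(truth, imputed) {
  if (length(truth) != length(imputed)) stop("length mismatch")
  ok <- !is.na(truth) & !is.na(imputed)
  if (!any(ok)) stop("no pairwise non-missing genotype pairs")
  tab <- table(factor(truth[ok], levels = 0:2),
               factor(imputed[ok], levels = 0:2))
  iqsFromTable(tab)
}

#' IQS from a 3x3 contingency table
#' @param tab 3x3 numeric matrix, rows = truth class, columns = imputed
#'   class.
#' @return numeric scalar.
#' @export
iqsFromTable <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(3L, 3L))) stop("expected a 3x3 table")
  N <- sum(tab)
  if (N == 0) stop("empty table")
  P0 <- sum(diag(tab)) / N
  Pc <- sum(rowSums(tab) * colSums(tab)) / N^2
  if (Pc >= 1) return(1)
  (P0 - Pc) / (1 - Pc)
}

#' Pearson correlation between genotype vectors, raw or MAF-centered
#'
#' The MAF-centered mode subtracts twice the marker's minor allele
#' frequency from both vectors before correlating (per-individual use,
#' where each position is a different marker). Returns \code{NA} when
#' either vector has zero variance -- a fixed marker cannot have an r.
#'
#' @param x,y numeric genotype vectors (NA allowed; pairwise deleted).
#' @param centering "raw" or "maf-centered".
#' @param maf per-position MAF vector, required for centered mode.
#' @return numeric scalar, or \code{NA_real_} when undefined.
#' @export
pearsonR <- function(x, y, centering = c("raw", "maf-centered"), maf = NULL) {
  centering <- match.arg(centering)
  if (length(x) != length(y)) stop("length mismatch")
  if (centering == "maf-centered") {
    if (is.null(maf)) stop("maf-centered mode requires per-position MAF")
    if (length(maf) != length(x)) stop("maf length mismatch")
    x <- x - 2 * maf
    y <- y - 2 * maf
  }
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no pairwise-complete data")
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

## Align truth calls with an imputation result, returning the entries
## scored (provenance == "imputed" and truth non-missing), optionally
## restricted to a sample subset.
.scoredEntries <- function(truth, result, samples = NULL) {
  mk <- intersect(colnames(truth@calls), colnames(result@dosage))
  if (!length(mk)) stop("truth and result share no markers")
  smp <- rownames(result@dosage)
  if (!is.null(samples)) {
    if (!all(samples %in% smp)) stop("unknown sample id(s) in samples=")
    smp <- samples
  }
  t_ <- truth@calls[smp, mk, drop = FALSE]
  b_ <- result@bestGuess[smp, mk, drop = FALSE]
  p_ <- result@provenance[smp, mk, drop = FALSE]
  list(truth = t_, best = b_, scored = (p_ == "imputed") & !is.na(t_),
       markers = mk, samples = smp)
}

#' Per-variant imputation accuracy
#'
#' Scores only withheld entries (provenance \code{"imputed"}) against the
#' truth calls, per marker: concordance, IQS, raw Pearson r (NA when either
#' side is constant), error counts by type, and the MAF bin (half-open
#' bins (0,0.05], ..., (0.45,0.50]; MAF = 0 markers fall into a dedicated
#' "fixed" bin).
#'
#' @param truth a \linkS4class{GenotypeMatrix} of true calls for the test
#'   samples (full marker set).
#' @param result an \linkS4class{ImputationResult}.
#' @param maf named numeric vector of panel-wide MAF (from the combined
#'   reference + test set).
#' @param samples optional character vector restricting scoring to a sample
#'   subset (e.g. admixed individuals only).
#' @return data.frame with one row per scored marker: marker, chrom, pos,
#'   maf, maf_bin, n_compared, n_correct, n_false_het, n_false_hom,
#'   n_discordant, n_errors, concordance, iqs, r.
#' @export
perVariantAccuracy <- function(truth, result, maf, samples = NULL) {
  se <- .scoredEntries(truth, result, samples)
  nScored <- colSums(se$scored)
  keep <- which(nScored > 0L)
  if (!length(keep)) stop("no withheld (imputed) entries to score")
  map <- result@markerMap
  rows <- lapply(keep, function(j) {
    sc <- se$scored[, j]
    tv <- se$truth[sc, j]; iv <- se$best[sc, j]
    cls <- classifyErrors(tv, iv)
    cnt <- tabulate(cls, nbins = 4L)
    data.frame(marker = se$markers[j],
               n_compared = length(tv),
               n_correct = cnt[1], n_false_het = cnt[2],
               n_false_hom = cnt[3], n_discordant = cnt[4],
               concordance = cnt[1] / length(tv),
               iqs = iqs(tv, iv),
               r = pearsonR(tv, iv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$n_errors <- out$n_false_het + out$n_false_hom + out$n_discordant
  mi <- match(out$marker, map$id)
  out$chrom <- map$chrom[mi]
  out$pos <- map$pos[mi]
  mv <- maf[out$marker]
  if (anyNA(mv)) stop("MAF missing for scored marker(s)")
  out$maf <- unname(mv)
  out$maf_bin <- mafBin(out$maf)
  out <- out[order(match(out$marker, map$id)), ]
  rownames(out) <- NULL
  out[, c("marker", "chrom", "pos", "maf", "maf_bin", "n_compared",
          "n_correct", "n_false_het", "n_false_hom", "n_discordant",
          "n_errors", "concordance", "iqs", "r")]
}

#' Per-individual imputation accuracy
#'
#' Per test sample over its withheld entries: raw and MAF-centered Pearson
#' r between truth and best-guess genotypes, error counts by type and the
#' comparison count.
#'
#' @inheritParams perVariantAccuracy
#' @param breedOf optional named character, sample -> breed label.
#' @param samples optional character vector restricting scoring to a sample
#'   subset.
#' @return data.frame: sample, breed, n_compared, r_raw, r_centered,
#'   n_false_het, n_false_hom, n_discordant, total_errors.
#' @export
perIndividualAccuracy <- function(truth, result, maf, breedOf = NULL,
                                  samples = NULL) {
  se <- .scoredEntries(truth, result, samples)
  samples <- se$samples
  mafv <- maf[se$markers]
  if (anyNA(mafv)) stop("MAF missing for scored marker(s)")
  rows <- lapply(seq_along(samples), function(i) {
    sc <- se$scored[i, ]
    if (!any(sc)) stop("sample ", samples[i], " has no withheld entries")
    tv <- se$truth[i, sc]; iv <- se$best[i, sc]
    cls <- classifyErrors(tv, iv)
    cnt <- tabulate(cls, nbins = 4L)
    data.frame(sample = samples[i],
               breed = if (!is.null(breedOf)) breedOf[[samples[i]]] else NA_character_,
               n_compared = length(tv),
               r_raw = pearsonR(tv, iv),
               r_centered = pearsonR(tv, iv, "maf-centered", maf = mafv[sc]),
               n_false_het = cnt[2], n_false_hom = cnt[3],
               n_discordant = cnt[4],
               total_errors = cnt[2] + cnt[3] + cnt[4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' MAF-binned summary of per-variant accuracies
#'
#' @param va a per-variant accuracy data.frame.
#' @return data.frame with one row per occupied MAF bin: n_markers and the
#'   bin means of concordance, r (over markers where defined) and iqs.
#' @export
binnedAccuracy <- function(va) {
  sp <- split(va, va$maf_bin, drop = TRUE)
  out <- do.call(rbind, lapply(names(sp), function(b) {
    d <- sp[[b]]
    data.frame(maf_bin = b, n_markers = nrow(d),
               mean_concordance = mean(d$concordance),
               mean_r = if (all(is.na(d$r))) NA_real_ else mean(d$r, na.rm = TRUE),
               n_r_undefined = sum(is.na(d$r)),
               mean_iqs = mean(d$iqs),
               sd_iqs = if (nrow(d) > 1) sd(d$iqs) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  out$maf_bin <- factor(out$maf_bin, levels = .mafBinLabels())
  out[order(out$maf_bin), ]
}

#' Scan for genome regions of low imputation accuracy
#'
#' Slides non-overlapping windows of \code{window} markers along each
#' chromosome (markers ordered by position) and flags windows in which the
#' fraction of markers breaching either threshold -- IQS below
#' \code{iqsThreshold} or more than \code{errorThreshold} imputation errors
#' -- exceeds \code{flagFraction}.
#'
#' @param va per-variant accuracy data.frame (from
#'   \code{\link{perVariantAccuracy}}).
#' @param iqsThreshold IQS breach threshold (default 0.8).
#' @param errorThreshold error-count breach threshold (default 10).
#' @param window markers per window (default 50).
#' @param flagFraction breach fraction above which a window is flagged
#'   (default 0.2).
#' @return data.frame: chrom, start, end, n_markers, n_breach,
#'   breach_fraction, flagged, breaching_markers (comma-joined ids).
#' @export
regionScan <- function(va, iqsThreshold = 0.8, errorThreshold = 10L,
                       window = 50L, flagFraction = 0.2) {
  va <- va[order(va$chrom, va$pos), ]
  breach <- (!is.na(va$iqs) & va$iqs < iqsThreshold) |
            (va$n_errors > errorThreshold)
  out <- list()
  for (ch in unique(va$chrom)) {
    idx <- which(va$chrom == ch)
    starts <- seq(1L, length(idx), by = window)
    for (s in starts) {
      w <- idx[s:min(s + window - 1L, length(idx))]
      nb <- sum(breach[w])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = min(va$pos[w]), end = max(va$pos[w]),
        n_markers = length(w), n_breach = nb,
        breach_fraction = nb / length(w),
        flagged = nb / length(w) > flagFraction,
        breaching_markers = paste(va$marker[w][breach[w]], collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Compare per-variant accuracy between two reference panels
#'
#' Paired comparison over the shared marker set (markers with a defined IQS
#' in both): mean IQS difference (b - a) with the paired t statistic and
#' two-sided p-value, the variance-ratio F statistic var(a)/var(b) with its
#' two-sided p-value, counts of markers improved/worsened/unchanged under
#' b, and the mean |change| within the improved and worsened sets.
#'
#' @param a,b per-variant accuracy data.frames over the same marker set
#'   (e.g. breed-reference vs composite-reference runs).
#' @return list with elements n, mean_diff, t, df, p_t, f, p_f,
#'   n_improved, n_worsened, n_unchanged, mean_gain_improved,
#'   mean_loss_worsened.
#' @export
comparePanels <- function(a, b) {
  if (!setequal(a$marker, b$marker))
    stop("panels were scored on different marker sets")
  b <- b[match(a$marker, b$marker), ]
  ok <- !is.na(a$iqs) & !is.na(b$iqs)
  x <- a$iqs[ok]; y <- b$iqs[ok]
  d <- y - x
  n <- length(d)
  if (n < 2L) stop("need at least two paired markers")
  md <- mean(d)
  sdd <- sd(d)
  tstat <- if (sdd == 0) 0 else md / (sdd / sqrt(n))
  pT <- 2 * pt(-abs(tstat), df = n - 1)
  vr <- var(x) / var(y)
  pF <- 2 * min(pf(vr, n - 1, n - 1), 1 - pf(vr, n - 1, n - 1))
  imp <- d > 0; wor <- d < 0
  list(n = n, mean_diff = md, t = tstat, df = n - 1, p_t = pT,
       f = vr, p_f = pF,
       n_improved = sum(imp), n_worsened = sum(wor),
       n_unchanged = sum(d == 0),
       mean_gain_improved = if (any(imp)) mean(d[imp]) else NA_real_,
       mean_loss_worsened = if (any(wor)) mean(abs(d[wor])) else NA_real_)
}

#' Write a per-variant or per-individual report as tab-separated text
#' @param df report data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
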