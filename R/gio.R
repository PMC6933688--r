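## Genotype I/O (VCF 4.2 and PLINK text PED/MAP) and call-rate QC.

.vcfHeader <- function(map, extraFormat = character(), extraInfo = character()) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(map$chrom)),
    extraInfo,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    extraFormat)
}

#' Write genotypes, haplotypes or imputation results as VCF 4.2
#'
#' \code{GenotypeMatrix} objects are written with unphased GT ("0/1");
#' \code{HaplotypePanel} objects with phased GT ("0|1");
#' \code{ImputationResult} objects with GT (best guess), DS (posterior
#' dosage, 3 decimals) and an \code{IMPUTED} INFO flag on markers imputed
#' for at least one sample. Missing calls become "./.".
#'
#' @param x object to write.
#' @param path output path (plain text; no compression).
#' @return \code{path}, invisibly.
#' @export
writeVCF <- function(x, path) {
  if (is(x, "HaplotypePanel")) {
    map <- x@markerMap
    n <- length(x@sampleIds)
    h1 <- x@alleles[seq(1L, 2L * n, 2L), , drop = FALSE]
    h2 <- x@alleles[seq(2L, 2L * n, 2L), , drop = FALSE]
    gtcol <- matrix(paste0(h1, "|", h2), nrow = n)
    body <- vapply(seq_len(nrow(map)), function(j)
      paste(gtcol[, j], collapse = "\t"), character(1))
    fmt <- "GT"
    info <- rep(".", nrow(map))
    samples <- x@sampleIds
    header <- .vcfHeader(map)
  } else if (is(x, "GenotypeMatrix")) {
    map <- x@markerMap
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = nrow(x@calls), ncol = ncol(x@calls))
    ok <- !is.na(x@calls)
    gt[ok] <- code[x@calls[ok] + 1L]
    body <- vapply(seq_len(nrow(map)), function(j)
      paste(gt[, j], collapse = "\t"), character(1))
    fmt <- "GT"
    info <- rep(".", nrow(map))
    samples <- rownames(x@calls)
    header <- .vcfHeader(map)
  } else if (is(x, "ImputationResult")) {
    map <- x@markerMap
    code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = nrow(x@bestGuess), ncol = ncol(x@bestGuess))
    ok <- !is.na(x@bestGuess)
    gt[ok] <- code[x@bestGuess[ok] + 1L]
    ds <- matrix(sprintf("%.3f", x@dosage), nrow = nrow(x@dosage))
    cell <- matrix(paste0(gt, ":", ds), nrow = nrow(gt))
    body <- vapply(seq_len(nrow(map)), function(j)
      paste(cell[, j], collapse = "\t"), character(1))
    fmt <- "GT:DS"
    info <- ifelse(colSums(x@provenance == "imputed") > 0, "IMPUTED", ".")
    samples <- rownames(x@dosage)
    header <- .vcfHeader(map,
      extraFormat = "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Posterior alternate allele dosage\">",
      extraInfo = "##INFO=<ID=IMPUTED,Number=0,Type=Flag,Description=\"Genotype imputed for at least one sample\">")
  } else stop("writeVCF supports HaplotypePanel, GenotypeMatrix and ImputationResult")

  lines <- c(header,
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"),
             paste(map$chrom, map$pos, map$id, map$ref, map$alt, ".", "PASS",
                   info, fmt, body, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write the breed/ancestry sample-metadata sidecar
#'
#' Tab-separated columns: sample_id, breed, proportions (semicolon-joined
#' \code{breed=value} pairs for admixed samples, otherwise the breed itself
#' at 1).
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSampleMetadata <- function(panel, path) {
  b <- breedOf(panel)
  prop <- vapply(panel@sampleIds, function(s) {
    a <- panel@admixture[panel@admixture$sample == s & panel@admixture$proportion > 0, ]
    if (nrow(a)) paste(sprintf("%s=%g", a$breed, a$proportion), collapse = ";")
    else sprintf("%s=1", b[[s]])
  }, character(1))
  df <- data.frame(sample_id = panel@sampleIds, breed = unname(b),
                   proportions = unname(prop))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an assay definition as a one-marker-per-line text list
#' @param assay an \linkS4class{AssayDefinition}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAssayDefinition <- function(assay, path) {
  writeLines(assay@markerIds, path)
  invisible(path)
}

#' Write genotypes as PLINK text PED/MAP
#'
#' The MAP file is extended with allele columns: chrom, id, cM (0), pos,
#' ref, alt; the counted (alternate) allele is column 6. PED alleles use the
#' marker map's ref/alt letters, with "0 0" for missing.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param prefix output path prefix (writes \code{prefix.ped} and
#'   \code{prefix.map}).
#' @return the prefix, invisibly.
#' @export
writePlink <- function(g, prefix) {
  map <- g@markerMap
  write.table(data.frame(map$chrom, map$id, 0, map$pos, map$ref, map$alt),
              paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  n <- nrow(g@calls)
  a1 <- matrix(map$ref[col(g@calls)], nrow = n)  # first written allele
  a2 <- a1
  cl <- g@calls
  a1[!is.na(cl) & cl >= 1L] <- map$alt[col(cl)[!is.na(cl) & cl >= 1L]]
  a2[!is.na(cl) & cl == 2L] <- map$alt[col(cl)[!is.na(cl) & cl == 2L]]
  a1[is.na(cl)] <- "0"; a2[is.na(cl)] <- "0"
  geno <- matrix(paste(a1, a2), nrow = n)
  lines <- vapply(seq_len(n), function(i)
    paste(c("FAM", rownames(cl)[i], 0, 0, 0, -9, geno[i, ]), collapse = " "),
    character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(prefix)
}

.readVcfGenotypes <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi))
    stop("multi-allelic site(s) not supported: ",
         paste(fix[multi, "ID"], collapse = ", "))
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gtRaw)) stop("VCF has no GT field")
  nHeader <- length(v@meta) + 1L
  parseOne <- function(s, row) {
    if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_integer_)
    al <- strsplit(s, "[/|]")[[1]]
    if (!all(al %in% c("0", "1", ".")))
      stop("malformed GT '", s, "' at line ", nHeader + row, call. = FALSE)
    if (any(al == ".")) return(NA_integer_)
    sum(as.integer(al))
  }
  cl <- matrix(NA_integer_, nrow = ncol(gtRaw), ncol = nrow(gtRaw),
               dimnames = list(colnames(gtRaw), rownames(gtRaw)))
  for (j in seq_len(nrow(gtRaw)))
    cl[, j] <- vapply(gtRaw[j, ], parseOne, integer(1), row = j)
  phased <- all(grepl("\\|", gtRaw[!is.na(gtRaw) & !grepl("^\\.", gtRaw)]) |
                !grepl("[/|]", gtRaw[!is.na(gtRaw) & !grepl("^\\.", gtRaw)]))
  map <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                    id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  noid <- is.na(map$id) | map$id == "."
  map$id[noid] <- paste0(map$chrom[noid], ":", map$pos[noid])
  .newGenotypeMatrix(cl, map, phased = phased)
}

.readPlinkGenotypes <- function(prefix) {
  mapPath <- paste0(prefix, ".map"); pedPath <- paste0(prefix, ".ped")
  if (!file.exists(mapPath) || !file.exists(pedPath))
    stop("expected '", mapPath, "' and '", pedPath, "'")
  mp <- read.table(mapPath, header = FALSE, stringsAsFactors = FALSE)
  if (!ncol(mp) %in% c(4L, 6L))
    stop("MAP file must have 4 (chrom,id,cM,pos) or 6 (+ref,alt) columns")
  M <- nrow(mp)
  pedLines <- readLines(pedPath)
  pedLines <- pedLines[nzchar(trimws(pedLines))]
  n <- length(pedLines)
  ids <- character(n)
  A1 <- matrix("0", n, M); A2 <- matrix("0", n, M)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(pedLines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * M)
      stop("malformed PED record at line ", i, ": expected ",
           6L + 2L * M, " fields, found ", length(f))
    ids[i] <- f[2]
    al <- f[-(1:6)]
    A1[i, ] <- al[seq(1L, 2L * M, 2L)]
    A2[i, ] <- al[seq(2L, 2L * M, 2L)]
  }
  if (ncol(mp) == 6L) {
    ref <- as.character(mp[[5]]); alt <- as.character(mp[[6]])
  } else {
    ## infer counted allele: minor allele in the data (alphabetical tie-break)
    ref <- character(M); alt <- character(M)
    for (j in seq_len(M)) {
      obs <- c(A1[, j], A2[, j]); obs <- obs[obs != "0"]
      alls <- sort(unique(obs))
      if (length(alls) > 2L)
        stop("multi-allelic site not supported: marker ", mp[[2]][j])
      if (length(alls) == 0L) { ref[j] <- "A"; alt[j] <- "B"; next }
      if (length(alls) == 1L) { ref[j] <- alls; alt[j] <- setdiff(c("A","B","C","D"), alls)[1]; next }
      cnt <- table(factor(obs, levels = alls))
      alt[j] <- if (cnt[[1]] == cnt[[2]]) alls[2] else alls[which.min(cnt)]
      ref[j] <- setdiff(alls, alt[j])
    }
  }
  cl <- matrix(NA_integer_, n, M)
  for (j in seq_len(M)) {
    valid <- c(ref[j], alt[j], "0")
    bad <- !(A1[, j] %in% valid) | !(A2[, j] %in% valid)
    if (any(bad))
      stop("allele(s) at marker ", mp[[2]][j],
           " not matching MAP declaration (sample(s): ",
           paste(ids[bad], collapse = ", "), ")")
    miss <- A1[, j] == "0" | A2[, j] == "0"
    cl[, j] <- (A1[, j] == alt[j]) + (A2[, j] == alt[j])
    cl[miss, j] <- NA_integer_
  }
  rownames(cl) <- ids
  map <- data.frame(chrom = as.character(mp[[1]]), pos = as.integer(mp[[4]]),
                    id = as.character(mp[[2]]), ref = ref, alt = alt,
                    stringsAsFactors = FALSE)
  .newGenotypeMatrix(cl, map, phased = FALSE)
}

#' Read biallelic SNP genotypes from VCF or PLINK text files
#'
#' VCF parsing is delegated to \pkg{vcfR}; "./." and half-missing calls map
#' to \code{NA}; counts follow the file's REF/ALT orientation; the matrix is
#' flagged phased only when every genotype separator is "|". PLINK text
#' input expects \code{prefix.ped} / \code{prefix.map}; "0 0" maps to
#' missing. A 6-column MAP declares ref (col 5) and counted alt (col 6)
#' alleles; with a 4-column MAP the counted allele is inferred as the minor
#' allele.
#'
#' @param path VCF file path, or the PED/MAP prefix.
#' @param format "vcf" or "plink-text".
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypes <- function(path, format = c("vcf", "plink-text")) {
  format <- match.arg(format)
  switch(format,
         "vcf" = .readVcfGenotypes(path),
         "plink-text" = .readPlinkGenotypes(path))
}

.isAutosome <- function(chrom) {
  x <- sub("^[Cc]hr", "", chrom)
  suppressWarnings(!is.na(as.integer(x)))
}

#' Call-rate and autosome quality control
#'
#' Removes non-autosomal markers first, then markers with call rate
#' strictly below \code{minCallRate}, then samples with call rate strictly
#' below the threshold computed on the surviving markers. No MAF filter and
#' no Hardy-Weinberg filter are applied: monomorphic and rare markers are
#' deliberately retained (their behaviour under chance-corrected accuracy
#' scoring is a core concern).
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param minCallRate call-rate threshold in (0,1]; entities at exactly the
#'   threshold are kept (removal requires call rate < threshold).
#' @param autosomesOnly drop non-autosomal markers first (default TRUE).
#' @return list with elements \code{genotypes} (filtered GenotypeMatrix) and
#'   \code{log} (data.frame: entity, type, reason, value).
#' @export
qcFilter <- function(g, minCallRate = 0.90, autosomesOnly = TRUE) {
  stopifnot(minCallRate > 0, minCallRate <= 1)
  log <- data.frame(entity = character(0), type = character(0),
                    reason = character(0), value = numeric(0),
                    stringsAsFactors = FALSE)
  cl <- g@calls; map <- g@markerMap
  if (autosomesOnly) {
    drop <- !.isAutosome(map$chrom)
    if (any(drop)) {
      log <- rbind(log, data.frame(entity = map$id[drop], type = "marker",
                                   reason = "non-autosomal", value = NA_real_))
      cl <- cl[, !drop, drop = FALSE]
      map <- map[!drop, , drop = FALSE]
    }
  }
  if (ncol(cl) == 0L) stop("no markers remain after autosome filtering")
  mcr <- colMeans(!is.na(cl))
  drop <- mcr < minCallRate
  if (any(drop)) {
    log <- rbind(log, data.frame(entity = map$id[drop], type = "marker",
                                 reason = "call-rate", value = mcr[drop]))
    cl <- cl[, !drop, drop = FALSE]
    map <- map[!drop, , drop = FALSE]
  }
  if (ncol(cl) == 0L) stop("no markers remain after call-rate filtering")
  scr <- rowMeans(!is.na(cl))
  drop <- scr < minCallRate
  if (any(drop)) {
    log <- rbind(log, data.frame(entity = rownames(cl)[drop], type = "sample",
                                 reason = "call-rate", value = scr[drop]))
    cl <- cl[!drop, , drop = FALSE]
  }
  if (nrow(cl) == 0L) stop("no samples remain after call-rate filtering")
  rownames(map) <- NULL
  list(genotypes = .newGenotypeMatrix(cl, map, phased = g@phased,
                                      metadata = g@metadata),
       log = log)
}

#' Write a QC log as tab-separated text
#' @param log the \code{log} element returned by \code{\link{qcFilter}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeQcLog <- function(log, path) {
  write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Minor allele frequency from genotype calls
#'
#' MAF = min(f, 1-f) with f the alternate-allele frequency over non-missing
#' calls; invariant to swapping REF/ALT orientation.
#'
#' @param g a \linkS4class{GenotypeMatrix}.
#' @param scope optional character vector of marker ids to restrict to.
#' @return named numeric vector of per-marker MAF in [0, 0.5].
#' @export
computeMaf <- function(g, scope = NULL) {
  cl <- g@calls
  if (!is.null(scope)) {
    idx <- match(scope, colnames(cl))
    if (anyNA(idx)) stop("unknown marker id(s) in scope")
    cl <- cl[, idx, drop = FALSE]
  }
  nObs <- colSums(!is.na(cl))
  if (any(nObs == 0L))
    stop("all-missing marker(s): ",
         paste(colnames(cl)[nObs == 0L], collapse = ", "))
  f <- colSums(cl, na.rm = TRUE) / (2 * nObs)
  setNames(pmin(f, 1 - f), colnames(cl))
}
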