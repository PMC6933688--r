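# Fixture builders used across the suite. Everything is generated in code;
# no stored data files.

# HaplotypePanel from a raw haplotype matrix (rows = haplotypes, must be
# even; columns = markers). Markers are placed on `nChrom` chromosomes of
# equal length, positions 1000, 2000, ...
makePanel <- function(alleles, nChrom = 1L, breeds = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- nrow(alleles) %/% 2L
  M <- ncol(alleles)
  perChr <- M %/% nChrom
  stopifnot(perChr * nChrom == M)
  sampleIds <- sprintf("S%03d", seq_len(n))
  if (is.null(breeds)) breeds <- rep("X", n)
  map <- data.frame(
    chrom = rep(as.character(seq_len(nChrom)), each = perChr),
    pos = rep(seq_len(perChr) * 1000L, times = nChrom),
    id = sprintf("chr%d:%d", rep(seq_len(nChrom), each = perChr),
                 rep(seq_len(perChr) * 1000L, times = nChrom)),
    ref = "A", alt = "B", stringsAsFactors = FALSE)
  rownames(alleles) <- as.vector(rbind(paste0(sampleIds, "_h1"),
                                       paste0(sampleIds, "_h2")))
  colnames(alleles) <- map$id
  new("HaplotypePanel", alleles = alleles, markerMap = map,
      sampleIds = sampleIds, breedOf = setNames(breeds, sampleIds),
      founderFreqs = matrix(0, 0, 0), breedFreqs = matrix(0, 0, 0),
      ancestralFreqs = numeric(0),
      admixture = data.frame(sample = character(0), breed = character(0),
                             proportion = numeric(0)),
      metadata = list())
}

# GenotypeMatrix from a calls matrix (rows = samples); marker layout as in
# makePanel unless a map is given.
makeGm <- function(calls, nChrom = 1L, map = NULL, phased = FALSE,
                   chrom = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  M <- ncol(calls)
  if (is.null(map)) {
    if (is.null(chrom)) {
      perChr <- M %/% nChrom
      chrom <- rep(as.character(seq_len(nChrom)), each = perChr)
    }
    pos <- unlist(lapply(split(seq_len(M), factor(chrom, unique(chrom))),
                         function(ix) seq_along(ix) * 1000L), use.names = FALSE)
    ord <- order(match(chrom, unique(chrom)))
    map <- data.frame(chrom = chrom, pos = pos,
                      id = sprintf("m%03d", seq_len(M)),
                      ref = "A", alt = "B", stringsAsFactors = FALSE)
  }
  if (is.null(rownames(calls)))
    rownames(calls) <- sprintf("S%03d", seq_len(nrow(calls)))
  colnames(calls) <- map$id
  new("GenotypeMatrix", calls = calls, markerMap = map, phased = phased,
      metadata = list())
}

assayOf <- function(ids, name = "ASSAY") {
  new("AssayDefinition", name = name, markerIds = ids, rule = "manual",
      parent = NA_character_)
}

# A small two-breed panel used by several structural tests.
smallSimPanel <- function(seed = 11L, nMarkers = 300L, nChrom = 2L) {
  simulatePanel(simConfig(
    nMarkers = nMarkers, nChromosomes = nChrom,
    breeds = data.frame(name = c("B1", "B2"),
                        nRefHaplotypes = c(80L, 40L),
                        nTestIndividuals = c(5L, 5L),
                        fst = c(0.10, 0.15)),
    admixedSamples = data.frame(name = "ADM01", B1 = 0.5, B2 = 0.5),
    seed = seed))
}
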