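test_that("simulation is deterministic given the seed", {
  p1 <- smallSimPanel(seed = 3L)
  p2 <- smallSimPanel(seed = 3L)
  expect_identical(alleles(p1), alleles(p2))
  expect_identical(p1@founderFreqs, p2@founderFreqs)
  p3 <- smallSimPanel(seed = 4L)
  expect_false(identical(alleles(p1), alleles(p3)))
})

test_that("without founder switching every haplotype is a verbatim founder copy", {
  cfg <- simConfig(nMarkers = 200L, nChromosomes = 1L,
    breeds = data.frame(name = "B1", nRefHaplotypes = 40L,
                        nTestIndividuals = 0L, fst = 0.1),
    nFoundersPerBreed = 3L, mosaicSwitchRate = 1e-12,
    admixedSamples = data.frame(name = character(0)), seed = 5L)
  panel <- simulatePanel(cfg)
  # every haplotype copies exactly one of the 3 founders end to end
  distinct <- unique(apply(alleles(panel), 1L, paste, collapse = ""))
  expect_lte(length(distinct), 3L)
})

test_that("breed frequency divergence matches the Balding-Nichols moment", {
  cfg <- simConfig(nMarkers = 10000L, nChromosomes = 1L,
    breeds = data.frame(name = c("P", "Q"), nRefHaplotypes = c(4L, 4L),
                        nTestIndividuals = 0L, fst = 0.2),
    nFoundersPerBreed = 2L,
    admixedSamples = data.frame(name = character(0)), seed = 9L)
  panel <- simulatePanel(cfg)
  pa <- panel@ancestralFreqs
  d2 <- (panel@breedFreqs["P", ] - panel@breedFreqs["Q", ])^2
  # E[(p1 - p2)^2] = 2 F pa (1 - pa) for independent draws at the same F
  resid <- d2 - 2 * 0.2 * pa * (1 - pa)
  se <- sd(resid) / sqrt(length(resid))
  expect_lt(abs(mean(resid)), 3 * se)
})

test_that("empirical allele frequencies recover the founder frequencies", {
  cfg <- simConfig(nMarkers = 400L, nChromosomes = 1L,
    breeds = data.frame(name = "B1", nRefHaplotypes = 2000L,
                        nTestIndividuals = 0L, fst = 0.1),
    admixedSamples = data.frame(name = character(0)), seed = 13L)
  panel <- simulatePanel(cfg)
  emp <- colMeans(alleles(panel))
  truth <- panel@founderFreqs["B1", ]
  mid <- truth >= 0.1 & truth <= 0.9
  expect_true(any(mid))
  expect_lt(max(abs(emp[mid] - truth[mid])), 0.05)
})

test_that("linkage disequilibrium decays with marker distance", {
  cfg <- simConfig(nMarkers = 500L, nChromosomes = 1L,
    breeds = data.frame(name = "B1", nRefHaplotypes = 400L,
                        nTestIndividuals = 0L, fst = 0.1),
    nFoundersPerBreed = 10L, mosaicSwitchRate = 0.01,
    admixedSamples = data.frame(name = character(0)), seed = 17L)
  panel <- simulatePanel(cfg)
  H <- alleles(panel)
  f <- colMeans(H)
  poly <- which(f > 0.05 & f < 0.95)
  r2Bin <- function(lo, hi) {
    vals <- c()
    for (d in seq(lo, hi, by = max(1L, (hi - lo) %/% 5L))) {
      i <- poly[(poly + d) %in% poly]
      vals <- c(vals, vapply(i, function(j) cor(H[, j], H[, j + d])^2,
                             numeric(1)))
    }
    mean(vals)
  }
  vals <- c(r2Bin(1L, 5L), r2Bin(20L, 40L), r2Bin(100L, 150L),
            r2Bin(300L, 450L))
  expect_true(all(diff(vals) <= 0))
})

test_that("assay selection rules produce the intended marker subsets", {
  panel <- smallSimPanel(seed = 21L, nMarkers = 500L, nChrom = 1L)
  assays <- defineAssays(panel, data.frame(
    name = c("HD", "F250", "NEST", "FULLNEST"),
    count = c(400L, 150L, 60L, 400L),
    rule = c("common-evenly-spaced", "rare-enriched",
             "nested-subset-of", "nested-subset-of"),
    parent = c(NA, "HD", "HD", "HD"),
    overlap = c(NA, 50L, NA, NA)), seed = 2L)
  maf <- panelMaf(panel)

  # nested with target = parent count reproduces the parent exactly
  expect_identical(assayMarkers(assays$FULLNEST), assayMarkers(assays$HD))
  # nested subsets stay inside their parent
  expect_true(all(assayMarkers(assays$NEST) %in% assayMarkers(assays$HD)))
  # the rare-enriched assay shares its overlap block with the parent
  expect_gte(length(intersect(assayMarkers(assays$F250),
                              assayMarkers(assays$HD))), 50L)
  # rare-shifted MAF spectrum relative to the common assay
  expect_lt(median(maf[assayMarkers(assays$F250)]),
            median(maf[assayMarkers(assays$HD)]))
  # stochastic dominance toward zero (one-sided rank test)
  wt <- wilcox.test(maf[assayMarkers(assays$F250)],
                    maf[assayMarkers(assays$HD)], alternative = "less")
  expect_lt(wt$p.value, 0.01)
  # undefined parent raises
  expect_error(defineAssays(panel, data.frame(
    name = "BAD", count = 10L, rule = "nested-subset-of",
    parent = "NOPE", overlap = NA)), "undefined parent")
})

test_that("published assay densities scale by simple proportion", {
  expect_identical(unname(scaledAssayCounts(75372L)),
                   c(639L, 1685L, 4437L, 7058L, 12545L))
})

test_that("genotyping error injection matches its nominal rate", {
  cfg <- simConfig(nMarkers = 1000L, nChromosomes = 1L,
    breeds = data.frame(name = "B1", nRefHaplotypes = 2000L,
                        nTestIndividuals = 0L, fst = 0.1),
    admixedSamples = data.frame(name = character(0)), seed = 23L)
  panel <- simulatePanel(cfg)
  full <- assayOf(panel@markerMap$id)
  truth <- calls(genotypeWithError(panel, full, rate = 0, seed = 1L))

  # rate 0: identical to truth
  expect_identical(truth, ImputeEval:::.panelGenotypes(panel))

  # rate 1: every genotype replaced by a different class
  g1 <- calls(genotypeWithError(panel, full, rate = 1, seed = 1L))
  expect_true(all(g1 != truth))

  # rate 0.002 on 1e6 genotypes: binomial 3-sigma band
  g <- genotypeWithError(panel, full, rate = 0.002, seed = 2L)
  n <- length(truth)
  expect_gte(n, 1e6)
  frac <- mean(calls(g) != truth)
  expect_lt(abs(frac - 0.002), 3 * sqrt(0.002 * 0.998 / n))
  # recorded error positions agree with the observed differences
  expect_identical(nrow(g@metadata$errors), sum(calls(g) != truth))
})
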