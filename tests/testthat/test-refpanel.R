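# Shared fixture: a two-breed simulated reference with assay pair.
refFixture <- local({
  panel <- simulatePanel(simConfig(
    nMarkers = 400L, nChromosomes = 2L,
    breeds = data.frame(name = c("B1", "B2", "B3"),
                        nRefHaplotypes = c(20L, 40L, 60L),
                        nTestIndividuals = 0L,
                        fst = c(0.1, 0.1, 0.12)),
    admixedSamples = data.frame(name = character(0)), seed = 83L))
  assays <- defineAssays(panel, data.frame(
    name = c("A", "B"), count = c(700L, 200L),
    rule = c("common-evenly-spaced", "rare-enriched"),
    parent = c(NA, "A"), overlap = c(NA, 100L)), seed = 1L)
  list(panel = panel, assays = assays)
})

test_that("breed panels restrict the reference to one breed", {
  panel <- refFixture$panel
  b2 <- buildBreedPanel(panel, "B2")
  expect_identical(nrow(alleles(b2)), 40L)
  expect_true(all(breedOf(b2) == "B2"))
  # identity when one breed covers everything
  only <- ImputeEval:::.subsetPanel(panel, samples = sampleIds(b2))
  expect_identical(alleles(buildBreedPanel(only, "B2")), alleles(only))
  expect_error(buildBreedPanel(panel, "NOPE"), "absent")
})

test_that("composite construction flags exactly the cross-imputed entries", {
  panel <- refFixture$panel
  as <- refFixture$assays
  groups <- assignAssayGroups(sampleIds(panel),
                              c(A = 0.3, B = 0.5, AB = 0.2), seed = 3L)
  pp <- panelPair(panel, as$A, as$B, groups)
  comp <- buildCompositeOneRound(pp, hmmParams(maxReferenceHaplotypes = 500L),
                                 seed = 4L)
  prov <- provenance(comp)
  u <- unionMarkers(pp)
  bExcl <- setdiff(assayMarkers(as$B), assayMarkers(as$A))
  aExcl <- setdiff(assayMarkers(as$A), assayMarkers(as$B))
  for (smp in names(groups)[groups == "A"][1:3]) {
    rows <- ImputeEval:::.hapRows(comp, smp)
    expect_true(all(prov[rows, bExcl] == "cross-imputed"))
    expect_true(all(prov[rows, setdiff(u, bExcl)] == "observed"))
  }
  # overlap samples are fully observed
  for (smp in names(groups)[groups == "AB"][1:3]) {
    rows <- ImputeEval:::.hapRows(comp, smp)
    expect_true(all(prov[rows, ] == "observed"))
  }
  # observed entries bit-equal the input panel
  sub <- ImputeEval:::.subsetPanel(panel, markers = u)
  expect_identical(alleles(comp)[prov == "observed"],
                   alleles(sub)[prov == "observed"])
})

test_that("composite construction requires a sample bridge", {
  panel <- refFixture$panel
  as <- refFixture$assays
  groups <- setNames(rep(c("A", "B"), length.out = length(sampleIds(panel))),
                     sampleIds(panel))
  pp <- panelPair(panel, as$A, as$B, groups)
  expect_error(buildCompositeOneRound(pp), "overlap")
  # all-overlap input is returned unchanged
  groupsAB <- setNames(rep("AB", length(sampleIds(panel))), sampleIds(panel))
  ppAB <- panelPair(panel, as$A, as$B, groupsAB)
  comp <- buildCompositeOneRound(ppAB)
  expect_true(all(provenance(comp) == "observed"))
  expect_identical(alleles(comp),
                   alleles(ImputeEval:::.subsetPanel(panel,
                                                     markers = unionMarkers(ppAB))))
})

test_that("cross-imputed entries recover truth at most common markers", {
  # 50 overlap samples bridge the assays
  panel <- simulatePanel(simConfig(
    nMarkers = 500L, nChromosomes = 1L,
    breeds = data.frame(name = c("B1", "B2"),
                        nRefHaplotypes = c(120L, 80L),
                        nTestIndividuals = 0L, fst = c(0.1, 0.12)),
    nFoundersPerBreed = 10L,
    admixedSamples = data.frame(name = character(0)), seed = 89L))
  assays <- defineAssays(panel, data.frame(
    name = c("A", "B"), count = c(450L, 200L),
    rule = c("common-evenly-spaced", "rare-enriched"),
    parent = c(NA, "A"), overlap = c(NA, 120L)), seed = 1L)
  n <- length(sampleIds(panel))
  groups <- assignAssayGroups(sampleIds(panel), c(A = 0.25, B = 0.25, AB = 0.5),
                              seed = 2L)
  expect_identical(sum(groups == "AB"), 50L)
  pp <- panelPair(panel, assays$A, assays$B, groups)
  comp <- buildCompositeOneRound(pp, hmmParams(maxReferenceHaplotypes = 500L),
                                 seed = 3L)
  prov <- provenance(comp)
  truth <- alleles(ImputeEval:::.subsetPanel(panel, markers = unionMarkers(pp)))
  maf <- panelMaf(panel)[unionMarkers(pp)]
  common <- names(maf)[maf >= 0.05]
  ci <- prov[, common, drop = FALSE] == "cross-imputed"
  acc <- mean(alleles(comp)[, common][ci] == truth[, common][ci])
  expect_gt(acc, 0.95)
})

test_that("two-round and one-round cover the union and agree on typed markers", {
  panel <- refFixture$panel
  as <- refFixture$assays
  groups <- assignAssayGroups(sampleIds(panel),
                              c(A = 0.3, B = 0.5, AB = 0.2), seed = 5L)
  # hold three samples out as test
  testIds <- sampleIds(panel)[1:3]
  refIds <- setdiff(sampleIds(panel), testIds)
  refPanel <- ImputeEval:::.subsetPanel(panel, samples = refIds,
                                        markers = unionMarkers(
                                          panelPair(panel, as$A, as$B,
                                                    groups)))
  pp <- panelPair(refPanel, as$A, as$B, groups[refIds])
  g <- genotypeWithError(panel, assayOf(unionMarkers(pp)), rate = 0, seed = 1)
  gm <- makeGm(calls(g)[testIds, , drop = FALSE], map = g@markerMap)
  snp <- assayOf(assayMarkers(as$A)[seq(1, 700, by = 10)], "SNP")
  m <- maskToAssay(gm, snp, panel = panel)
  params <- hmmParams(maxReferenceHaplotypes = 500L)
  comp <- buildCompositeOneRound(pp, params, seed = 6L)
  one <- runOneRound(m, comp, params, seed = 7L)
  two <- runTwoRound(m, pp, params, seed = 7L)
  u <- unionMarkers(pp)
  expect_identical(colnames(dosage(one)), u)
  expect_identical(colnames(dosage(two)), u)
  # exact agreement at test-assay markers (observed pass-through)
  typed <- assayMarkers(snp)
  expect_identical(bestGuess(one)[, typed], bestGuess(two)[, typed])
  expect_true(all(provenance(one)[, typed] == "observed"))
  expect_identical(unname(bestGuess(one)[, typed]), unname(calls(gm)[, typed]))
})

test_that("two-round reduces to a single A-round when B adds no markers", {
  panel <- refFixture$panel
  as <- refFixture$assays
  aOnly <- as$A
  bNested <- new("AssayDefinition", name = "Bn",
                 markerIds = assayMarkers(as$A)[1:100], rule = "manual",
                 parent = NA_character_)
  testIds <- sampleIds(panel)[1:2]
  refIds <- setdiff(sampleIds(panel), testIds)
  refPanel <- ImputeEval:::.subsetPanel(panel, samples = refIds,
                                        markers = assayMarkers(aOnly))
  groups <- setNames(rep("AB", length(refIds)), refIds)
  pp <- panelPair(refPanel, aOnly, bNested, groups)
  g <- genotypeWithError(panel, aOnly, rate = 0, seed = 1)
  gm <- makeGm(calls(g)[testIds, , drop = FALSE], map = g@markerMap)
  snp <- assayOf(assayMarkers(aOnly)[seq(1, 700, by = 10)], "SNP")
  m <- maskToAssay(gm, snp, panel = panel)
  params <- hmmParams(maxReferenceHaplotypes = 500L)
  two <- runTwoRound(m, pp, params, seed = 8L)
  single <- imputeSamples(m, refPanel, params, seed = 8L)
  expect_equal(dosage(two), dosage(single))
  expect_identical(bestGuess(two), bestGuess(single))
})
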