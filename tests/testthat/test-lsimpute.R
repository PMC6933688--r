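test_that("forward-backward matches exhaustive path enumeration (K=2, M=3)", {
  H <- matrix(c(0L, 1L, 1L,
                1L, 0L, 1L), nrow = 2, byrow = TRUE)
  ref <- makePanel(H)  # exactly 2 haplotypes (one sample)
  obs <- c(0L, 0L, 1L)
  params <- hmmParams(switchRate = 0.1, emissionError = 0.05)
  got <- imputeHaploid(obs, ref@markerMap$id, ref, params, details = TRUE)
  oracle <- pathSumPosterior(H, 1:3, obs, 0.1, 0.05)
  expect_lt(max(abs(got$gamma[["1"]] - oracle$gamma)), 1e-10)
  expect_lt(max(abs(unname(got$posterior) - oracle$dosage)), 1e-10)
})

test_that("state posteriors are normalized at every typed site", {
  set.seed(53)
  H <- matrix(rbinom(40 * 30, 1, 0.5), nrow = 40)
  ref <- makePanel(H)
  obs <- rbinom(10, 1, 0.5)
  typed <- ref@markerMap$id[seq(1, 30, by = 3)]
  got <- imputeHaploid(as.integer(obs), typed, ref, hmmParams(), details = TRUE)
  sums <- rowSums(got$gamma[["1"]])
  expect_lt(max(abs(sums - 1)), 1e-9)
})

test_that("a target copying one reference haplotype tracks it closely", {
  set.seed(59)
  K <- 10
  H <- matrix(rbinom(K * 60, 1, 0.5), nrow = K)
  ref <- makePanel(H)
  typed <- ref@markerMap$id[seq(1, 60, by = 2)]
  target <- H[4, seq(1, 60, by = 2)]
  params <- hmmParams(switchRate = 0.01, emissionError = 0.002)
  post <- imputeHaploid(as.integer(target), typed, ref, params)
  expect_lt(max(abs(post - H[4, ])), 0.05)
})

test_that("uninformative observations collapse to the reference frequency", {
  set.seed(61)
  H <- matrix(rbinom(8 * 20, 1, 0.4), nrow = 8)
  ref <- makePanel(H)
  typed <- ref@markerMap$id[1:10]
  # missing target alleles give uniform emissions exactly
  post <- imputeHaploid(rep(NA_integer_, 10), typed, ref, hmmParams())
  expect_lt(max(abs(post - colMeans(H))), 1e-12)
  # near-uninformative emissions with switch rate (K-1)/K approach it too
  params <- hmmParams(switchRate = 7 / 8, emissionError = 0.4999999)
  post2 <- imputeHaploid(H[1, 1:10], typed, ref, params)
  expect_lt(max(abs(post2 - colMeans(H))), 1e-4)
})

test_that("reference subsampling is breed-stratified and respects the cap", {
  set.seed(67)
  H <- matrix(rbinom(200 * 10, 1, 0.5), nrow = 200)
  breeds <- rep(c("P", "Q"), c(75, 25))
  ref <- makePanel(H, breeds = breeds)
  sub <- ImputeEval:::.subsampleReference(ref, 40L, seed = 1L)
  expect_identical(nrow(alleles(sub)), 40L)
  tb <- table(breedOf(sub))
  expect_identical(unname(tb[["P"]]), 15L)  # 75% of 20 samples
  expect_identical(unname(tb[["Q"]]), 5L)
})

test_that("samples copying reference haplotypes are imputed error-free", {
  set.seed(71)
  K <- 40
  M <- 200
  # reference with block structure so haplotypes are distinguishable
  H <- matrix(rbinom(K * M, 1, 0.5), nrow = K)
  refPanel <- makePanel(H)
  # two test samples whose haplotypes are verbatim reference copies
  testH <- H[c(3, 17, 8, 25), ]
  testPanel <- makePanel(testH)
  g <- genotypeWithError(testPanel, assayOf(testPanel@markerMap$id),
                         rate = 0, seed = 1)
  assay <- assayOf(testPanel@markerMap$id[seq(1, M, by = 4)], "SUB")
  m <- maskToAssay(g, assay, panel = testPanel)
  res <- imputeSamples(m, refPanel, hmmParams(emissionError = 0.002), seed = 2)
  wh <- m@withheldMarkerIds
  expect_identical(sum(bestGuess(res)[, wh] != calls(m@truth)[, wh]), 0L)
})

test_that("full-assay input passes through as observed", {
  panel <- smallSimPanel(seed = 73L)
  ids <- panel@markerMap$id
  g <- genotypeWithError(panel, assayOf(ids), rate = 0, seed = 1)
  test <- sampleIds(panel)[1:3]
  gm <- makeGm(calls(g)[test, , drop = FALSE], map = g@markerMap)
  m <- maskToAssay(gm, assayOf(ids), panel = panel)
  ref <- ImputeEval:::.subsetPanel(panel, samples = sampleIds(panel)[-(1:3)])
  res <- imputeSamples(m, ref, hmmParams(maxReferenceHaplotypes = 300L))
  expect_true(all(provenance(res) == "observed"))
  expect_identical(unname(bestGuess(res)), unname(calls(gm)))
  expect_equal(unname(dosage(res)), unname(calls(gm)))
})

test_that("dosage ties at x.5 are called toward the heterozygote", {
  bg <- ImputeEval:::.bestGuessFromDosage(c(0, 0.4, 0.5, 0.9, 1.5, 1.6, 2))
  expect_identical(bg, c(0L, 0L, 1L, 1L, 1L, 2L, 2L))
})

test_that("switch-error phasing mode perturbs phase but not genotypes", {
  panel <- smallSimPanel(seed = 79L)
  ids <- panel@markerMap$id
  g <- genotypeWithError(panel, assayOf(ids), rate = 0, seed = 1)
  test <- sampleIds(panel)[1:4]
  gm <- makeGm(calls(g)[test, , drop = FALSE], map = g@markerMap)
  assay <- assayOf(ids[seq(1, length(ids), by = 5)], "SUB")
  m <- maskToAssay(gm, assay, panel = panel)
  ref <- ImputeEval:::.subsetPanel(panel, samples = setdiff(sampleIds(panel), test))
  r1 <- imputeSamples(m, ref, hmmParams(maxReferenceHaplotypes = 300L),
                      phaseMode = "truth-phase", seed = 5)
  r2 <- imputeSamples(m, ref, hmmParams(maxReferenceHaplotypes = 300L),
                      phaseMode = "switch-error", switchErrorRate = 0.2,
                      seed = 5)
  # observed entries identical either way
  obsIdx <- provenance(r1) == "observed"
  expect_identical(bestGuess(r1)[obsIdx], bestGuess(r2)[obsIdx])
  # imputed dosages differ somewhere once phase is perturbed
  expect_false(identical(dosage(r1), dosage(r2)))
})

test_that("degenerate inputs are rejected", {
  H <- matrix(c(0L, 1L), nrow = 2, ncol = 4)
  ref <- makePanel(H)
  expect_error(imputeHaploid(integer(0), character(0), ref, hmmParams()),
               "zero markers")
  expect_error(imputeHaploid(2L, ref@markerMap$id[1], ref, hmmParams()),
               "allele codes")
  expect_error(hmmParams(switchRate = 0), "switchRate")
  expect_error(hmmParams(emissionError = 0.5), "emissionError")
})
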