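test_that("error taxonomy follows the genotype-class definitions", {
  expect_identical(as.character(classifyErrors(0L, 1L)), "false_het")
  expect_identical(as.character(classifyErrors(2L, 1L)), "false_het")
  expect_identical(as.character(classifyErrors(1L, 2L)), "false_hom")
  expect_identical(as.character(classifyErrors(1L, 0L)), "false_hom")
  expect_identical(as.character(classifyErrors(0L, 2L)), "discordant")
  expect_identical(as.character(classifyErrors(2L, 0L)), "discordant")
  expect_identical(as.character(classifyErrors(1L, 1L)), "correct")
  expect_error(classifyErrors(NA_integer_, 1L), "missing")
})

test_that("IQS matches hand computations and the constant-column algebra", {
  # perfect agreement with >= 2 classes present
  expect_equal(iqs(c(0L, 1L, 2L, 1L), c(0L, 1L, 2L, 1L)), 1)
  # imputed all-0 against truth 46x0 + 3x1: concordant but worthless
  truth <- c(rep(0L, 46), rep(1L, 3))
  imp <- rep(0L, 49)
  expect_equal(sum(truth == imp) / 49, 46 / 49, tolerance = 1e-12)
  expect_equal(iqs(truth, imp), 0)
  # hand-computed mixed table: P0 = 0.9, Pc = 0.49, IQS = 0.41/0.51
  tab <- matrix(c(6, 0, 0,
                  1, 2, 0,
                  0, 0, 1), nrow = 3, byrow = TRUE)
  expect_equal(iqsFromTable(tab), 0.41 / 0.51, tolerance = 1e-12)
  # both sides constant and identical
  expect_equal(iqs(rep(2L, 5), rep(2L, 5)), 1)
  # IQS can go negative (systematic disagreement)
  expect_lt(iqs(c(0L, 0L, 2L, 2L), c(2L, 2L, 0L, 0L)), 0)
})

test_that("IQS equals the independent kappa oracle on random tables", {
  set.seed(97)
  for (i in 1:200) {
    tab <- randomTable()
    expect_equal(iqsFromTable(tab), kappaOracle(tab), tolerance = 1e-12)
  }
})

test_that("IQS never exceeds concordance", {
  set.seed(101)
  for (i in 1:500) {
    tab <- matrix(rpois(9, sample(1:6, 1)), 3, 3)
    if (sum(tab) == 0) next
    P0 <- sum(diag(tab)) / sum(tab)
    expect_lte(iqsFromTable(tab), P0 + 1e-12)
  }
})

test_that("Pearson r handles centering and degenerate vectors", {
  expect_equal(pearsonR(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(pearsonR(c(0, 1, 2, 1), c(0, 1, 1, 1)), 1 / sqrt(1.5),
               tolerance = 1e-12)
  expect_true(is.na(pearsonR(c(0, 0, 0), c(0, 1, 0))))
  expect_error(pearsonR(c(0, 1), c(1, 0), "maf-centered"), "MAF")
  # centering by per-position MAF changes r (not a constant shift)
  x <- c(0, 1, 2, 0, 1); y <- c(0, 1, 1, 0, 2)
  maf <- c(0.05, 0.3, 0.5, 0.1, 0.2)
  expect_false(isTRUE(all.equal(pearsonR(x, y),
                                pearsonR(x, y, "maf-centered", maf = maf))))
})

# A small end-to-end scoring fixture built by hand: 4 samples, 6 markers,
# 2 of them observed, 4 withheld.
scoringFixture <- function(withErrors = FALSE) {
  truthCalls <- rbind(c(0L, 1L, 2L, 1L, 0L, 2L),
                      c(1L, 1L, 0L, 0L, 0L, 2L),
                      c(2L, 0L, 1L, 1L, 0L, 2L),
                      c(0L, 2L, 2L, 1L, 0L, 2L))
  truth <- makeGm(truthCalls)
  best <- truthCalls
  if (withErrors) {
    best[1, 3] <- 1L  # truth 2 -> false het
    best[2, 4] <- 2L  # truth 0 -> discordant... (0 -> 2)
    best[3, 4] <- 0L  # truth 1 -> false hom
  }
  prov <- matrix("imputed", 4, 6)
  prov[, 1:2] <- "observed"
  res <- new("ImputationResult",
             dosage = matrix(as.numeric(best), 4, 6,
                             dimnames = dimnames(truth@calls)),
             bestGuess = matrix(best, 4, 6, dimnames = dimnames(truth@calls)),
             provenance = matrix(prov, 4, 6, dimnames = dimnames(truth@calls)),
             markerMap = truth@markerMap)
  maf <- computeMaf(truth)
  list(truth = truth, res = res, maf = maf)
}

test_that("perfect imputation scores perfectly at every level", {
  fx <- scoringFixture(withErrors = FALSE)
  va <- perVariantAccuracy(fx$truth, fx$res, fx$maf)
  expect_identical(va$marker, paste0("m00", 3:6))  # only withheld markers
  expect_true(all(va$concordance == 1))
  expect_true(all(va$iqs == 1))
  expect_true(all(va$n_errors == 0L))
  vi <- perIndividualAccuracy(fx$truth, fx$res, fx$maf)
  expect_true(all(vi$total_errors == 0L))
})

test_that("injected errors are classified, counted and conserved", {
  fx <- scoringFixture(withErrors = TRUE)
  va <- perVariantAccuracy(fx$truth, fx$res, fx$maf)
  m3 <- va[va$marker == "m003", ]
  expect_identical(m3$n_false_het, 1L)
  m4 <- va[va$marker == "m004", ]
  expect_identical(m4$n_false_hom, 1L)
  expect_identical(m4$n_discordant, 1L)
  # conservation per variant
  expect_true(all(va$n_correct + va$n_errors == va$n_compared))
  expect_equal(va$concordance, va$n_correct / va$n_compared)
  vi <- perIndividualAccuracy(fx$truth, fx$res, fx$maf)
  # per-variant and per-individual totals agree, by error type
  expect_identical(sum(va$n_errors), sum(vi$total_errors))
  expect_identical(sum(va$n_false_het), sum(vi$n_false_het))
  expect_identical(sum(va$n_false_hom), sum(vi$n_false_hom))
  expect_identical(sum(va$n_discordant), sum(vi$n_discordant))
  # iqs <= concordance marker-wise
  expect_true(all(va$iqs <= va$concordance + 1e-12))
})

test_that("MAF bins are half-open with a dedicated fixed bin", {
  b <- mafBin(c(0, 1e-6, 0.05, 0.0500001, 0.45, 0.4999, 0.5))
  expect_identical(as.character(b),
                   c("fixed", ">0.00-0.05", ">0.00-0.05", ">0.05-0.10",
                     ">0.40-0.45", ">0.45-0.50", ">0.45-0.50"))
})

test_that("region scan flags windows breaching the thresholds", {
  # 100 clean markers: no flags
  va <- data.frame(marker = sprintf("m%03d", 1:100), chrom = "1",
                   pos = 1:100 * 1000L, maf = 0.3,
                   maf_bin = ">0.25-0.30", n_compared = 50L,
                   n_correct = 50L, n_false_het = 0L, n_false_hom = 0L,
                   n_discordant = 0L, n_errors = 0L, concordance = 1,
                   iqs = 1, r = 1, stringsAsFactors = FALSE)
  rs <- regionScan(va)
  expect_false(any(rs$flagged))
  # 15 of the first 50 markers at IQS 0 -> 0.3 > 0.2, flagged
  va$iqs[1:15] <- 0
  rs <- regionScan(va)
  expect_true(rs$flagged[1])
  expect_false(any(rs$flagged[-1]))
  expect_identical(rs$n_breach[1], 15L)
  # error-count threshold works independently of IQS
  va$iqs <- 1
  va$n_errors[51:70] <- 11L
  rs <- regionScan(va)
  expect_true(rs$flagged[2])
})

test_that("panel comparison reproduces textbook paired statistics", {
  set.seed(103)
  va <- function(iqs) data.frame(marker = sprintf("m%02d", seq_along(iqs)),
                                 iqs = iqs, stringsAsFactors = FALSE)
  x <- round(runif(10, 0.5, 1), 3)
  y <- round(pmin(x + rnorm(10, 0.05, 0.05), 1), 3)
  cmp <- comparePanels(va(x), va(y))
  tt <- t.test(y, x, paired = TRUE)
  expect_equal(cmp$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(cmp$p_t, tt$p.value, tolerance = 1e-12)
  expect_equal(cmp$mean_diff, mean(y - x), tolerance = 1e-12)
  vt <- var.test(x, y)
  expect_equal(cmp$f, unname(vt$statistic), tolerance = 1e-12)
  expect_equal(cmp$p_f, vt$p.value, tolerance = 1e-12)
  # identical panels: zero difference, nothing improved or worsened
  cmp0 <- comparePanels(va(x), va(x))
  expect_equal(cmp0$mean_diff, 0)
  expect_identical(cmp0$n_improved, 0L)
  expect_identical(cmp0$n_worsened, 0L)
  # +0.1 on half the markers
  y2 <- x; y2[1:5] <- x[1:5] + 0.1
  cmp2 <- comparePanels(va(x), va(y2))
  expect_identical(cmp2$n_improved, 5L)
  expect_gt(cmp2$t, 0)
})
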