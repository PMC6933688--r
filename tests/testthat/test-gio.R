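test_that("VCF genotypes round-trip through write and read", {
  set.seed(31)
  cl <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 6)
  g <- makeGm(cl, nChrom = 2L)
  path <- tempfile(fileext = ".vcf")
  writeVCF(g, path)
  back <- readGenotypes(path, "vcf")
  expect_identical(unname(calls(back)), unname(calls(g)))
  expect_identical(rownames(calls(back)), rownames(calls(g)))
  expect_identical(markerMap(back)$id, markerMap(g)$id)
  expect_false(back@phased)
})

test_that("phased haplotype panels survive a VCF round-trip", {
  panel <- makePanel(matrix(rbinom(80, 1, 0.4), nrow = 8), nChrom = 2L)
  path <- tempfile(fileext = ".vcf")
  writeVCF(panel, path)
  back <- readGenotypes(path, "vcf")
  expect_true(back@phased)
  expect_identical(unname(calls(back)),
                   unname(ImputeEval:::.panelGenotypes(panel)))
})

test_that("heterozygous unphased GT parses to count 1, unphased flag", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\tm1\tA\tG\t.\tPASS\t.\tGT\t0/1"), path)
  g <- readGenotypes(path, "vcf")
  expect_identical(unname(calls(g)[1, 1]), 1L)
  expect_false(g@phased)
})

test_that("multi-allelic VCF records are rejected by marker id", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\tbadmarker\tA\tG,T\t.\tPASS\t.\tGT\t0/1"), path)
  expect_error(readGenotypes(path, "vcf"), "badmarker")
})

test_that("PED alleles are counted against the MAP declaration", {
  prefix <- tempfile()
  writeLines(c("1\tsite1\t0\t100\tA\tC",
               "1\tsite2\t0\t200\tT\tG",
               "1\tsite3\t0\t300\tA\tG"), paste0(prefix, ".map"))
  writeLines("FAM IND1 0 0 0 -9 A A G G 0 0", paste0(prefix, ".ped"))
  g <- readGenotypes(prefix, "plink-text")
  expect_identical(unname(calls(g)[1, ]), c(0L, 2L, NA))
  # malformed record names its line
  writeLines(c("FAM IND1 0 0 0 -9 A A G G 0 0",
               "FAM IND2 0 0 0 -9 A A G G"), paste0(prefix, ".ped"))
  expect_error(readGenotypes(prefix, "plink-text"), "line 2")
})

test_that("PLINK text genotypes round-trip including missing entries", {
  set.seed(37)
  cl <- matrix(sample(c(0:2, NA), 80, replace = TRUE, prob = c(.3,.3,.3,.1)),
               nrow = 8)
  g <- makeGm(cl)
  prefix <- tempfile()
  writePlink(g, prefix)
  back <- readGenotypes(prefix, "plink-text")
  expect_identical(unname(calls(back)), unname(calls(g)))
  expect_identical(markerMap(back)$id, markerMap(g)$id)
})

test_that("MAF is invariant to allele orientation and matches hand counts", {
  g <- makeGm(rbind(c(0L, 2L, 0L, 0L), c(0L, 2L, 1L, 1L),
                    c(0L, 2L, 1L, 2L), c(0L, 2L, 2L, 0L)))
  maf <- computeMaf(g)
  # fixed reference and fixed alternate both give MAF 0
  expect_equal(unname(maf[1]), 0)
  expect_equal(unname(maf[2]), 0)
  # counts (0,1,1,2): f = 4/8 = 0.5
  expect_equal(unname(maf[3]), 0.5)
  # orientation swap leaves MAF unchanged
  flipped <- makeGm(2L - calls(g))
  expect_equal(unname(computeMaf(flipped)), unname(maf))
  # all-missing marker errors
  gm <- calls(g); gm[, 4] <- NA
  expect_error(computeMaf(makeGm(gm)), "all-missing")
})

test_that("call-rate filtering removes below-threshold entities, strictly", {
  # complete matrix: unchanged, empty log
  g0 <- makeGm(matrix(1L, 5, 5))
  out <- qcFilter(g0)
  expect_identical(calls(out$genotypes), calls(g0))
  expect_identical(nrow(out$log), 0L)

  # marker with 2/10 missing (0.8) removed; 1/10 missing (0.9) kept
  cl <- matrix(1L, 10, 3)
  cl[1:2, 2] <- NA
  cl[1, 3] <- NA
  g <- makeGm(cl)
  out <- qcFilter(g, minCallRate = 0.90)
  expect_identical(colnames(calls(out$genotypes)), c("m001", "m003"))
  expect_true("m002" %in% out$log$entity)

  # non-autosomal markers removed before call-rate filtering
  cl <- matrix(1L, 4, 3)
  gx <- makeGm(cl, chrom = c("1", "1", "X"))
  out <- qcFilter(gx)
  expect_identical(ncol(calls(out$genotypes)), 2L)
  expect_identical(out$log$reason, "non-autosomal")

  # sample call rate computed on surviving markers
  cl <- matrix(1L, 10, 10)
  cl[1, 1:2] <- NA      # sample 1: 0.8 call rate
  g <- makeGm(cl)
  out <- qcFilter(g)
  expect_false("S001" %in% rownames(calls(out$genotypes)))
})

test_that("QC filtering is idempotent", {
  set.seed(41)
  cl <- matrix(sample(c(0:2, NA), 200, replace = TRUE,
                      prob = c(.28, .28, .28, .16)), nrow = 10)
  g <- makeGm(cl, nChrom = 2L)
  once <- qcFilter(g)
  twice <- qcFilter(once$genotypes)
  expect_identical(calls(twice$genotypes), calls(once$genotypes))
  expect_identical(nrow(twice$log), 0L)
})

test_that("fuzzed matrices round-trip through both formats", {
  set.seed(43)
  for (i in 1:5) {
    cl <- matrix(sample(c(0:2, NA), 48, replace = TRUE), nrow = 6)
    if (all(is.na(cl))) next
    g <- makeGm(cl)
    v <- tempfile(fileext = ".vcf"); writeVCF(g, v)
    expect_identical(unname(calls(readGenotypes(v, "vcf"))), unname(cl))
    p <- tempfile(); writePlink(g, p)
    expect_identical(unname(calls(readGenotypes(p, "plink-text"))), unname(cl))
  }
})
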