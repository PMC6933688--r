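## End-to-end experiment orchestration: simulate -> assays -> genotype ->
## QC -> split/mask -> build panels -> impute (strategies) -> score ->
## report. One global seed expands deterministically into per-stage seeds
## (stage-name hashing) so stages can be re-run in isolation.

#' Construct an end-to-end experiment configuration
#'
#' Defaults describe the desk-scale study: a six-breed panel of 5,000
#' markers on two chromosomes with ~600 reference samples, 60 purebred test
#' individuals and an admixed open-herdbook group; a common-variant assay
#' covering 90\% of the union marker set and a rare-enriched assay with a
#' 12\% shared block; five nested commercial-density assays at the
#' published density ratios; both reference-panel types and both
#' imputation strategies.
#'
#' @param sim a \linkS4class{SimConfig} (default \code{simConfig()}).
#' @param assaySpec assay specification data.frame (name, count, rule,
#'   parent, overlap); default derived from the simulated marker count.
#' @param masking list(maxPerBreed, maxBreedFraction); default caps 10 test
#'   individuals per breed.
#' @param hmm a \linkS4class{HmmParams}; the default raises the reference
#'   cap to cover the whole desk-scale panel (no subsampling), matching
#'   production imputation engines which use the full reference.
#' @param phaseMode "truth-phase" (default) or "switch-error".
#' @param switchErrorRate per-het switch probability for switch-error mode.
#' @param strategies subset of c("one-round:CR", "one-round:BR",
#'   "two-round:CR").
#' @param groupFractions reference genotyping-group fractions (A, B, AB).
#' @param maskAssay assay used for the panel and strategy comparisons
#'   (default "SNP50").
#' @param densityAssays nested assays for the starting-density sweep.
#' @param brBreed breed for the within-breed reference panel (default the
#'   dominant breed, which is also the admixed samples' majority ancestry).
#' @param seed global seed.
#' @return a validated \linkS4class{ExperimentConfig}.
#' @export
experimentConfig <- function(sim = simConfig(),
                             assaySpec = NULL,
                             masking = list(maxPerBreed = 10L,
                                            maxBreedFraction = 0.5),
                             hmm = hmmParams(maxReferenceHaplotypes = 4000L),
                             phaseMode = "truth-phase",
                             switchErrorRate = 0.02,
                             strategies = c("one-round:CR", "one-round:BR",
                                            "two-round:CR"),
                             groupFractions = c(A = 0.20, B = 0.72, AB = 0.08),
                             maskAssay = "SNP50",
                             densityAssays = c("ULD", "LD", "SNP50",
                                               "GGP90K", "GGPHD"),
                             brBreed = "B1",
                             seed = 1L) {
  if (is.null(assaySpec)) {
    M <- sim@nMarkers * sim@nChromosomes
    hd <- round(0.9 * M)
    nested <- scaledAssayCounts(hd)
    assaySpec <- rbind(
      data.frame(name = "HD", count = hd, rule = "common-evenly-spaced",
                 parent = NA_character_, overlap = NA_integer_),
      data.frame(name = "F250", count = round(0.2 * M), rule = "rare-enriched",
                 parent = "HD", overlap = as.integer(round(0.12 * M))),
      data.frame(name = names(nested), count = as.integer(nested),
                 rule = "nested-subset-of", parent = "HD",
                 overlap = NA_integer_)
    )
  }
  new("ExperimentConfig", sim = sim, assaySpec = assaySpec, masking = masking,
      hmm = hmm, phaseMode = phaseMode, switchErrorRate = switchErrorRate,
      strategies = strategies, groupFractions = groupFractions,
      maskAssay = maskAssay, densityAssays = densityAssays,
      brBreed = brBreed, seed = as.integer(seed))
}

## Serialize a configuration to a plain list (for the YAML manifest).
.configAsList <- function(cfg) {
  s <- cfg@sim
  list(
    sim = list(nMarkers = s@nMarkers, nChromosomes = s@nChromosomes,
               breeds = as.list(s@breeds),
               nFoundersPerBreed = s@nFoundersPerBreed,
               mosaicSwitchRate = s@mosaicSwitchRate,
               founderWeightRatio = s@founderWeightRatio,
               migrationRate = s@migrationRate,
               admixedSamples = as.list(s@admixedSamples),
               sfsBounds = s@sfsBounds,
               genotypeErrorRate = s@genotypeErrorRate, seed = s@seed),
    assaySpec = as.list(cfg@assaySpec),
    masking = cfg@masking,
    hmm = list(switchRate = cfg@hmm@switchRate,
               emissionError = cfg@hmm@emissionError,
               maxReferenceHaplotypes = cfg@hmm@maxReferenceHaplotypes),
    phaseMode = cfg@phaseMode, switchErrorRate = cfg@switchErrorRate,
    strategies = cfg@strategies,
    groupFractions = as.list(cfg@groupFractions),
    maskAssay = cfg@maskAssay, densityAssays = cfg@densityAssays,
    brBreed = cfg@brBreed, seed = cfg@seed)
}

#' Read an experiment configuration from a YAML document
#'
#' Keys mirror \code{\link{experimentConfig}} arguments; missing keys fall
#' back to the defaults.
#'
#' @param path YAML file path.
#' @return an \linkS4class{ExperimentConfig}.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  simArgs <- y$sim
  if (!is.null(simArgs$breeds)) simArgs$breeds <- as.data.frame(simArgs$breeds)
  if (!is.null(simArgs$admixedSamples))
    simArgs$admixedSamples <- as.data.frame(simArgs$admixedSamples)
  sim <- do.call(simConfig, simArgs %||% list())
  args <- list(sim = sim)
  for (k in c("masking", "phaseMode", "switchErrorRate", "strategies",
              "maskAssay", "densityAssays", "brBreed", "seed"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$assaySpec)) args$assaySpec <- as.data.frame(y$assaySpec)
  if (!is.null(y$groupFractions)) args$groupFractions <- unlist(y$groupFractions)
  if (!is.null(y$hmm)) args$hmm <- do.call(hmmParams, y$hmm)
  do.call(experimentConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stageMsg <- function(log, stage, seed, t0) {
  c(log, sprintf("%s\tseed=%d\telapsed=%.2fs", stage, seed,
                 as.numeric(proc.time()[3] - t0)))
}

#' Run an end-to-end imputation-accuracy experiment
#'
#' Executes every stage of the evaluation pipeline and (optionally) writes
#' all artifacts: masked and imputed VCFs, per-variant and per-individual
#' reports, MAF-binned tables, panel and strategy comparisons, the
#' low-accuracy region scan, the GRM similarity report, and a
#' machine-readable manifest (config, per-stage seeds, package version,
#' config hash). Re-running with the same configuration reproduces every
#' numeric output exactly.
#'
#' @param cfg an \linkS4class{ExperimentConfig}.
#' @param outDir output directory for artifacts, or \code{NULL} to skip
#'   writing.
#' @param verbose print stage progress (default FALSE).
#' @return invisible list: panel, assays, genotypes, maf, split, panelPair,
#'   composite, maskAssay results per strategy (per-variant and
#'   per-individual tables), panelComparison, roundsComparison, density
#'   sweep tables, regionScan, grm, similarity, log.
#' @export
runExperiment <- function(cfg, outDir = NULL, verbose = FALSE) {
  validObject(cfg)
  t0 <- proc.time()[3]
  log <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  fail <- function(stage, e) stop("stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  ## -- simulate -------------------------------------------------------------
  sSeed <- stageSeed(cfg@seed, "simulate")
  sim <- cfg@sim; sim@seed <- sSeed
  panel <- tryCatch(simulatePanel(sim), error = function(e) fail("simulate", e))
  log <- .stageMsg(log, "simulate", sSeed, t0); say("simulated panel")

  ## -- assays ---------------------------------------------------------------
  aSeed <- stageSeed(cfg@seed, "assays")
  assays <- tryCatch(defineAssays(panel, cfg@assaySpec, seed = aSeed),
                     error = function(e) fail("assays", e))
  log <- .stageMsg(log, "assays", aSeed, t0)

  nameA <- cfg@assaySpec$name[match("common-evenly-spaced", cfg@assaySpec$rule)]
  nameB <- cfg@assaySpec$name[match("rare-enriched", cfg@assaySpec$rule)]
  if (is.na(nameA) || is.na(nameB))
    fail("assays", simpleError("config needs one common-evenly-spaced and one rare-enriched assay"))

  ## -- genotype (research-assay calls with error) ---------------------------
  gSeed <- stageSeed(cfg@seed, "genotype")
  unionIds <- union(assays[[nameA]]@markerIds, assays[[nameB]]@markerIds)
  unionIds <- panel@markerMap$id[panel@markerMap$id %in% unionIds]
  unionAssay <- new("AssayDefinition", name = "UNION", markerIds = unionIds,
                    rule = "manual", parent = NA_character_)
  g <- tryCatch(genotypeWithError(panel, unionAssay,
                                  rate = sim@genotypeErrorRate, seed = gSeed),
                error = function(e) fail("genotype", e))
  log <- .stageMsg(log, "genotype", gSeed, t0)

  ## -- QC -------------------------------------------------------------------
  qc <- tryCatch(qcFilter(g), error = function(e) fail("qc", e))
  g <- qc$genotypes
  maf <- computeMaf(g)
  log <- .stageMsg(log, "qc", 0L, t0)

  ## -- test/reference split -------------------------------------------------
  mSeed <- stageSeed(cfg@seed, "mask")
  split <- tryCatch(
    selectTestIndividuals(g, breedOf(panel),
                          maxPerBreed = cfg@masking$maxPerBreed,
                          maxBreedFraction = cfg@masking$maxBreedFraction,
                          seed = mSeed),
    error = function(e) fail("split", e))
  log <- .stageMsg(log, "split", mSeed, t0)

  gTest <- .newGenotypeMatrix(g@calls[split$test, , drop = FALSE],
                              g@markerMap, phased = FALSE)
  truthBreeds <- breedOf(panel)

  ## -- reference panel pair and composite -----------------------------------
  pSeed <- stageSeed(cfg@seed, "panel")
  refPanel <- .subsetPanel(panel, samples = split$reference,
                           markers = unionIds)
  groups <- assignAssayGroups(split$reference, cfg@groupFractions,
                              seed = pSeed)
  pp <- panelPair(refPanel, assays[[nameA]], assays[[nameB]], groups)
  composite <- tryCatch(buildCompositeOneRound(pp, cfg@hmm, seed = pSeed),
                        error = function(e) fail("composite", e))
  log <- .stageMsg(log, "composite", pSeed, t0); say("composite built")

  ## -- strategy runs on the comparison assay --------------------------------
  iSeed <- stageSeed(cfg@seed, "impute")
  mask <- maskToAssay(gTest, assays[[cfg@maskAssay]], panel = panel)
  runs <- list()
  for (strat in cfg@strategies) {
    res <- tryCatch(switch(strat,
      "one-round:CR" = runOneRound(mask, composite, cfg@hmm,
                                   phaseMode = cfg@phaseMode,
                                   switchErrorRate = cfg@switchErrorRate,
                                   seed = iSeed),
      "one-round:BR" = runOneRound(mask,
                                   buildBreedPanel(composite, cfg@brBreed),
                                   cfg@hmm, phaseMode = cfg@phaseMode,
                                   switchErrorRate = cfg@switchErrorRate,
                                   seed = iSeed),
      "two-round:CR" = runTwoRound(mask, pp, cfg@hmm,
                                   phaseMode = cfg@phaseMode,
                                   switchErrorRate = cfg@switchErrorRate,
                                   seed = iSeed)),
      error = function(e) fail(strat, e))
    va <- perVariantAccuracy(mask@truth, res, maf)
    vi <- perIndividualAccuracy(mask@truth, res, maf, breedOf = truthBreeds)
    runs[[strat]] <- list(result = res, va = va, vi = vi,
                          binned = binnedAccuracy(va))
    log <- .stageMsg(log, strat, iSeed, t0); say("ran %s", strat)
  }

  panelComparison <- NULL
  if (all(c("one-round:CR", "one-round:BR") %in% names(runs)))
    panelComparison <- comparePanels(runs[["one-round:BR"]]$va,
                                     runs[["one-round:CR"]]$va)
  roundsComparison <- NULL
  if (all(c("one-round:CR", "two-round:CR") %in% names(runs)))
    roundsComparison <- comparePanels(runs[["two-round:CR"]]$va,
                                      runs[["one-round:CR"]]$va)

  ## -- starting-density sweep (one-round CR) --------------------------------
  density <- list()
  if (length(cfg@densityAssays)) {
    for (an in cfg@densityAssays) {
      dm <- maskToAssay(gTest, assays[[an]], panel = panel)
      res <- runOneRound(dm, composite, cfg@hmm, phaseMode = cfg@phaseMode,
                         switchErrorRate = cfg@switchErrorRate, seed = iSeed)
      va <- perVariantAccuracy(dm@truth, res, maf)
      vi <- perIndividualAccuracy(dm@truth, res, maf, breedOf = truthBreeds)
      density[[an]] <- list(va = va, vi = vi, binned = binnedAccuracy(va),
                            assaySize = length(assays[[an]]@markerIds))
      log <- .stageMsg(log, paste0("density:", an), iSeed, t0)
      say("density sweep: %s", an)
    }
    ## markers withheld under every density (not on the densest assay):
    ## the clean within-run comparison set
    densest <- cfg@densityAssays[which.max(vapply(density, `[[`,
                                                  numeric(1), "assaySize"))]
    common <- setdiff(unionIds, assays[[densest]]@markerIds)
    density$sweep <- do.call(rbind, lapply(cfg@densityAssays, function(an) {
      va <- density[[an]]$va
      va <- va[va$marker %in% common, ]
      data.frame(assay = an, assay_size = density[[an]]$assaySize,
                 n_markers = nrow(va), mean_iqs = mean(va$iqs, na.rm = TRUE),
                 mean_iqs_low_maf = mean(va$iqs[va$maf < 0.1], na.rm = TRUE),
                 mean_concordance = mean(va$concordance),
                 stringsAsFactors = FALSE)
    }))
  }

  ## -- region scan on the comparison run ------------------------------------
  scanVa <- if ("one-round:CR" %in% names(runs)) runs[["one-round:CR"]]$va
            else runs[[1]]$va
  regions <- regionScan(scanVa)
  log <- .stageMsg(log, "region-scan", 0L, t0)

  ## -- GRM and reference similarity -----------------------------------------
  grm <- standardizedGRM(g)
  simTab <- data.frame(
    sample = split$test,
    breed = unname(truthBreeds[split$test]),
    similarity_all = similarityToReference(grm, split$test, split$reference),
    stringsAsFactors = FALSE)
  bySample <- setNames(vapply(split$test, function(s) {
    b <- truthBreeds[[s]]
    if (b == "Admixed" || !b %in% truthBreeds[split$reference]) NA_real_
    else similarityToReference(grm, s, split$reference, breed = b,
                               breedOf = truthBreeds)
  }, numeric(1)), split$test)
  simTab$similarity_breed <- unname(bySample)
  if ("one-round:CR" %in% names(runs)) {
    vi <- runs[["one-round:CR"]]$vi
    simTab$r_raw <- vi$r_raw[match(simTab$sample, vi$sample)]
  }
  log <- .stageMsg(log, "grm", 0L, t0)

  bundle <- list(panel = panel, assays = assays, genotypes = g, maf = maf,
                 qcLog = qc$log, split = split, panelPair = pp,
                 composite = composite, mask = mask, runs = runs,
                 panelComparison = panelComparison,
                 roundsComparison = roundsComparison,
                 density = density, regionScan = regions,
                 grm = grm, similarity = simTab, log = log)

  if (!is.null(outDir)) .writeExperimentArtifacts(cfg, bundle, outDir)
  invisible(bundle)
}

.writeExperimentArtifacts <- function(cfg, bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeSampleMetadata(bundle$panel, file.path(outDir, "samples.tsv"))
  for (a in bundle$assays)
    writeAssayDefinition(a, file.path(outDir, paste0("assay_", a@name, ".txt")))
  writeQcLog(bundle$qcLog, file.path(outDir, "qc_log.tsv"))
  writeSampleSplit(bundle$split, outDir)
  writeVCF(bundle$mask@observed, file.path(outDir, "masked_test.vcf"))
  writeVCF(bundle$composite, file.path(outDir, "composite_panel.vcf"))
  writeProvenance(bundle$composite, file.path(outDir, "composite_provenance.tsv"))
  for (strat in names(bundle$runs)) {
    tag <- gsub("[^A-Za-z0-9]+", "_", strat)
    r <- bundle$runs[[strat]]
    writeVCF(r$result, file.path(outDir, paste0("imputed_", tag, ".vcf")))
    writeReport(r$va, file.path(outDir, paste0("per_variant_", tag, ".tsv")))
    writeReport(r$vi, file.path(outDir, paste0("per_individual_", tag, ".tsv")))
    writeReport(r$binned, file.path(outDir, paste0("binned_", tag, ".tsv")))
  }
  if (!is.null(bundle$panelComparison))
    yaml::write_yaml(bundle$panelComparison,
                     file.path(outDir, "panel_comparison.yaml"))
  if (!is.null(bundle$roundsComparison))
    yaml::write_yaml(bundle$roundsComparison,
                     file.path(outDir, "rounds_comparison.yaml"))
  if (!is.null(bundle$density$sweep))
    writeReport(bundle$density$sweep, file.path(outDir, "density_sweep.tsv"))
  writeReport(bundle$regionScan, file.path(outDir, "region_scan.tsv"))
  writeGRM(bundle$grm, file.path(outDir, "grm"))
  writeReport(bundle$similarity, file.path(outDir, "similarity.tsv"))
  writeLines(bundle$log, file.path(outDir, "stages.log"))
  cfgPath <- file.path(outDir, "config.yaml")
  yaml::write_yaml(.configAsList(cfg), cfgPath)
  manifest <- list(package = "ImputeEval",
                   version = as.character(utils::packageVersion("ImputeEval")),
                   seed = cfg@seed,
                   config_md5 = unname(tools::md5sum(cfgPath)),
                   stages = bundle$log)
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(outDir)
}
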