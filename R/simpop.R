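## Synthetic multi-breed panel generator.
##
## Breed allele frequencies follow the Balding-Nichols model around a shared
## ancestral frequency; within-breed LD arises from a founder-mosaic process:
## every output haplotype is a left-to-right mosaic of a finite set of breed
## founder haplotypes with a constant per-marker switch probability. This is
## deliberately non-genealogical -- it produces the haplotype sharing that
## copying-model imputation exploits at a tiny fraction of the cost of a
## coalescent simulation.

#' Construct a simulation configuration
#'
#' Defaults describe a desk-scale structured cattle-like population: six
#' breeds with strongly unequal reference representation (one dominant breed
#' holding half the reference, one mid-sized, several sparse), a handful of
#' admixed test individuals, a 1/x-shaped ancestral site-frequency spectrum,
#' and a 0.2\% genotype-call error rate.
#'
#' @param nMarkers markers per chromosome (default 2500).
#' @param nChromosomes number of autosomes (default 2).
#' @param breeds data.frame with columns \code{name}, \code{nRefHaplotypes}
#'   (even), \code{nTestIndividuals}, \code{fst}.
#' @param nFoundersPerBreed founder haplotypes per breed (default 8; small
#'   effective founder numbers emulate the strong within-breed haplotype
#'   sharing of livestock populations).
#' @param mosaicSwitchRate per-marker founder-switch probability
#'   (default 0.001, i.e. founder segments of ~1000 markers; together with
#'   the founder count this sets the ratio of assay spacing to haplotype
#'   segment length, the quantity that controls the achievable imputation
#'   accuracy regime).
#' @param founderWeightRatio geometric ratio of founder copying weights in
#'   (0,1]: founder f is copied with probability proportional to
#'   \code{founderWeightRatio^f}, skewing the haplotype frequency spectrum
#'   so that rare variants ride rare haplotype backgrounds (1 = equal
#'   founder weights). Default 0.6.
#' @param migrationRate probability that a mosaic segment's founder is drawn
#'   from a uniformly chosen breed instead of the sample's own breed (or
#'   admixture profile). Breeds are therefore not haplotype-disjoint: they
#'   share common haplotypes and differ mostly in rare ones, as real cattle
#'   breeds connected by recent crossbreeding do. Default 0.08.
#' @param admixedSamples data.frame with column \code{name} plus one numeric
#'   ancestry-proportion column per breed (rows sum to 1); default: thirty
#'   majority-dominant-breed individuals with minor outside ancestry
#'   (0.80/0.15/0.05 across the dominant, mid and a sparse breed) -- the
#'   profile of an open-herdbook population whose admixture segregates in
#'   both the reference and the test set.
#' @param sfsBounds support of the 1/x ancestral frequency density
#'   (default c(0.01, 0.99)).
#' @param genotypeErrorRate per-genotype call error probability
#'   (default 0.002).
#' @param seed integer random seed (default 1).
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nMarkers = 200, nChromosomes = 1)
#' cfg
#' @export
simConfig <- function(nMarkers = 2500L,
                      nChromosomes = 2L,
                      breeds = NULL,
                      nFoundersPerBreed = 8L,
                      mosaicSwitchRate = 0.001,
                      founderWeightRatio = 0.6,
                      migrationRate = 0.08,
                      admixedSamples = NULL,
                      sfsBounds = c(0.01, 0.99),
                      genotypeErrorRate = 0.002,
                      seed = 1L) {
  if (is.null(breeds)) {
    breeds <- data.frame(
      name = c("B1", "B2", "B3", "B4", "B5", "B6"),
      nRefHaplotypes = c(600L, 240L, 160L, 100L, 60L, 40L),
      nTestIndividuals = c(10L, 10L, 10L, 10L, 10L, 10L),
      fst = c(0.10, 0.12, 0.10, 0.15, 0.12, 0.20),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(admixedSamples)) {
    admixedSamples <- data.frame(name = sprintf("ADM%02d", 1:30))
    for (b in breeds$name) admixedSamples[[b]] <- 0
    if (all(c("B1", "B2", "B5") %in% breeds$name)) {
      admixedSamples$B1 <- 0.80
      admixedSamples$B2 <- 0.15
      admixedSamples$B5 <- 0.05
    } else {
      admixedSamples[[breeds$name[1]]] <- 1
    }
  }
  new("SimConfig",
      nMarkers = as.integer(nMarkers), nChromosomes = as.integer(nChromosomes),
      breeds = breeds, nFoundersPerBreed = as.integer(nFoundersPerBreed),
      mosaicSwitchRate = mosaicSwitchRate,
      founderWeightRatio = founderWeightRatio,
      migrationRate = migrationRate,
      admixedSamples = admixedSamples,
      sfsBounds = as.numeric(sfsBounds),
      genotypeErrorRate = genotypeErrorRate, seed = as.integer(seed))
}

## Inverse-CDF draw from the density proportional to 1/x on [lo, hi].
.rSfs <- function(n, lo, hi) {
  lo * (hi / lo)^runif(n)
}

## One mosaic haplotype: founder segments over M markers (single chromosome).
## founders: list per breed of founder matrices (nFounders x M).
## probs: breed sampling probabilities (length = number of breeds).
## fw: founder copying weights (shared across breeds).
.mosaicHaplotype <- function(founders, probs, switchRate, M, fw) {
  sw <- c(TRUE, runif(M - 1L) < switchRate)
  starts <- which(sw)
  ends <- c(starts[-1L] - 1L, M)
  nb <- length(founders)
  out <- integer(M)
  bidx <- sample.int(nb, length(starts), replace = TRUE, prob = probs)
  for (s in seq_along(starts)) {
    f <- founders[[bidx[s]]]
    fi <- sample.int(nrow(f), 1L, prob = fw)
    out[starts[s]:ends[s]] <- f[fi, starts[s]:ends[s]]
  }
  out
}

#' Simulate a phased multi-breed haplotype panel
#'
#' Generation procedure, per chromosome: (1) draw ancestral frequencies from
#' a 1/x-shaped spectrum on \code{sfsBounds}; (2) draw per-breed frequencies
#' from the Balding-Nichols distribution
#' Beta(p(1-F)/F, (1-p)(1-F)/F); (3) draw founder haplotypes by independent
#' Bernoulli sampling at the breed frequency; (4) build each output
#' haplotype as a left-to-right founder mosaic with constant per-marker
#' switch probability; (5) admixed samples draw each segment's founder from
#' breed b with probability equal to their ancestry proportion.
#'
#' Output is deterministic given the configuration (including its seed).
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return a \linkS4class{HaplotypePanel} containing reference and test
#'   samples for every breed plus the admixed samples. The realized founder
#'   allele frequencies (simulation truth) are kept in \code{founderFreqs},
#'   the Balding-Nichols draws in \code{breedFreqs}.
#' @examples
#' panel <- simulatePanel(simConfig(nMarkers = 100, nChromosomes = 1,
#'   breeds = data.frame(name = c("X", "Y"), nRefHaplotypes = c(20L, 20L),
#'                       nTestIndividuals = c(2L, 2L), fst = c(0.1, 0.1)),
#'   admixedSamples = data.frame(name = character(0))))
#' panel
#' @export
simulatePanel <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  br <- cfg@breeds
  nb <- nrow(br)
  M <- cfg@nMarkers
  nC <- cfg@nChromosomes
  Mtot <- M * nC
  nf <- cfg@nFoundersPerBreed

  ## sample bookkeeping: per breed, reference samples then test samples;
  ## admixed samples appended last
  nSamp <- br$nRefHaplotypes %/% 2L + br$nTestIndividuals
  sampleIds <- character(0)
  breedVec <- character(0)
  for (i in seq_len(nb)) {
    ids <- sprintf("%s_%03d", br$name[i], seq_len(nSamp[i]))
    sampleIds <- c(sampleIds, ids)
    breedVec <- c(breedVec, rep(br$name[i], nSamp[i]))
  }
  adm <- cfg@admixedSamples
  nAdm <- nrow(adm)
  if (nAdm) {
    sampleIds <- c(sampleIds, adm$name)
    breedVec <- c(breedVec, rep("Admixed", nAdm))
  }
  nTot <- length(sampleIds)
  breedOf <- setNames(breedVec, sampleIds)

  alleles <- matrix(0L, nrow = 2L * nTot, ncol = Mtot)
  pAnc <- numeric(Mtot)
  pBreed <- matrix(0, nrow = nb, ncol = Mtot, dimnames = list(br$name, NULL))
  pFounder <- matrix(0, nrow = nb, ncol = Mtot, dimnames = list(br$name, NULL))

  admProps <- if (nAdm) as.matrix(adm[, br$name, drop = FALSE]) else NULL

  fw <- cfg@founderWeightRatio^seq_len(nf)
  fw <- fw / sum(fw)
  mig <- cfg@migrationRate
  mixProbs <- function(own) (1 - mig) * own + mig / nb

  for (ch in seq_len(nC)) {
    cols <- ((ch - 1L) * M + 1L):(ch * M)
    pa <- .rSfs(M, cfg@sfsBounds[1], cfg@sfsBounds[2])
    pAnc[cols] <- pa
    founders <- vector("list", nb)
    for (i in seq_len(nb)) {
      F <- br$fst[i]
      pb <- rbeta(M, pa * (1 - F) / F, (1 - pa) * (1 - F) / F)
      ## Beta draws can hit 0/1 numerically; clamp inside (0,1)
      pb <- pmin(pmax(pb, 1e-6), 1 - 1e-6)
      pBreed[i, cols] <- pb
      fm <- matrix(rbinom(nf * M, 1L, rep(pb, each = nf)), nrow = nf)
      founders[[i]] <- fm
      pFounder[i, cols] <- as.vector(fw %*% fm)
    }
    hap <- 1L
    for (i in seq_len(nb)) {
      probs <- mixProbs(as.numeric(seq_len(nb) == i))
      for (h in seq_len(2L * nSamp[i])) {
        alleles[hap, cols] <- .mosaicHaplotype(founders, probs,
                                               cfg@mosaicSwitchRate, M, fw)
        hap <- hap + 1L
      }
    }
    if (nAdm) {
      for (a in seq_len(nAdm)) {
        for (h in 1:2) {
          alleles[hap, cols] <- .mosaicHaplotype(founders, mixProbs(admProps[a, ]),
                                                 cfg@mosaicSwitchRate, M, fw)
          hap <- hap + 1L
        }
      }
    }
  }

  map <- data.frame(
    chrom = rep(as.character(seq_len(nC)), each = M),
    pos = rep(seq_len(M) * 1000L, times = nC),
    id = sprintf("chr%d:%d", rep(seq_len(nC), each = M),
                 rep(seq_len(M) * 1000L, times = nC)),
    ref = "A", alt = "B",
    stringsAsFactors = FALSE
  )
  rownames(alleles) <- as.vector(rbind(paste0(sampleIds, "_h1"),
                                       paste0(sampleIds, "_h2")))
  colnames(alleles) <- map$id

  admLong <- if (nAdm) {
    data.frame(sample = rep(adm$name, each = nb),
               breed = rep(br$name, times = nAdm),
               proportion = as.vector(t(admProps)),
               stringsAsFactors = FALSE)
  } else data.frame(sample = character(0), breed = character(0),
                    proportion = numeric(0))

  new("HaplotypePanel", alleles = alleles, markerMap = map,
      sampleIds = sampleIds, breedOf = breedOf,
      founderFreqs = pFounder, breedFreqs = pBreed, ancestralFreqs = pAnc,
      admixture = admLong,
      metadata = list(role = setNames(
        c(unlist(lapply(seq_len(nb), function(i)
          rep(c("reference", "test"),
              c(br$nRefHaplotypes[i] %/% 2L, br$nTestIndividuals[i])))),
          rep("test", nAdm)),
        sampleIds)))
}

#' Panel-wide minor allele frequency from phased haplotypes
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @return numeric vector of per-marker MAF (named by marker id).
#' @export
panelMaf <- function(panel) {
  f <- colMeans(panel@alleles)
  setNames(pmin(f, 1 - f), panel@markerMap$id)
}

#' Define commercial-assay-like marker subsets
#'
#' Three selection rules are supported. \code{"common-evenly-spaced"}
#' (HD-like): evenly indexed markers preferring panel MAF >= 0.05.
#' \code{"rare-enriched"} (F250-like): a fixed overlap block shared with the
#' parent common assay plus markers sampled preferentially at MAF < 0.1, so
#' the selected MAF spectrum is rare-shifted. \code{"nested-subset-of"}: a
#' uniformly spaced subset of a parent assay (emulating the nested commercial
#' densities).
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param spec data.frame with columns \code{name}, \code{count},
#'   \code{rule}, \code{parent} (NA unless nested or rare-enriched) and
#'   \code{overlap} (shared-block size; used by the rare-enriched rule).
#' @param seed integer seed for the weighted rare-variant sampling.
#' @return named list of \linkS4class{AssayDefinition} objects, in spec
#'   order.
#' @export
defineAssays <- function(panel, spec, seed = 1L) {
  stopifnot(all(c("name", "count", "rule") %in% names(spec)))
  if (is.null(spec$parent)) spec$parent <- NA_character_
  if (is.null(spec$overlap)) spec$overlap <- NA_integer_
  maf <- panelMaf(panel)
  ids <- panel@markerMap$id
  M <- length(ids)
  out <- list()
  set.seed(seed)
  for (i in seq_len(nrow(spec))) {
    nm <- spec$name[i]; cnt <- as.integer(spec$count[i]); rule <- spec$rule[i]
    if (cnt > M) stop("assay '", nm, "' requests more markers than the panel holds")
    sel <- switch(rule,
      "common-evenly-spaced" = {
        common <- which(maf >= 0.05)
        if (length(common) >= cnt) {
          common[unique(round(seq(1L, length(common), length.out = cnt)))]
        } else {
          ## not enough common markers: take all, fill evenly from the rest
          rest <- setdiff(seq_len(M), common)
          extra <- rest[unique(round(seq(1L, length(rest),
                                         length.out = cnt - length(common))))]
          sort(c(common, extra))
        }
      },
      "rare-enriched" = {
        parent <- out[[spec$parent[i]]]
        if (is.null(parent)) stop("rare-enriched assay '", nm,
                                  "' needs a defined parent assay")
        ov <- as.integer(spec$overlap[i])
        if (is.na(ov) || ov < 1L) stop("rare-enriched assay needs a positive overlap size")
        pidx <- match(parent@markerIds, ids)
        block <- pidx[unique(round(seq(1L, length(pidx), length.out = ov)))]
        pool <- setdiff(seq_len(M), block)
        w <- ifelse(maf[pool] < 0.1, 10, 1)
        nEx <- cnt - length(block)
        if (nEx > length(pool)) stop("assay '", nm, "' larger than available markers")
        extra <- pool[sample.int(length(pool), nEx, prob = w)]
        sort(c(block, extra))
      },
      "nested-subset-of" = {
        parent <- out[[spec$parent[i]]]
        if (is.null(parent)) stop("nested assay '", nm,
                                  "' has an undefined parent ('", spec$parent[i], "')")
        pidx <- match(parent@markerIds, ids)
        if (cnt > length(pidx)) stop("nested assay larger than its parent")
        sort(pidx[unique(round(seq(1L, length(pidx), length.out = cnt)))])
      },
      stop("unknown selection rule: ", rule)
    )
    out[[nm]] <- new("AssayDefinition", name = nm, markerIds = ids[sel],
                     rule = rule, parent = as.character(spec$parent[i]))
  }
  out
}

#' Scale the published commercial assay densities to a simulated panel
#'
#' Preserves the density ratios of the filtered commercial assays
#' (6394 : 16854 : 44366 : 70581 : 125446 relative to a 753715-marker
#' common-variant research assay) at a given common-assay size.
#'
#' @param hdCount size of the simulated common-variant (HD-like) assay.
#' @return named integer vector of nested assay sizes
#'   (ULD, LD, SNP50, GGP90K, GGPHD).
#' @export
scaledAssayCounts <- function(hdCount) {
  ref <- c(ULD = 6394, LD = 16854, SNP50 = 44366, GGP90K = 70581,
           GGPHD = 125446)
  setNames(pmax(1L, as.integer(round(ref * hdCount / 753715))), names(ref))
}

#' Collapse haplotypes to genotype calls with random genotyping error
#'
#' Collapses each haplotype pair to unphased alternate-allele counts at the
#' assay's markers, then replaces each genotype, with probability
#' \code{rate}, by one of the two other genotype classes chosen uniformly
#' (symmetric error model). Error positions are retained in the result's
#' metadata as simulation truth.
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param assay an \linkS4class{AssayDefinition} (markers to genotype).
#' @param rate per-genotype error probability in [0, 1]; realistic platform
#'   rates are ~0.002, and simulation configurations restrict the default to
#'   at most 0.05, but the operation itself accepts any probability (rate = 1
#'   forces every genotype to a wrong class, useful for testing).
#' @param seed integer seed.
#' @return a \linkS4class{GenotypeMatrix} whose \code{metadata$errors} is a
#'   data.frame (sample, marker, truth, observed).
#' @export
genotypeWithError <- function(panel, assay, rate = 0.002, seed = 1L) {
  if (rate < 0 || rate > 1) stop("error rate must lie in [0, 1]")
  sub <- .subsetPanel(panel, markers = assay@markerIds)
  g <- .panelGenotypes(sub)
  set.seed(seed)
  flip <- which(runif(length(g)) < rate)
  errs <- data.frame(sample = character(0), marker = character(0),
                     truth = integer(0), observed = integer(0))
  if (length(flip)) {
    old <- g[flip]
    ## uniform choice among the two other genotype classes
    shift <- sample(1:2, length(flip), replace = TRUE)
    g[flip] <- (old + shift) %% 3L
    ij <- arrayInd(flip, dim(g))
    errs <- data.frame(sample = rownames(g)[ij[, 1]],
                       marker = colnames(g)[ij[, 2]],
                       truth = as.integer(old), observed = as.integer(g[flip]),
                       stringsAsFactors = FALSE)
  }
  .newGenotypeMatrix(g, sub@markerMap, phased = FALSE,
                     metadata = list(errors = errs, errorRate = rate))
}
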