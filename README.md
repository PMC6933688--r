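# ImputeEval

Evaluation framework for SNP genotype imputation accuracy in structured
(multi-breed) populations, written for livestock genomicists who need to
decide how to build an imputation reference panel — within-breed or
multi-breed composite, one-round or two-round — and which starting assay
density is worth paying for.

Real high-density panels of this kind are rarely shareable, so the package
pairs the evaluation machinery with a synthetic-data generator that
reproduces the statistical structure such studies rest on: multiple breeds
with strongly unequal reference representation, within-breed linkage
disequilibrium from founder-mosaic haplotypes, admixed open-herdbook
individuals, a common-variant assay and a rare-variant-enriched assay with
a shared marker block, nested lower-density commercial assays, and ~0.2%
genotyping error.

## What it computes

Genotypes are coded as alternate-allele counts (0/1/2). For each variant,
accuracy is scored by genotype concordance, Pearson *r*, and the
**imputation quality score (IQS)** — concordance corrected for the chance
that an imputed genotype is guessed right from the table margins. With
`n_gh` the count of genotypes truly `g` and imputed `h` (N = Σ n_gh):

    P0  = Σ_g n_gg / N                    (observed concordance)
    Pc  = Σ_g n_g. · n_.g / N²            (chance agreement)
    IQS = (P0 − Pc) / (1 − Pc)

IQS is 0 whenever only one side varies (the rare-variant trap in which
concordance approaches 1), may be negative, and is defined even where *r*
is not. Errors are also catalogued as false heterozygotes (AA/BB imputed
AB), false homozygotes (AB imputed AA/BB), or completely discordant
(opposite homozygotes), per variant and per individual.

The imputation engine is a haploid Li–Stephens copying model (scaled
forward–backward over K reference haplotypes, uniform switch kernel,
emission error ε, left-flank interpolation at untyped sites) — a
desk-scale stand-in for production imputation software with the same
contract: phased target, phased reference, posterior dosages plus hard
calls. Reference panels are built either per breed (BR) or as a
multi-breed composite (CR) whose two research assays are merged by
reciprocal cross-imputation ("one-round"), and compared against the
sequential "two-round" strategy. A standardized genomic relationship
matrix, G_jk = (1/m) Σ_i (x_ij − 2p_i)(x_ik − 2p_i) / (2p_i(1−p_i)),
supplies relatedness-to-reference diagnostics, and a sliding-window scan
flags genome regions where IQS or error counts collapse (a signature of
misplaced markers).

## Worked example

A small three-breed study with an admixed open-herdbook group, masked to a
SNP50-like assay and imputed back with both panel types:

```r
library(ImputeEval)

cfg <- experimentConfig(
  sim = simConfig(nMarkers = 500L, nChromosomes = 2L,
    breeds = data.frame(name = c("ANG", "HER", "GEL"),
                        nRefHaplotypes = c(200L, 100L, 60L),
                        nTestIndividuals = c(5L, 5L, 5L),
                        fst = c(0.10, 0.12, 0.15)),
    admixedSamples = local({
      a <- data.frame(name = sprintf("X%02d", 1:8))
      a$ANG <- 0.8; a$HER <- 0.15; a$GEL <- 0.05
      a
    })),
  masking = list(maxPerBreed = 5L, maxBreedFraction = 0.5),
  hmm = hmmParams(maxReferenceHaplotypes = 1000L),
  densityAssays = c("SNP50", "GGPHD"),
  brBreed = "ANG",
  seed = 11L)

study <- runExperiment(cfg, outDir = "results")
study$runs[["one-round:CR"]]$binned[, c("maf_bin", "n_markers",
                                        "mean_concordance", "mean_iqs")]
```

```
    maf_bin n_markers mean_concordance  mean_iqs
      fixed       177        1.0000000 1.0000000
 >0.00-0.05       176        0.9724880 0.6732675
 >0.05-0.10        94        0.9546473 0.7720536
 >0.10-0.15        85        0.9362229 0.8148075
 >0.15-0.20        68        0.9094427 0.7857178
 >0.20-0.25        49        0.9258861 0.8482903
 ...
```

Reading the table: concordance is *highest* in the rarest bin (0.97) while
IQS is lowest there (0.67) — rare variants look well imputed only until
chance agreement is removed, which is why the package scores variants by
IQS. The panel comparison on the same run:

```r
str(study$panelComparison[c("n", "mean_diff", "t", "p_t",
                            "n_improved", "n_worsened")])
#> $ n         : int 858
#> $ mean_diff : num 0.105
#> $ t         : num 12.8
#> $ p_t       : num 1.19e-34
#> $ n_improved: int 368
#> $ n_worsened: int 70
```

so the composite panel raises mean per-variant IQS by 0.105 over the
within-breed panel (paired t = 12.8), improving 368 markers for every 70
it worsens. `study$density$sweep` shows accuracy rising with starting
assay density (here 0.816 → 0.876 mean IQS from the SNP50-like to the
GGP-HD-like assay). `runExperiment(cfg, outDir = ...)` also writes masked
and imputed VCFs, per-variant/per-individual TSV reports, the region scan,
the GRM, and a YAML manifest; a thin command-line wrapper lives at
`inst/scripts/run_experiment.R`.

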