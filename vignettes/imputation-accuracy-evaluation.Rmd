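---
title: "Evaluating genotype imputation accuracy in multi-breed populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating genotype imputation accuracy in multi-breed populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ImputeEval answers a practical question in livestock genomics: when
genotypes from a medium- or low-density SNP assay are imputed up to the
union of two high-density research assays, how accurate is the result, and
how is that accuracy shaped by the reference panel (within-breed vs
multi-breed composite), the imputation strategy (one-round vs two-round),
the starting assay density, and a variant's minor allele frequency? Because
panels of real high-density genotypes are rarely shareable, the package
evaluates these questions on synthetic panels engineered to reproduce the
statistical structure that drives them. This vignette records the models,
the parameter choices and their rationale, the numerical conventions, and
what the synthetic evaluation can and cannot say about real data.

## The population generator

`simulatePanel()` builds phased haplotypes in four layers.

**Allele frequencies.** Each marker draws an ancestral frequency from a
1/x-shaped spectrum on [0.01, 0.99] (sampled exactly by inversion:
p = 0.01 · 99^u), matching the observation that dense variant panels
enriched for rare sites resemble the genome's site frequency spectrum.
Each breed then draws its own frequency from the Balding–Nichols
distribution Beta(p(1−F)/F, (1−p)(1−F)/F) with a per-breed F_ST. Defaults
(0.10–0.20) span the differentiation typical of cattle breeds. Both the
Balding–Nichols draws (`breedFreqs`) and the realized founder frequencies
(`founderFreqs`) are retained as simulation truth; empirical panel
frequencies converge to the latter, since output haplotypes are mosaics of
a finite founder set.

**Haplotypes and LD.** Each breed receives a small set of founder
haplotypes (independent Bernoulli draws at the breed frequency), and every
output haplotype is a left-to-right mosaic of founders with a constant
per-marker switch probability. This is deliberately non-genealogical: it
produces the haplotype sharing that copying-model imputation exploits at a
tiny fraction of a coalescent simulation's cost. Two parameters control
the regime. `nFoundersPerBreed` (default 8) sets within-breed haplotype
diversity — small effective founder numbers are the defining feature of
intensively selected livestock populations. `mosaicSwitchRate` (default
0.001 per marker, i.e. founder segments of roughly a thousand markers)
sets segment length; together with assay spacing it determines how many
typed markers identify each copied segment, which is the quantity that
controls achievable accuracy. The defaults were calibrated so that
imputation from the SNP50-like assay lands in the high-accuracy regime
reported for real cattle panels (genotype concordance in the high 0.9s),
with the lowest-density assay clearly degraded — the regime in which the
reference-panel and assay-density questions are meaningful at all.

**Haplotype frequency spectrum.** Founders are not copied equally:
founder f is chosen with probability proportional to
`founderWeightRatio^f` (default 0.6). The resulting geometric haplotype
spectrum makes rare variants ride rare haplotype backgrounds with few (or
no) reference copies. Without this skew every founder is equally well
represented in any reference subset and rare variants are no harder to
impute than common ones — inverting the central MAF pattern the framework
exists to measure.

**Breed overlap and admixture.** With probability `migrationRate`
(default 0.08) a mosaic segment copies a founder from a uniformly chosen
breed rather than the sample's own. Breeds therefore share common
haplotypes and differ mostly in rare and introgressed ones, as real breeds
connected by recent crossbreeding do; a within-breed panel is then a
reasonable reference for its own breed's common variation while the
composite panel adds diversity precisely where the breed panel is thin.
Named admixed samples (default: thirty individuals at 0.80/0.15/0.05
across a dominant, a mid-sized and a sparse breed) emulate an
open-herdbook population whose admixture segregates in reference and test
sets alike.

**Genotyping error.** Assay genotype calls flip to a uniformly chosen
wrong class at rate 0.002, the reproducibility error of the emulated
platforms. Error is applied to the genotype calls of all samples; since
the calls are also the scoring truth (as in studies that treat the
research-assay calls as correct), the error rate bounds measurable
accuracy from above. Reference haplotypes are taken phase-perfect from the
simulator; imperfect statistical phasing can be emulated separately with
`phaseMode = "switch-error"` (default 0.02 switches per heterozygote).

## Assays and masking

`defineAssays()` supports the three selection rules of the emulated
chips: common-evenly-spaced (prefer MAF ≥ 0.05, even index spacing),
rare-enriched (a fixed block shared with the common assay plus sampling
weighted toward MAF < 0.1), and nested-subset-of (uniform subset of a
parent). The default geometry keeps the published proportions: the
common assay covers 90% of the union marker set, the rare-enriched assay
20% with a shared block of 12% of the union, and the five nested assays
scale the published filtered densities (6,394 … 125,446 relative to a
753,715-marker common assay) down to the simulated size.
`selectTestIndividuals()` draws at most `min(50, ⌊0.5·breed size⌋)` test
individuals per breed (sorted ids, seeded sampling, so the split is
reproducible and input-order invariant), and `maskToAssay()` restricts
their genotypes to one assay while retaining the withheld truth.

## The imputation engine

`imputeHaploid()` is a haploid Li–Stephens copying model: K reference
haplotypes, transition stay probability (1−s) + s/K and move probability
s/K to each other state (default s = 0.01 per typed interval; constant
because simulated maps are uniform — there is no genetic map), emission
1−ε on allele match and ε on mismatch (default ε = 0.002, uninformative on
missing input). The forward–backward recursions are scaled row-wise, so
posteriors are exact and underflow-free at any practical marker count; the
C++ core is linear in K·M. Untyped markers take the state posterior at the
nearest typed marker to the left (the leftmost interval uses the first
typed site) — the simplest defensible interpolation; production engines
interpolate within intervals, and the left-flank rule slightly penalizes
markers far from typed support on both sides equally. A chromosome with no
typed markers falls back to the copying prior (the reference frequency).
Diploid samples are imputed one haplotype at a time on their (simulator)
phase; the K²-state diploid HMM was rejected on cost. Dosage is the sum of
the two haplotype posteriors; the hard call rounds dosage with ties at x.5
resolved toward the heterozygote (arbitrary but fixed). Observed assay
genotypes always pass through unchanged, flagged `observed`.

When a reference exceeds `maxReferenceHaplotypes` it is subsampled with a
seed, stratified by breed with whole samples kept together. The
constructor default is a conservative 200; the experiment pipeline raises
the cap beyond the desk-scale panel size so the full reference is used,
matching production imputation engines, which never subsample.

## Reference panels and strategies

The composite (CR) panel merges samples genotyped on the common assay
only, the rare-enriched assay only, and both. `buildCompositeOneRound()`
fills each group's missing marker block by reciprocal cross-imputation
through the shared block, hard-calling posteriors to alleles (ties at 0.5
to the panel major allele) because the copying model consumes discrete
reference alleles; every entry carries an `observed`/`cross-imputed`
provenance flag, and observed entries are never altered.
`runTwoRound()` instead imputes test samples to the common assay's
markers against observed common-assay references only, then imputes the
rare-assay-exclusive markers against observed rare-assay references,
threading the hard-called shared-block output of step one. Both
strategies cover the union marker set and agree exactly on the markers
the test assay observed.

`buildBreedPanel()` builds the within-breed (BR) panel by registry-style
membership: samples labeled with the breed plus admixed samples whose
recorded ancestry for that breed reaches `minAncestry` (default 0.5).
Open-herdbook breed panels are assembled from labels in practice, so they
contain the breed's admixed members; excluding them (set `minAncestry`
above 1) changes the question being asked from "label-based breed panel
vs composite" to "strictly purebred panel vs composite".

## Metrics

Only withheld entries (provenance `imputed`) with non-missing truth are
scored. Per variant: concordance, the chance-corrected IQS
(P0 − Pc)/(1 − Pc) from the 3×3 truth-by-imputed table (defined as 1 when
both sides are constant and identical; identically 0 whenever exactly one
side is constant — the algebra that deflates concordance at rare and
fixed sites), raw Pearson r (a typed NA sentinel when either side is
constant, never silently dropped), and error counts by type. Per
individual: raw and MAF-centered r (2·MAF subtracted from both vectors,
per marker) and the same error taxonomy. Best-guess genotypes, not
dosages, are scored, because the error taxonomy and IQS are defined on
genotype classes. MAF for binning and centering comes from the combined
reference-plus-test genotype calls; bins are half-open,
(0, 0.05], …, (0.45, 0.50], with MAF = 0 in a dedicated `fixed` bin since
the first bin is strictly above zero. `regionScan()` slides
non-overlapping 50-marker windows per chromosome and flags those where
more than 20% of markers breach IQS < 0.8 or more than 10 errors.
`comparePanels()` reports the paired mean IQS difference with the t
statistic computed from the textbook formula (cross-checked against
`t.test` in the test suite), the variance-ratio F, and
improved/worsened/unchanged counts. The standardized GRM excludes
monomorphic markers (their term is undefined) and mean-imputes missing
genotypes, so they contribute zero.

## The default desk-scale study

`experimentConfig()` encodes the study the acceptance script reruns: six
breeds with reference haplotype counts 600/240/160/100/60/40 (one
dominant breed at half the reference, mirroring the published panel's
imbalance), ten test candidates per breed plus the admixed group, 5,000
markers on two chromosomes, reference genotyping groups at 20% common-only
/ 72% rare-only / 8% both, masking to the SNP50-like assay for the panel
and strategy comparisons, and the five-assay density sweep. These sizes
run end to end in about two minutes on one CPU; they are the package's
statement of a desk-scale problem, chosen so that per-variant comparisons
still rest on thousands of markers.

Two evaluation conventions deserve note. The density sweep is scored on
the markers withheld under *every* assay (those absent from the densest
one): nested assays withhold nested marker sets, and scoring each run on
its own withheld set would credit the sparsest assay with the easy common
markers the denser assays observe. And the strategy comparison at rare
common-assay-exclusive markers is made among markers the two-round method
imputed imperfectly — the population on which that comparison is defined —
while the composite-vs-breed gain profile is examined among markers the
breed panel got wrong: at desk scale every MAF class retains imputation
headroom, so concentration of the gain is only visible once headroom is
controlled; full-scale panels saturate common variants and make the same
pattern visible unconditionally.

## What the simulation does and does not emulate

The generator reproduces: breed structure with realistic divergence,
unequal reference representation, strong within-breed LD with a skewed
haplotype spectrum, partial haplotype sharing between breeds, admixture,
the two-assay geometry with a shared block, nested assay densities, and
platform genotyping error. It does not contain: mutation or selection,
genetic-map heterogeneity (positions are uniformly spaced; switch rates
constant), sex chromosomes, multi-allelic sites or indels,
assay-specific cluster/probe artifacts, or real marker coordinates.
Passing directional tests on these simulations therefore demonstrates
that the machinery recovers the expected orderings where the generating
mechanism is the stated one; it does not certify accuracy magnitudes for
any particular real panel, and absolute IQS levels at desk scale sit
below those achievable with panels of tens of thousands of animals.

## Numerical conventions and degenerate inputs

Scaled forward–backward recursions (no log-space needed); posterior rows
renormalized at every typed site. Dosage ties at x.5 go to the
heterozygote; cross-imputation allele ties at 0.5 go to the panel major
allele. QC removes non-autosomal markers first, then markers, then
samples by call rate, with strictly-below-threshold removal (an entity at
exactly 0.90 survives) and *no* MAF or Hardy–Weinberg filter — rare and
monomorphic markers are the point. Undefined correlations are NA
sentinels; IQS of an empty comparison, imputation of a target typed
nowhere, masking with unknown markers, empty breed panels and empty
overlap groups all raise named errors rather than degrade silently. All
randomness flows from explicit seeds; the pipeline expands one global
seed into per-stage seeds by stage-name hashing so stages can be re-run
in isolation, and rerunning a configuration reproduces every number
bit-for-bit.

## Known limitations

Phasing is taken from the simulator (or perturbed with a constant
per-het switch rate) rather than re-estimated; reference-based phasing
software would introduce correlated, position-dependent switch errors.
The left-flank interpolation rule is pessimistic immediately left of
typed markers compared with interval-weighted interpolation. Cross-imputed
composite entries are hard-called, discarding their uncertainty — a
dosage-aware reference representation is a known alternative. The
region scan uses marker-count windows, not physical distance. And the
breed-panel membership rule relies on recorded ancestry proportions;
with real data those come from an upstream breed-composition estimator
whose error is not modeled here.
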