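Package: ImputeEval
Title: Evaluation of Genotype Imputation Accuracy with Multi-Breed Reference Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation framework for SNP genotype imputation in
    structured (multi-breed) populations. Simulates phased multi-breed haplotype
    panels with linkage disequilibrium, admixture, and genotyping error; defines
    commercial-assay-like marker subsets (common evenly spaced, rare-enriched,
    and nested densities); masks test individuals to assay densities; imputes
    withheld genotypes with a Li-Stephens haplotype-copying hidden Markov model
    against within-breed or multi-breed composite reference panels using
    one-round (reciprocally cross-imputed composite) or two-round (sequential)
    strategies; and scores results with chance-corrected concordance (IQS),
    raw and MAF-centered Pearson correlation, an error taxonomy (false
    heterozygote, false homozygote, completely discordant), MAF-binned
    summaries, low-accuracy genome region scans, and standardized genomic
    relationship diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
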