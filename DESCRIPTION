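Package: virtmet
Title: Virtual Metabolomics via Polygenic Score PheWAS and Two-Sample
    Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genotype-based ("virtual") metabolomics: metabolite
    polygenic scores computed from SNP weight files, PheCode-based
    case/control assembly and phenome-wide association scans with
    Benjamini-Hochberg control, instrument construction (p-value selection,
    greedy LD clumping, effect-allele harmonization), two-sample Mendelian
    randomization estimators (Wald ratio, fixed/random-effects
    inverse-variance weighted, MR-Egger, weighted median) with Cochran's Q
    heterogeneity diagnostics, a simulation-based MR-PRESSO implementation
    (global, outlier and distortion tests), and a stage-gated
    discovery/screen/replication pipeline.  A synthetic-data module
    generates genotypes in LD blocks, sparse metabolite architectures,
    binary phenotypes with configurable causal and pleiotropic effects, and
    non-overlapping two-sample GWAS summary statistics with known ground
    truth, so every stage is testable without access-controlled data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
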