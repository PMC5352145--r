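Package: panelsurv
Title: Survival Phenotypes and Quantitative Genetics for Inbred Line Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting natural variation in pathogen resistance
    across panels of inbred lines (such as the Drosophila Genetic Reference
    Panel). Summarizes per-fly survival records into replicate- and line-level
    phenotypes (Kaplan-Meier LT50, within-line standard deviation, coefficient
    of environmental variation), partitions phenotypic variance with mixed
    ANOVA models and estimates broad-sense heritability at both the trait-mean
    and micro-environmental-variance levels, runs covariate-adjusted
    single-marker association scans on line means, characterizes the minor
    allele frequency and effect-size spectrum, classifies associated
    polymorphisms into gene-model site classes and tests their enrichment
    against genome composition, and relates within-host pathogen load
    kinetics to survival. Includes a synthetic-data generator with recorded
    ground truth for parameter-recovery testing and a pipeline orchestrator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    car,
    vcfR,
    jsonlite,
    yaml,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
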