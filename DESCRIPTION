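Package: duplexmrd
Title: Duplex Molecule Counting, Selectivity Statistics and Bayesian MRD
    Calling for Selective Variant-Enrichment Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis stack for hybridization-capture assays that selectively
    enrich rare somatic variants before sequencing. Converts UMI-tagged
    aligned reads into duplex and single-strand molecule counts per probe,
    quantifies probe and panel selectivity and the implied sequencing-depth
    reduction, fits Gamma-Poisson background error models from blank samples,
    derives per-variant calling thresholds at a fixed false-positive budget,
    estimates LoD95 and posterior input VAF, and integrates duplex and
    non-duplex evidence across a probe panel into a Bayesian minimal residual
    disease (MRD) call. Includes a synthetic-data generator that emulates
    dilution-series runs (probe-to-probe performance variation, substitution
    type dependent background errors, sample scaling, control probes,
    dropouts and phased-SNP cross-contamination) so every stage is testable
    without sequencing data, plus probe-design feature computation, melting
    temperature filtering and panel sampling with a pluggable scorer.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings,
    vcfR,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
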