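Package: BoolPatterns
Title: Pattern-Specific Detection of Boolean Relationships in Microbial
    Communities
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects non-continuous Boolean relationship patterns
    (co-presence, co-exclusion, one-way dependencies and their three- and
    four-dimensional analogs) between microbial abundance profiles.
    Pattern strength is scored as the fraction of samples consistent with
    the pattern, maximized over organism-specific presence/absence
    thresholds and guarded by a minimum per-cell population threshold.
    Statistical reporting is gated by a shuffle-based null model that
    restricts the scan to population-threshold/minimal-score combinations
    at which shuffled data yield zero patterns. Includes a
    mutual-information-score baseline, a planted-pattern synthetic data
    generator, QIIME-classic OTU table preprocessing (read-depth
    filtering, relative-abundance normalization, taxonomy-level merging,
    prevalence filtering), and typed multi-layer network export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.0),
    SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    igraph
Suggests:
    testthat (>= 3.0.0),
    biomformat,
    jsonlite,
    optparse
biocViews: Microbiome, Metagenomics, Network, GraphAndNetwork
Config/testthat/edition: 3
RoxygenNote: 7.3.3
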