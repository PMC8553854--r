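Package: mstates
Title: Task-Based EEG Microstate Analysis with Topographic Clustering and
    Permutation TANOVA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of event-related potential (ERP) microstates in
    multichannel task EEG. Provides a synthetic epoch generator with known
    microstate structure and controllable between-condition topographic
    effects, global field power (GFP) computation and normalization,
    polarity-sensitive k-means clustering of timepoint topographies with
    temporal segmentation into microstates, permutation-based topographic
    analysis of variance (TANOVA) using a cosine-angle statistic,
    channel-wise post-hoc paired t-tests with epoch-count equalization, a
    reverse power analysis for paired t-tests, and an end-to-end pipeline
    driven by a reproducible configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'montage.R'
    'synthetic.R'
    'erp.R'
    'clustering.R'
    'tanova.R'
    'posthoc.R'
    'stats-utils.R'
    'io.R'
    'pipeline.R'
    'show-methods.R'
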