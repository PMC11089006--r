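Package: precisionmap
Title: Precision Functional Network Mapping for Dense BOLD Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-specific functional brain network mapping from dense
    grayordinate BOLD time series. Implements template matching with
    eta-squared similarity, overlapping multi-network (OMNI) mapping with
    data-driven bimodal thresholds, multi-density community-detection
    consensus with Jaccard relabeling, population probabilistic atlases with
    derived ROI sets and integration zones, and split-half / subset
    reliability analysis. Ships motion preprocessing (framewise displacement,
    frame censoring, nuisance regression, band-pass filtering), readers and
    writers for CIFTI-2 and a plain-text dialect, and a synthetic
    multi-participant cohort generator with planted network topographies for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    signal,
    igraph,
    minpack.lm,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
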