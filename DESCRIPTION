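Package: metalrisk
Title: Probabilistic Trace-Metal Exposure Risk Assessment for Residential Soil and Dust
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for assessing human health risks from
    trace metals (As, Cr, Cu, Mn, Ni, Pb, Zn) measured in residential garden
    soil and indoor vacuum dust. Provides ingestion of delimited sample tables
    with below-detection-limit substitution at half the instrument LOD,
    standard-reference-material recovery QA, home-level aggregation,
    Mn-normalised geochemical enrichment factors with five-band
    classification, guideline benchmarking (e.g. NEPM HIL-A), nonparametric
    comparisons (Mann-Whitney, Kruskal-Wallis with Dunn's post hoc, Spearman),
    a Monte Carlo probabilistic risk engine computing route-specific average
    daily doses, hazard quotients/indices and incremental lifetime cancer
    risks for children and adults, Spearman tornado sensitivity analysis, and
    a copula-based synthetic data generator for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
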