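Package: glycocurate
Title: Curation Engine for Label-Free LC-MS Glycoproteomics and Glycomics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Headless curation engine for label-free liquid
    chromatography-mass spectrometry (LC-MS) glycoproteomics and glycomics
    quantitation output. Ingests per-analyte intensities and quality metrics
    from LaCyTools-style summary files and Skyline-style reports, links
    96-well plate layouts and sample metadata, curates whole (sample, site)
    measurements by sum intensity and fraction of quality-passing analytes,
    selects quantifiable analytes via per-sample, whole-dataset or
    per-biological-group consensus lists, performs total-area normalization
    per glycosylation site, computes derived glycosylation traits via a
    formula mini-language, and supports stable-isotope-label based protein
    quantitation and plate-level repeatability (CV) metrics. A synthetic-data
    simulator with ground truth makes every stage testable without external
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    readxl,
    ggplot2,
    withr
Config/testthat/edition: 3
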