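Package: plaqueagree
Title: Multi-Level Agreement Analysis of Coronary Plaque Metrics Between
    NIRS-IVUS and CT Angiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing coronary atherosclerotic plaque
    quantification between near-infrared spectroscopy intravascular
    ultrasound (NIRS-IVUS) and computed tomography angiography (CTA) on
    matched cross-sections. Computes segment-level burden metrics (total
    and percent atheroma volume, lipid- and calcium-burden indices from
    chemogram spread-out plots, maxLCBI4mm), detects lesions from
    plaque-burden profiles and derives lesion geometry (minimum lumen
    area, remodelling index, reference areas), and quantifies
    between-modality agreement with Bland-Altman analysis (parametric and
    quantile-regression based), mixed-model intraclass correlation with
    restricted-cubic-spline calcium adjustment, calcium-stratified
    heterogeneity meta-analysis, and proportional-odds / least-squares
    interaction models. A synthetic-cohort generator with known ground
    truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    lme4,
    pracma,
    readr,
    rlang,
    sandwich,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    MASS,
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
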