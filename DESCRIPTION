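Package: smiletrace
Title: Smile Event Detection and Group Analysis for Infant Facial
    Action Unit Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying infant smiling behaviour from
    automated facial Action Unit (AU) estimates such as those produced
    by OpenFace. Provides readers for the OpenFace CSV output dialect
    with per-frame confidence gating and dropout handling, boxcar
    smoothing and threshold-based segmentation of AU12/AU06 activation
    episodes, classification of smile events into Social Smiles (AU12
    with AU06 co-activation) and Simple Smiles (AU12 only), per-subject
    feature extraction (event duration, intensity, and frequency per
    120 s), and a group-level statistical battery (one-way MANOVA with
    Pillai's trace, Bonferroni-corrected univariate follow-up ANOVAs
    with partial eta squared, assumption checks, partial Spearman
    correlations, and demographic comparisons). A synthetic-cohort
    generator with ground truth supports end-to-end validation when
    real recordings cannot be shared.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    car
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    knitr
Config/testthat/edition: 3
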