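Package: carotexture
Title: Carotid Artery Wall Ultrasound Texture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Texture analysis of the carotid artery vessel wall in longitudinal
    B-mode ultrasound images, aimed at separating primary aldosteronism from
    essential hypertension and from normotensive controls. Computes 152 texture
    features inside a thin far-wall region of interest (first-order intensity
    statistics, 140 gray-level co-occurrence Haralick descriptors, and 10
    undecimated Haar wavelet-frame energies), screens features with Welch,
    Kolmogorov-Smirnov and Mann-Whitney tests, and evaluates feature subsets by
    patient-level leave-one-out gradient-boosted classification with unit
    patient weighting. Includes a synthetic cohort generator (speckle-textured
    wall images, region-of-interest polygons and clinical covariates) so the
    whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
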