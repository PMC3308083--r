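Package: cartex
Title: Cartilage T2 Relaxometry, Texture Quantification, and Morphologic
    Scoring Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Noise-corrected pixel-wise T2 relaxometry for multi-echo
    spin-echo knee MRI, grey-level co-occurrence matrix (GLCM) texture
    quantification of cartilage T2 maps within compartment masks,
    WORMS-style ordinal lesion scoring with prevalence summaries,
    reliability metrics (RMS coefficient of variation, intraclass
    correlation, quadratic-weighted kappa), and covariate-adjusted group
    statistics. Includes a seeded synthetic phantom and cohort generator
    that emulates a two-group observational imaging study, so the full
    simulate-fit-texture-score-analyze pipeline runs end to end without
    access to restricted clinical images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
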