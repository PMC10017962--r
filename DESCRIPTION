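Package: robustmark
Title: Language-Robust Speech and Language Biomarkers for Parkinson's Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extraction and cross-lingual evaluation of interpretable acoustic,
    linguistic, and cognitive biomarkers of Parkinson's disease from speech
    recordings and time-aligned transcripts. Implements prosodic contour and
    pause-based feature extraction (pitch, intensity, and first-formant
    variability; voice-activity segmentation and pause statistics),
    part-of-speech and phrase-count linguistic features, word-onset rhythm and
    informational-unit cognitive features, nonparametric group comparison
    (Kruskal-Wallis with Benjamini-Hochberg false-discovery-rate control,
    H-based eta-squared effect sizes, AUROC), Spearman correlation with
    clinical severity scales, and a three-condition adjudication of biomarker
    robustness across language cohorts. A synthetic two-group cohort generator
    with plantable effects provides fully reproducible end-to-end validation
    in place of restricted clinical datasets.
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
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
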