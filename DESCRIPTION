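Package: lesioncorrect
Title: Two-Stage Segmentation and Correction of Tiny White-Matter Lesions
    on Paired FLAIR MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects and discriminates tiny white-matter hyperintensities on
    paired T2/T1 FLAIR slices with a two-stage cascade: an encoder-decoder
    network segments candidate lesion pixels on the T2 image, then a small
    convolutional classifier relabels each connected lesion instance from a
    gamma-transformed T1 region of interest, distinguishing focal cerebral
    ischemia (FCI) from lacunar infarction (LACI). Includes a seeded phantom
    generator producing paired slices with exact ground truth, RMSProp
    training with a two-phase oversampling schedule for extreme class
    imbalance, rotation augmentation, and lesion-wise evaluation (Dice,
    detection and classification precision at IoU > 0.6) under patient-level
    five-fold cross-validation, plus a Table-style ablation runner.
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
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
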