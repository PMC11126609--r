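Package: mammoconcord
Title: Reader Concordance and Saliency-Agreement Evaluation for Screening Mammography CAD
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluation framework for lesion-localizing AI in double-read
    screening mammography. Implements inter-reader annotation concordance
    (bounding-box IoU matching, Lin's concordance correlation coefficient on
    box corners, McBride interpretation levels, challenging-to-localise
    flagging), saliency-map agreement metrics (histogram intersection SIM and
    regularized Kullback-Leibler divergence), the deterministic saliency
    operators used by globally-aware multiple-instance classifiers (top-t%
    pooling, greedy patch selection, patch aggregation, multi-scale fusion),
    the image standardization pipeline (breast segmentation, tight crop,
    laterality flip, bilinear resize), and concordance- and
    category-stratified sensitivity/specificity reporting with group
    comparison tests. A seeded synthetic cohort generator emulates screening
    cases, paired reader annotations and model-like saliency maps so the full
    pipeline runs without access to private screening data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
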