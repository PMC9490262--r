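Package: stromascope
Title: Whole-Slide Tumor-Stroma Reaction Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tumor-stroma reaction (TSR) on whole-slide histology
    images. Provides slide tiling with LAB-lightness foreground detection,
    polygon annotation parsing and rasterization, pluggable patch-level
    tumor/stroma segmentation and three-criterion TSR scoring backends with
    classical reference implementations, morphological tumor-stroma interface
    detection from stitched slide masks, slide-level TSR feature
    summarization, and downstream clinical (Cox proportional hazards) and
    molecular (Spearman correlation, over-representation) association
    analysis. Includes a synthetic phantom-slide and cohort generator with
    planted effects so the full pipeline can be exercised and validated
    end-to-end without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    jsonlite,
    survival,
    MASS,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
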