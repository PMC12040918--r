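Package: cxrseg
Title: Edge-Enhanced U-Net Segmentation of Chest Radiograph Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of chest radiograph-like grayscale images
    (lungs, heart, clavicles plus background) with gradient-based edge
    enhancement. Implements Sobel and Scharr edge operators with selectable
    border handling, CLAHE and adaptive mean thresholding for artifact
    suppression, a from-scratch U-Net (sigmoid multi-label output) trained
    with inverse-frequency class-weighted focal loss under a polynomial
    learning-rate decay, Dice/Jaccard/accuracy evaluation with stratified
    hold-out and k-fold protocols, and a seeded synthetic phantom generator
    so the whole pipeline is testable without external image data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
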