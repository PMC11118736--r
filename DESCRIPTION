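Package: lungfat
Title: Lung Slice Localization and Adipose Tissue Segmentation in Chest CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis of axial chest CT series: a convolutional
    bidirectional gated recurrent unit (ConvBiGRU) classifier localizes the
    first and last lung-bearing slices in an ordered slice sequence, and a
    multi-module UNet segments subcutaneous (SAT) and visceral (VAT) adipose
    tissue on the selected slice range. The UNet can be extended with
    multi-resolution fusion, competitive Maxout, and attention-gate blocks in
    any combination, giving an eight-way ablation harness. Training uses
    stochastic gradient descent with momentum and a smoothed Dice loss with
    an additive, logarithmically scaled class-weight penalty. A synthetic
    phantom generator produces 16-bit slice sequences with known SAT/VAT
    masks and localization labels so the full pipeline is exercisable and
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    png,
    stats,
    utils,
    grDevices
Suggests:
    mgcv,
    optparse,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
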