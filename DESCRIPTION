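Package: pitcount
Title: Automated Pitted Red Blood Cell Counting from DIC Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated workflow for counting pitted red blood cells
    (RBCs) in differential interference contrast (DIC) microscopy images,
    a surrogate biomarker of splenic filtration function. Provides a
    synthetic DIC scene simulator with exhaustive ground truth, a
    trainable multi-scale filter-bank and random-forest pixel classifier
    separating background, cells and pits, macro-style post-processing
    (hole filling, distance-transform watershed separation of adjoining
    cells, size/edge/solidity object filters), sample-level %PIT and pit
    morphometrics with splenic-function classification rules, and
    method-comparison statistics (Bland-Altman limits of agreement with
    stratified acceptance bounds, observer consensus maps, paired t-test,
    Pearson correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    ranger,
    jsonlite,
    tiff,
    png,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
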