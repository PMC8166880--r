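Package: igtd
Title: Transform Tabular Data into Images by Distance-Rank Matching
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts each row of a numeric table into a compact 2-D
    grayscale image by assigning features to pixel positions so that the
    ranking of pairwise feature distances matches the ranking of pairwise
    pixel distances. The assignment is found by an iterative feature-swap
    search that minimises the rank-difference error with an incremental
    update touching only the two swapped rows and columns. Includes the
    local-heterogeneity metric for judging how well an image layout keeps
    similar features adjacent, a block-correlated synthetic table generator
    with known neighbourhood structure, rendering and export of sample
    images, and a two-tower convolutional network (one subnetwork per input
    image, e.g. a cell-line expression image paired with a drug descriptor
    image) for downstream response regression, with exact trainable
    parameter accounting.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
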