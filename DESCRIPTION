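Package: cypridtrack
Title: Tracking and Behavioural Classification of Barnacle Cyprid Larvae
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated tracking of multiple barnacle cypris larvae (cyprids) in
    fixed-camera grayscale image sequences, and rule-based classification of
    their surface-exploration behaviour into swimming, wide search, close
    search and inspection events. Provides iterative background modelling,
    threshold segmentation with 8-connected labelling, identity-preserving
    multi-animal tracking with explicit resolution of merged and splitting
    blobs via ellipse-based cost functions, reduction of each animal to
    centre and terminal points, temporal dwell-node extraction, an ethogram
    assembler with Table-style summaries, and a seeded synthetic-data
    generator that renders behaviour-scripted larvae for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
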