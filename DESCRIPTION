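Package: fourcbricks
Title: 4C-Seq Interaction Analysis with Domainogram Brick Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 4C-seq (circularized chromosome conformation
    capture) data: builds virtual restriction-fragment libraries, converts
    aligned reads to per-fragment counts with self-ligation filtering,
    normalizes and smooths viewpoint profiles, removes the power-law
    distance-decay background, calls significantly interacting windows
    ("Bricks") at multiple scales with tiered false-discovery control, detects
    differential (ratio) Bricks between a rearranged and a control condition,
    and scores enrichment of interacting regions in genomic feature sets by
    interval shuffling. Includes a synthetic-data generator with planted
    interaction peaks and a hemizygous deletion so the full pipeline can be
    exercised and validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges,
    BiocGenerics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
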