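Package: barcodeNBC
Title: Naive Bayesian k-mer Classification of Insect COI DNA Barcodes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Rank-flexible taxonomic assignment of insect (class Insecta)
    cytochrome c oxidase subunit 1 (COI) barcode sequences with a naive
    Bayesian 8-mer classifier and bootstrap confidence estimation.
    Provides reference-database curation filters (length, ambiguity,
    insufficiently identified names, lineage completeness), readers and
    writers for the two-file training format (lineage-annotated FASTA
    plus a rank-taxonomy text file), leave-one-out cross-validation at
    full and partial query lengths, type I/II error and bootstrap-support
    cut-off calibration, coverage summaries against described-taxa
    censuses, and a sequence simulator with controlled divergence and
    taxon-coverage gaps for end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
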