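Package: barcodeForest
Title: Alignment-Free DNA Barcode Species Identification with Gapped
    Base-Pair Features and Random Forests
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Assigns species labels to DNA barcode sequences (fungal ITS
    and other markers) without alignment. Sequences are encoded as
    compositions of g-spaced nucleotide base pairs (ordered dinucleotides
    separated by exactly g skipped positions) and, optionally, contiguous
    k-mer compositions, then classified with a multiclass random forest.
    Includes out-of-bag-error driven tuning of the forest size and of the
    number of candidate features per split, species-stratified k-fold
    cross-validation scored by the species identification success rate
    (SISR), a seeded simulator of multi-species barcode reference
    libraries, and a command-line interface for training, prediction, and
    evaluation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    randomForest,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
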