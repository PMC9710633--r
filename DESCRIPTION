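Package: rbpattn
Title: Attention-Based Prediction and Interpretation of RNA-Protein Binding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts RNA-binding protein (RBP) target sites from RNA sequence
    with a k-mer-tokenized transformer encoder classifier, and interprets the
    trained model through its attention weights. Implements eCLIP-style dataset
    preparation (cleaning, balanced sampling, 64/16/20 splits), sequence-level
    relative attention to the CLS token, token-level attention ratios for RNA
    secondary-structure loop types, head-specialization statistics, and an
    attention-driven motif extraction pipeline with hypergeometric enrichment
    filtering and pairwise-alignment merging. A synthetic-data module generates
    motif-implanted sequence sets, region-type flags, well-formed dot-bracket
    structures and attention tensors with planted head specializations so the
    full pipeline can be exercised at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
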