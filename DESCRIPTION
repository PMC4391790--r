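Package: foldsignal
Title: Sequence Complexity and Structure-Derived Signals for Protein Fold Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Scores multiple-sequence-alignment columns by variability,
    normalized Shannon entropy and compression-based (bzip2) Kolmogorov
    complexity; derives per-residue structural tracks from CA traces and
    secondary-structure strings (HST/HSTD encoding, CA-triangle areas,
    rigid-body superposition and cognate-state displacements, contact maps);
    predicts residue-residue contacts by box-filtering the complexity scores
    and evaluates predictions with confusion counts and the Matthews
    correlation coefficient; correlates per-residue tracks; and generates
    synthetic alignments and toy CA traces for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
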