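Package: enhanceodimer
Title: Cell-Type-Specific Transcription-Factor Dimer Arrangements and the
    Interferon-Beta Enhanceosome
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects overrepresented transcription-factor dimer arrangements
    (motif pair, spacing, mutual orientation) in cell-type-specific open
    chromatin, matches them against the rigid binding-site architecture of
    the 57-bp interferon-beta enhanceosome with a configurable spacing
    tolerance, annotates dimer instances with chromatin states and gene
    context, and compares human and mouse gene selections through GO-term
    and ortholog-partition Fisher tests. Includes TRANSFAC matrix parsing,
    exact score-distribution dynamic programming for balanced motif
    thresholds, and seeded synthetic-data generators with planted ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
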