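Package: promoscan
Title: Scanning and Comparative Analysis of Sequence Motifs in Promoter Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scans 2-kb upstream promoter sequences for perfect short tandem
    repeats (periods 2-6, at least six units, with canonical motif families),
    CpG islands under the Gardiner-Garden-Frommer criteria with truncation at
    the transcription start site, potential G-quadruplex sequences under
    QGRS-style constraints, and fixed consensus motifs (TATA box, poly-A,
    poly-G, degenerate IUPAC patterns). Characterises motif abundance,
    positional distribution relative to the transcription start site, and
    spatial arrangement with respect to CpG islands, and provides the
    comparative statistical layer used in avian promoter-architecture studies:
    frequency-table correlation with minor-motif pruning, Kendall tau-b,
    Mann-Whitney U, Fisher's exact tests and Fisher-exact gene-ontology
    enrichment. A seeded synthetic promoter generator with ground-truth
    tables makes every stage testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
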