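Package: primerscreen
Title: In Silico Evaluation of Degenerate 16S rRNA Primers and
    Intergenomic Variation Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate degenerate 16S rRNA gene primer sets by
    in silico PCR with exact degeneracy-aware matching, compute per-taxon
    amplification coverage and apply two-stage candidate-selection rules,
    profile conserved and hypervariable regions of aligned 16S genes via
    per-column Shannon entropy in an anchored 1,500-column frame, and
    analyse primer binding-site conservation with sequence-logo
    information content and 3'-end mismatch flags.  A synthetic 16S-like
    sequence generator with a known conserved/variable architecture,
    taxonomy and planted primer-site mismatch fractions provides ground
    truth for every stage, so the whole pipeline is testable without any
    reference database download.
License: MIT
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
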