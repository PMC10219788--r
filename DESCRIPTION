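Package: uorfscout
Title: Annotation of Conserved Upstream Open Reading Frames
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates candidate upstream open reading frames (uORFs) in 5'
    upstream nucleotide sequences, scores prokaryotic Shine-Dalgarno elements
    by SD:anti-SD hybridization free energy, detects uORFs conserved across
    homologous upstream regions with a greedy search that maximizes the sum of
    pairwise alignment scores, builds center-star multiple sequence alignments
    with per-column sequence-logo statistics, and renders deterministic
    SVG annotation plots, sequence logos, and alignment figures. Includes a
    synthetic planted-uORF dataset generator for fully offline validation and
    an optional, pluggable NCBI retrieval adapter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    codetools,
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
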