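Package: chiptempo
Title: Temporal Transcription-Factor ChIP-Seq Occupancy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for transcription-factor ChIP-Seq
    occupancy measured across differentiation time points: six-category
    genomic annotation of peaks with strand-aware promoter/upstream/TTS
    windows, presence/absence temporal clustering of consensus binding
    regions with depth-normalized intensities, category enrichment against
    sampled random backgrounds, position-weight-matrix scanning with exact
    p-values and summit-distance profiles, metagene decile/flank
    IP-over-Input signal profiling with per-window rank-sum tests, and
    integration with knockdown differential expression and motif-site
    conservation using length-matched controls. Ships a fully specified
    synthetic-study generator with machine-readable ground truth so every
    stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
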