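Package: stresscycle
Title: Stress-Response Transcriptome Overlap, Protein Half-Life and qPCR
    Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative toolkit for bacterial stress-response studies.
    Classifies per-gene expression fold-changes into directional (up/down)
    regulated sets, scores the similarity of two regulons with a seeded
    Monte-Carlo intersection z-score validated against the hypergeometric
    closed form, estimates protein half-lives from translation shut-off
    (chloramphenicol chase) immunoblot time courses by log-linear
    regression, and implements comparative-Ct (delta-delta-Ct) qRT-PCR and
    ChIP-qPCR percent-of-input quantification. Includes seeded synthetic
    generators (fold-change tables with a planted shared regulon,
    exponential decay time courses, Ct tables) so the whole pipeline is
    testable without external data, plus TSV readers/writers and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    readxl,
    jsonlite
Config/testthat/edition: 3
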