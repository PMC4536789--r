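Package: chromhelix
Title: Polymer Models of Chromatin Contact-Frequency Decay Within
    Topological Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models and fits chromosome-conformation-capture (3C/Hi-C)
    contact-frequency decay curves within topologically associating
    domains (TADs). Implements the combined freely-jointed-chain /
    worm-like-chain contact-frequency model for an unconstrained
    chromatin fiber, its statistical-helix extension for constrained
    supranucleosomal dynamics, and globule power-law scalings; estimates
    cross-linking efficiency, linear compaction and Kuhn-segment
    flexibility by weighted nonlinear least squares with multi-start
    search; tests alternating supranucleosomal separation-distance
    domains with Mann-Whitney U statistics; converts binned Hi-C contact
    maps into per-anchor "virtual 3C" decay profiles stratified by TADs
    and epigenetic domains; and generates fully synthetic inputs
    (profiles, genome annotation, contact maps) with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    minpack.lm,
    Matrix,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
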