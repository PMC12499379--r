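Package: chromascope
Title: Multiscale Chromatin Contact-Map Analysis and In Silico Perturbation Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hierarchical analysis of chromosome-conformation (Hi-C style)
    contact maps: iterative-correction balancing, distance-decay expected
    and log fold over background, insulation scoring with TAD boundary
    calling, A/B compartment assignment by spectral clustering with a
    linear-discriminant score, a compartmentalization order parameter,
    chromatin-loop nesting hierarchies with valency statistics, regulatory
    annotation of genome fragments, and an in silico perturbation screen of
    accessibility and CTCF tracks driven by a deterministic mechanistic
    surrogate predictor. A synthetic contact-map generator with planted
    compartments, TADs and nested loops provides ground truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
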