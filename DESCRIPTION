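Package: refmiR
Title: Stability Analysis for Selecting Reference miRNAs in RT-qPCR Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for choosing stably expressed reference (normalizer) miRNAs
    from RT-qPCR quantification-cycle (Cq) data in two-group study designs.
    Provides Cq matrix input with technical-replicate quality control,
    amplification-efficiency estimation from serial-dilution standard curves,
    candidate exclusion rules (detection in all samples, between-group
    differential expression by Mann-Whitney U, gene-family co-regulation),
    four stability algorithms (geNorm M with iterative ranking and pairwise
    variation V, a model-based intra/inter-group variance decomposition in the
    NormFinder style, BestKeeper descriptive statistics, and the comparative
    delta-Ct method), consensus ranking by the geometric mean of ranks, and a
    synthetic Cq generator with a shared per-sample loading effect for
    validating the whole pipeline by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
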