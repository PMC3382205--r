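Package: vocnet
Title: Non-Targeted GC-MS Volatile Profiling by Multivariate Mass Spectra
    Reconstruction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Reconstructs volatile compounds from aligned GC-MS molecular
    fragment tables by correlation clustering under a retention-time window
    (multivariate mass spectra reconstruction), filters blank-borne and
    SPME-fiber contaminants, assembles pseudo-spectra and matches them
    against an MSP spectral library, quantifies compounds as log2 ratios to
    daily pooled reference samples, and derives metabolite-metabolite
    correlation networks and fruit-quality-trait correlation tables. A
    synthetic-data generator emulates a multi-genotype, multi-stage fruit
    volatile experiment (co-regulated compound groups, per-day fiber drift,
    blank contaminants, ripening-linked traits) so every pipeline stage can
    be scored against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
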