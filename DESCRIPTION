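Package: dualscreen
Title: Dual CRISPR Screen Analysis for Sorted-Bin Flow and Perturb-Seq Readouts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of pooled CRISPR knockout screens of epidermal
    differentiation read out two ways: a FACS sorted-bin (CRISPR-Flow)
    arm scored by UMI-deduplicated guide counting, alpha-robust rank
    aggregation with a permutation null and a Fisher-combined pseudo
    p-value (psi-P), and a Perturb-seq arm scored by principal-curve
    pseudotime (correlation distances, classical multidimensional
    scaling) with per-target Mann-Whitney shift tests and a Gaussian
    kernel-density sliding-window enrichment statistic on a 40-point
    pseudotime grid. Includes a seeded synthetic-data generator that
    plants known knockout effects so every stage can be validated
    against ground truth, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
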