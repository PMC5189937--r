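Package: sctipping
Title: Early-Warning Analysis of Critical State Transitions in
    Single-Cell Expression Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects impending critical state transitions (tipping points)
    in differentiating cell populations from single-cell expression
    snapshots. Computes the critical-transition index I_C, the ratio of
    the average absolute gene-gene Pearson correlation to the average
    cell-cell Pearson correlation of a cell ensemble, together with
    bootstrap uncertainty, permutation significance, and gene-subsampling
    robustness. Includes quantification-cycle (Cq) preprocessing for
    single-cell qPCR data (replicate collapsing, limit-of-detection
    filtering, delta-Cq normalization), principal-component state-space
    projection with a quasi-potential landscape, and a stochastic
    gene-regulatory-network simulator that drives cell ensembles through
    a pitchfork-like bifurcation to generate synthetic benchmark data
    exhibiting the early-warning phenomenology: falling cell-cell
    correlation, rising gene-gene correlation, critical slowing down,
    and rebellious cells entering the non-intended fate.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
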