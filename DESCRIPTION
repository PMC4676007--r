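Package: plvnet
Title: Phase-Locking Functional Networks for Thalamocortical Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multichannel local field potential (LFP)
    and spike recordings from the somatosensory thalamocortical axis.
    Extracts instantaneous phases by the analytic signal, measures pairwise
    synchrony with the phase-locking value (PLV) in sliding windows, builds
    percentile-thresholded binary functional graphs with admissibility
    filtering, and summarises them with small-world statistics (clustering
    coefficient, characteristic path length, betweenness centrality).
    Includes spike-train quality control and firing-rate analysis, Wilcoxon
    rank-sum comparisons with Bonferroni correction across a group-by-
    condition design, and a coupled-oscillator synthetic-recording generator
    with ground truth so the whole chain runs and is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
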