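Package: ssvepTRCA
Title: SSVEP Frequency Recognition via Task-Related Component Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Frequency recognition for steady-state visual evoked potential
    (SSVEP) brain-computer interfaces. Implements two-step task-related
    component analysis (TSTRCA), in which TRCA spatial filters learned for
    every stimulus frequency are reused as an ensemble and fused by signed
    squared correlations, together with the canonical correlation analysis
    (CCA), extended CCA and standard TRCA baselines and their filter-bank
    variants. Includes Chebyshev band-pass preprocessing with latency-aware
    window extraction, a synthetic SSVEP generator with controllable
    signal-to-noise ratio and inter-trial reproducibility, and a
    leave-one-block-out evaluation harness reporting accuracy, information
    transfer rate and precision/recall/F1.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
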