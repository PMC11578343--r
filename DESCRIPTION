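Package: visconps
Title: Single-Cell Viscoelastic Phenotyping from Multi-Zone Node-Pore Sensing Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multi-zone node-pore sensing (NPS)
    resistance traces for single-cell mechanophenotyping. Cells transiting a
    microfluidic channel with a Coulter sizing pore and a series of sinusoidal
    contraction zones produce cascading resistive pulses; the package sizes each
    cell from its pore pulse, reconstructs the oscillatory stress it experienced
    in every contraction zone from the in-pulse resistance modulation, and
    extracts the frequency-dependent storage (G') and loss (G'') moduli by
    linear least squares against the standard oscillatory-rheology relationship.
    Includes a forward simulator with ground truth for end-to-end validation,
    a full signal-processing pipeline (zero-phase low-pass filtering, moving
    median, robust baseline tracking, event detection and cross-channel
    matching), population-level statistics (Tukey-fence outlier removal, rank
    tests, cross-zone heterogeneity scores), heatmap displays, and a thin
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
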