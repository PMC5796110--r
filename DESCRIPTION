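Package: drgexcite
Title: Excitability Typing of Large Dorsal Root Ganglion Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of large dorsal root ganglion
    (DRG) sensory neurons and a pipeline that types their excitability in
    the Hodgkin scheme (Class 1, 2-1, 2-2 and 3) from current-clamp
    recordings: spike detection, rheobase by bisection over step
    amplitudes, intensity-frequency (I-F) curve analysis, subthreshold
    membrane-potential oscillation detection, passive membrane properties,
    quantification of the hyperpolarization-activated cation current (Ih)
    from voltage-clamp step families, and cohort-level statistics (Pearson
    chi-square tests of class-proportion shifts, one-way ANOVA with
    uncorrected Fisher's LSD comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
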