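Package: strokeeg
Title: Quantitative EEG Biomarkers of Ischemic Stroke and tDCS Intervention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of quantitative EEG biomarkers used to
    track ischemic stroke and transcranial direct current stimulation (tDCS)
    intervention effects. Provides per-band relative power from Welch spectra,
    Lempel-Ziv complexity of median-symbolized epochs, and sample entropy,
    computed on zero-phase band-pass filtered signals over the delta, theta,
    alpha and beta bands, with four-group one-way ANOVA and eta-squared effect
    sizes. Includes a seeded synthetic EEG generator that emulates a
    Control / MCAO / MCAO+tDCS / MCAO+Sham cohort so the full pipeline can be
    exercised and calibrated without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    tibble,
    jsonlite,
    yaml,
    car,
    rlang,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
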