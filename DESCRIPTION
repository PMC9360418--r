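Package: n1sense
Title: Developmental Visual N1 Category-Sensitivity Analysis for Longitudinal EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for developmental event-related
    potential (ERP) studies of visual category sensitivity. Generates synthetic
    longitudinal EEG cohorts (geodesic-style montage, three-condition
    single-character target-detection design, N1 component with
    condition-dependent occipito-temporal amplitude, 1/f background noise,
    artifact epochs), preprocesses continuous recordings (zero-phase band-pass
    and notch filtering, downsampling, channel interpolation, common average
    reference, epoching with amplitude-threshold rejection and minimum-epoch
    inclusion), extracts ERP features (global field power, data-driven N1
    window around the second GFP local maximum, occipito-temporal cluster mean
    amplitudes, coarse and fine digit-sensitivity differences), performs
    topographic permutation testing (TANOVA on strength-normalized maps) and
    electrode-wise t-maps, fits random-intercept linear mixed models with
    normalized-residual outlier exclusion and signed per-timepoint contrasts,
    and computes Spearman brain-behavior correlation grids with
    Benjamini-Hochberg false discovery rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    emmeans,
    generics,
    ggplot2,
    jsonlite,
    nlme,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
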