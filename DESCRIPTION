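Package: bpci
Title: Cuff-Less Blood Pressure Estimation with Per-Subject Confidence Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for estimating systolic and diastolic blood pressure from
    synchronized photoplethysmogram (PPG) and electrocardiogram (ECG) waveforms
    without a cuff, together with per-subject confidence intervals. The pipeline
    covers dual-stage preprocessing (maximal-overlap discrete wavelet transform
    denoising with empirical-Bayes Cauchy shrinkage, zero-phase high-pass
    filtering, beat segmentation, and wavelet-enhanced R-peak detection), a
    rule-plus-template signal-quality index, a 47-entry timing/morphology/
    statistical feature set with arterial-line reference pressures, minimum-
    redundancy-maximum-relevance feature ranking combined with gradient-boosted
    regression trees for weighted feature decisions, Gaussian process regression
    with marginal-likelihood hyperparameter fitting, and four interval
    constructions (GPR posterior, parametric bootstrap, GUM expanded
    uncertainty, and central-limit Monte Carlo). Evaluation helpers implement
    AAMI/ESH error criteria, BHS cumulative-percentage grading, and
    Bland-Altman agreement limits. A synthetic three-channel waveform generator
    with known per-beat ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
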