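# bpci

Cuff-less blood-pressure estimation from synchronized PPG and ECG waveforms,
with per-subject confidence intervals.

## The problem

Home and bedside cuff-less monitors estimate systolic and diastolic blood
pressure (SBP/DBP) from the photoplethysmogram (PPG) and electrocardiogram
(ECG) instead of an inflatable cuff. Almost all of them report a single
number per reading, with no statement of how uncertain that number is —
although physiological variability, sensor noise and model error all push
the estimate away from the true pressure. `bpci` implements a complete
estimation pipeline that ends in an *interval*, not a point:

1. **Dual-stage preprocessing.** Each 20-s analysis window (2500 samples at
   125 Hz) is denoised by a 10-level maximal-overlap discrete wavelet
   transform (db8) with empirical-Bayes Cauchy posterior-median shrinkage of
   the fine details, the coarse details d7–d10 and the approximation zeroed,
   then high-passed at 0.5 Hz with a zero-phase IIR filter. R peaks are
   detected on a sym4 reconstruction of detail levels 2–3.
2. **Signal-quality index (SQI).** Three physiological rules (heart rate in
   40–180 bpm, no inter-beat gap over 3 s, max/min interval ratio below 2.2)
   followed by adaptive template matching of PPG pulses and QRS complexes;
   windows are labeled *trusted* or *untrusted*.
3. **Features.** 47 timing, morphology, area, width, spectral and
   statistical descriptors per 1.4-s beat segment (ST, DT, PAT1–3, PIR,
   LASI, AUI, A1–A4, SW/DW widths at six amplitude fractions, …) with
   reference SBP/DBP read off the arterial-line (ABP) channel.
4. **Weighted feature decision (WFD).** Minimum-redundancy
   maximum-relevance (MRMR) ranking by mutual-information quotient, then a
   cross-validated search over ranking prefixes scored by the test MSE of a
   from-scratch gradient-boosted regression-tree engine (50 stages, exact
   squared-error line search). The prefix with the lowest CV error is the
   selected feature set.
5. **Gaussian process regression (GPR).** Exponential kernel by default,
   hyperparameters `(eta, sigma^2, sigma_f^2)` fit by multi-restart
   quasi-Newton ascent of the log marginal likelihood (analytic gradients,
   Cholesky factorizations, basis weights profiled in closed form). The
   posterior supplies both the BP estimate and its predictive SD.
6. **Per-subject confidence intervals**, four ways, from the ~10
   segment-level estimates each 20-s window yields per subject:
   - `gpr` — posterior mean ± z · mean predictive SD;
   - `boot` — parametric bootstrap: Gaussian MLE refit, `n × B` redraws,
     percentile interval of the B column means;
   - `uncer` — GUM expanded uncertainty `U = K · u_c`,
     `u_c = sqrt(u_alpha^2 + u_beta^2 + u_gamma^2)` with the Type A
     component `u_alpha = sd/sqrt(n)` and a 1-mmHg reference allowance;
   - `monte` — the central-limit interval `mean ± z · s/sqrt(n)`.

Evaluation helpers grade results against the AAMI/ESH criterion
(|ME| ≤ 5 mmHg and SD ≤ 8 mmHg), the BHS cumulative-percentage tiers, and
Bland–Altman agreement limits (ME ± 2·SD).

A synthetic three-channel generator with known per-beat ground truth
(R-peak times, pulse feet, per-beat SBP/DBP, and a shared `SBP = a − b·PTT`
coupling) makes the whole pipeline testable without any waveform database;
see the methods vignette (`vignettes/bpci-methods.Rmd`) for what it does and
does not emulate.

## Worked example

```r
library(bpci)

rec <- generate_record(
  subject_profile(hr_bpm = 72, noise_sd = c(ppg = 0.01, ecg = 0.01, abp = 0.5)),
  duration_s = 81, fs = 125, seed = 7)
win <- extract_window(rec)          # the 20-s window after the first 60 s
pre <- preprocess_window(win)
classify_segment(pre)
#> # A tibble: 1 x 6
#>   record_id rule1 rule2 rule3 mean_template_corr label
#>   <chr>     <lgl> <lgl> <lgl>              <dbl> <chr>
#> 1 synth-7   TRUE  TRUE  TRUE               0.990 trusted

fids  <- detect_ppg_fiducials(pre$ppg, 125)
feats <- extract_features(pre, segment_window(pre, fids))
feats[1:3, c("HR", "PAT2", "PAT3", "PIR", "PPGk", "sbp", "dbp")]
#> # A tibble: 3 x 7
#>      HR  PAT2  PAT3   PIR  PPGk   sbp   dbp
#> 1  72.8 0.392 0.264  2.97 0.336  123.  82.3
#> 2  73.5 0.392 0.232  2.98 0.335  123.  81.9
#> 3  72.8 0.4   0.248  2.93 0.342  121.  81.0
```

The window is trusted (all three rules pass; mean template correlation
0.99), and the twelve 1.4-s beat segments each yield the 47 features plus
reference pressures around 122/82 mmHg. Feeding the twelve segment-level
SBP estimates into the four interval constructions:

```r
cis <- subject_cis(
  tibble::tibble(subject_id = "subj-1", estimate = feats$sbp, sd = 2),
  target = "sbp", B = 1000, seed = 1)
cis[, c("method", "center", "lower", "upper", "width")]
#> # A tibble: 4 x 5
#>   method center lower upper width
#> 1 gpr      122.  118.  125.  7.84
#> 2 boot     122.  120.  123.  2.18
#> 3 uncer    122.  119.  124.  4.56
#> 4 monte    122.  120.  123.  2.14
```

The ordering is the expected one: the GPR posterior interval is widest (it
covers single-beat prediction error), the expanded-uncertainty interval
keeps a ≥ 4 mmHg floor from the 1-mmHg reference allowance, and the
bootstrap and central-limit intervals — both targeting the *mean* of the
subject's estimates — are the narrowest and agree closely.

For the full chain on a cohort (generation → SQI → features → WFD → GPR →
evaluation → CIs) see `run_pipeline()`.

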