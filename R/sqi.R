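#' Physiological plausibility rules for signal quality
#'
#' Three rules applied sequentially to the detected beat train of a 20-s
#' window: (1) the extrapolated heart rate must lie in `[hr_lo, hr_hi]` bpm;
#' (2) no inter-peak gap may exceed `max_gap` seconds (at most one missed
#' beat); (3) the max/min inter-peak interval ratio must stay below
#' `interval_ratio_max` — the heart rate should not swing more than a missed
#' beat's worth within 20 s. The printed "2.2 s" limit for rule 3 is read as
#' a unitless max/min interval ratio of 2.2 (a ratio is what "maximum to
#' minimum beat interval ratio" describes).
#'
#' @param hr_lo,hr_hi Heart-rate band in bpm.
#' @param max_gap Maximum inter-peak interval in seconds.
#' @param interval_ratio_max Maximum max/min interval ratio.
#' @return A `bp_sqi_rules` list.
#' @export
sqi_rules <- function(hr_lo = 40, hr_hi = 180, max_gap = 3,
                      interval_ratio_max = 2.2) {
  stopifnot(hr_lo < hr_hi, max_gap > 0, interval_ratio_max > 1)
  structure(list(hr_lo = hr_lo, hr_hi = hr_hi, max_gap = max_gap,
                 interval_ratio_max = interval_ratio_max),
            class = "bp_sqi_rules")
}

#' Evaluate the three SQI rules on a beat train
#'
#' @param peak_indices Ascending 1-based sample indices of detected beats.
#' @param fs Sampling rate (Hz).
#' @param window_s Window duration in seconds (HR is extrapolated to 60 s
#'   from the beat count in this window).
#' @param rules A [sqi_rules()].
#' @return A tibble row with logicals `rule1`, `rule2`, `rule3` and a
#'   `reason` string (`"insufficient_peaks"` fails all three when fewer than
#'   two peaks are present).
#' @export
check_rules <- function(peak_indices, fs, window_s = 20, rules = sqi_rules()) {
  stopifnot(window_s > 0)
  if (length(peak_indices) < 2) {
    return(tibble::tibble(rule1 = FALSE, rule2 = FALSE, rule3 = FALSE,
                          reason = "insufficient_peaks"))
  }
  iv <- diff(peak_indices) / fs
  hr <- length(peak_indices) * 60 / window_s
  rule1 <- hr >= rules$hr_lo && hr <= rules$hr_hi
  rule2 <- max(iv) <= rules$max_gap
  rule3 <- (max(iv) / min(iv)) < rules$interval_ratio_max
  tibble::tibble(rule1 = rule1, rule2 = rule2, rule3 = rule3,
                 reason = NA_character_)
}

#' Mean correlation of individual beats with their average template
#'
#' Each beat is a window of width equal to the median beat interval,
#' centered on its detected peak; the template is the pointwise mean of all
#' complete beats, and the result is the mean Pearson correlation of each
#' beat with that template. Beats truncated at the signal edges are
#' excluded rather than zero-padded, so artifacts cannot hide behind
#' deflated padding.
#'
#' @param x Signal vector (PPG or QRS-enhanced ECG).
#' @param peak_indices Ascending beat indices (>= 2).
#' @param fs Sampling rate (Hz).
#' @return Mean correlation in `[-1, 1]`.
#' @export
template_correlation <- function(x, peak_indices, fs) {
  if (length(peak_indices) < 2) {
    abort("Need at least 2 peaks for template matching.",
          class = "bpci_input_error")
  }
  width <- round(median(diff(peak_indices)))
  half <- width %/% 2
  lo <- peak_indices - half
  hi <- peak_indices + (width - half) - 1L
  ok <- lo >= 1 & hi <= length(x)
  if (!any(ok)) {
    abort("All beats are edge-truncated; template correlation undefined.",
          class = "bpci_undefined_correlation")
  }
  beats <- vapply(which(ok), function(k) x[lo[k]:hi[k]], numeric(width))
  template <- rowMeans(beats)
  if (sd(template) == 0) return(0)
  corrs <- apply(beats, 2, function(b) {
    if (sd(b) == 0) 0 else cor(b, template)
  })
  mean(corrs)
}

#' Classify a 20-s window as trusted or untrusted
#'
#' Applies the three plausibility rules to both the ECG R-peak train and the
#' PPG pulse-peak train (both must pass — the strict joint reading of
#' "QRS/PPG pulse template matching"). Any rule failure short-circuits: the
#' template step is skipped and the window is untrusted with
#' `mean_template_corr = NA`. Otherwise the window is trusted iff the mean
#' of the PPG-pulse and QRS template correlations reaches `corr_threshold`.
#'
#' The correlation cut-off is the pipeline's one large free constant; 0.8 is
#' the package default and should be revisited for new sensors.
#'
#' @param window A preprocessed `bp_record` window.
#' @param rules A [sqi_rules()].
#' @param corr_threshold Template-correlation acceptance threshold.
#' @return A tibble row (`record_id`, rule flags per channel collapsed with
#'   AND, `mean_template_corr`, `label`).
#' @export
classify_segment <- function(window, rules = sqi_rules(), corr_threshold = 0.8) {
  fs <- record_fs(window)
  window_s <- nrow(window) / fs
  r_idx <- detect_rpeaks(window$ecg, fs)
  p_idx <- tryCatch(detect_ppg_fiducials(window$ppg, fs)$peak,
                    error = function(e) integer(0))
  rc_e <- check_rules(r_idx, fs, window_s, rules)
  rc_p <- check_rules(p_idx, fs, window_s, rules)
  rule1 <- rc_e$rule1 && rc_p$rule1
  rule2 <- rc_e$rule2 && rc_p$rule2
  rule3 <- rc_e$rule3 && rc_p$rule3
  if (!(rule1 && rule2 && rule3)) {
    return(tibble::tibble(record_id = record_id(window),
                          rule1 = rule1, rule2 = rule2, rule3 = rule3,
                          mean_template_corr = NA_real_, label = "untrusted"))
  }
  # QRS correlations are computed on the same enhanced signal the detector saw
  qrs <- modwt_reconstruct(modwt(window$ecg, "sym4", 4), keep_d = c(2, 3))
  corr <- mean(c(template_correlation(window$ppg, p_idx, fs),
                 template_correlation(qrs, r_idx, fs)))
  tibble::tibble(record_id = record_id(window),
                 rule1 = rule1, rule2 = rule2, rule3 = rule3,
                 mean_template_corr = corr,
                 label = if (corr >= corr_threshold) "trusted" else "untrusted")
}
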