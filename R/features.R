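#' Canonical names of the 47 beat-segment features
#'
#' Timing: ST, DT, CT, IBI, HR, PAT1-3. Amplitude/shape: PIR, LASI, AUI,
#' PPGk, MXAP, MIAP, MEU, FHR, first/second-derivative descriptors. Areas:
#' A1-A4, IPAR, SA, DA, areaPPG. Widths: SW/DW at 10/25/33/50/66/75% of the
#' pulse amplitude. Spectral/statistical: MPSD, MCORR, Skew, Kurt, Entr.
#'
#' @return Character vector of length 47.
#' @export
feature_names <- function() {
  c("ST", "DT", "PIR", "HR", "PAT1", "PAT2", "PAT3", "LASI", "AUI",
    "A1", "A2", "A3", "A4", "IPAR", "PPGk",
    "dPPG_H", "dPPG_W", "ddPPG_PH", "ddPPG_TH", "ddPPG_W", "ddPPG_H",
    "SA", "DA", "areaPPG", "IBI", "MXAP", "MIAP", "MEU", "FHR", "CT",
    "MPSD", "MCORR", "Skew", "Kurt", "Entr",
    paste0("SW", c(10, 25, 33, 50, 66, 75)),
    paste0("DW", c(10, 25, 33, 50, 66, 75)))
}

#' Basic waveform parameters of a single PPG pulse
#'
#' Cuts the pulse between two troughs, shifts it so its minimum is zero,
#' and derives: duration `ppgt = (pt2 - pt1)/fs`, mean height
#' `pm = area / duration` (the sample mean of the shifted pulse), extreme
#' amplitudes `ps`/`pd`, and the normalized mean height
#' `ppgc = (pm - pd)/(ps - pd)`.
#'
#' @param ppg PPG vector.
#' @param pt1,pt2 Trough indices bounding one pulse (1-based, `pt1 < pt2`).
#' @param fs Sampling rate (Hz).
#' @return List `ppgp` (shifted pulse), `ppgt`, `pm`, `ps`, `pd`, `ppgc`.
#' @export
waveform_params <- function(ppg, pt1, pt2, fs) {
  stopifnot(pt1 < pt2, pt2 <= length(ppg))
  ppgp <- ppg[pt1:pt2]
  ppgp <- ppgp - min(ppgp)
  ps <- max(ppgp); pd <- min(ppgp)
  if (ps <= pd + .Machine$double.eps * 10) {
    abort("Degenerate (flat) pulse: ps == pd.", class = "bpci_degenerate_pulse")
  }
  ppgt <- (pt2 - pt1) / fs
  pm <- mean(ppgp)
  list(ppgp = ppgp, ppgt = ppgt, pm = pm, ps = ps, pd = pd,
       ppgc = (pm - pd) / (ps - pd))
}

# linear-interpolated time (s, relative to pulse start) at which the shifted
# pulse first crosses `level` moving toward the peak (dir = 1 rising limb,
# searching foot->peak) or away from it (dir = -1 falling limb, peak->end)
crossing_time <- function(p, peak_i, level, fs, dir) {
  if (dir > 0) {
    seg <- seq_len(peak_i)
    above <- which(p[seg] >= level)
    if (length(above) == 0) return(NA_real_)
    i <- above[1]
    if (i == 1) return((i - 1) / fs)
  } else {
    seg <- peak_i:length(p)
    below <- which(p[seg] <= level)
    if (length(below) == 0) return((length(p) - 1) / fs)
    i <- peak_i + below[1] - 1L
    if (i == peak_i) return((i - 1) / fs)
  }
  # interpolate between i-1 and i
  x0 <- p[i - 1L]; x1 <- p[i]
  frac <- if (x1 == x0) 0 else (level - x0) / (x1 - x0)
  ((i - 2L) + frac) / fs
}

trapz <- function(y, dx) {
  if (length(y) < 2) return(0)
  dx * sum((y[-1] + y[-length(y)]) / 2)
}

# Shannon entropy (nats) of a 16-bin amplitude histogram of the 0-1
# normalized pulse
pulse_entropy <- function(p, bins = 16) {
  r <- range(p)
  if (diff(r) == 0) return(0)
  u <- (p - r[1]) / diff(r)
  cnt <- tabulate(pmin(bins, floor(u * bins) + 1L), nbins = bins)
  pr <- cnt[cnt > 0] / sum(cnt)
  -sum(pr * log(pr))
}

# max normalized cross-correlation between two equal-length segments over
# lags up to max_lag samples
max_xcorr <- function(a, b, max_lag) {
  n <- length(a)
  best <- -1
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      ia <- (1 + lag):n; ib <- 1:(n - lag)
    } else {
      ia <- 1:(n + lag); ib <- (1 - lag):n
    }
    if (length(ia) < 8) next
    if (sd(a[ia]) == 0 || sd(b[ib]) == 0) next
    best <- max(best, cor(a[ia], b[ib]))
  }
  best
}

# Features of one beat-segment. `fid` is one row of detect_ppg_fiducials();
# `fids` the full table (for IBI); `rpeaks` ECG R-peak indices; all indices
# refer to the parent window.
segment_features <- function(ppg, abp, fid, fids, rpeaks, fs,
                             seg_len, ptt_offset = 0, with_abp = TRUE) {
  f0 <- fid$foot; pk <- fid$peak; f1 <- fid$foot_next
  wp <- waveform_params(ppg, f0, f1, fs)
  p <- wp$ppgp
  peak_i <- pk - f0 + 1L
  infl_i <- fid$inflection - f0 + 1L
  ms_i <- fid$max_slope - f0 + 1L
  dx <- 1 / fs

  ST <- (pk - f0) / fs
  DT <- (f1 - pk) / fs
  CT <- wp$ppgt
  # R peak anchoring this beat: last R at or before the pulse foot
  r_prev <- rpeaks[rpeaks <= f0]
  r_this <- if (length(r_prev) > 0) r_prev[length(r_prev)] else NA_integer_
  r_next <- rpeaks[rpeaks > r_this][1]
  HR <- if (!is.na(r_this) && !is.na(r_next)) 60 / ((r_next - r_this) / fs) else NA_real_
  PAT1 <- if (!is.na(r_this)) (pk - r_this) / fs else NA_real_
  PAT2 <- if (!is.na(r_this)) (fid$max_slope - r_this) / fs else NA_real_
  PAT3 <- if (!is.na(r_this)) (f0 - r_this) / fs else NA_real_
  # IBI: this systolic peak to the next pulse's systolic peak
  nxt <- fids$peak[fids$peak > pk]
  IBI <- if (length(nxt) > 0) (nxt[1] - pk) / fs else CT

  PIR <- wp$ps / wp$pm                     # peak over mean, baseline-shifted
  LASI <- if (infl_i > peak_i) 1 / ((infl_i - peak_i) / fs) else NA_real_
  AUI <- p[infl_i] / p[peak_i]
  PPGk <- wp$ppgc

  A1 <- trapz(p[1:ms_i], dx)
  A2 <- trapz(p[ms_i:peak_i], dx)
  A3 <- trapz(p[peak_i:infl_i], dx)
  A4 <- trapz(p[infl_i:length(p)], dx)
  IPAR <- A4 / (A1 + A2 + A3)
  SA <- trapz(p[1:peak_i], dx)
  DA <- trapz(p[peak_i:length(p)], dx)
  areaPPG <- trapz(p, dx)

  d1 <- diff(p) * fs
  dPPG_H <- max(d1)
  hm <- which(d1 >= dPPG_H / 2)
  dPPG_W <- if (length(hm) > 0) (hm[length(hm)] - hm[1] + 1) / fs else NA_real_
  d2 <- diff(d1) * fs
  ddPPG_PH <- max(d2)
  ddPPG_TH <- min(d2)
  ddPPG_H <- ddPPG_PH - ddPPG_TH
  ddPPG_W <- abs(which.max(d2) - which.min(d2)) / fs

  MXAP <- wp$ps
  MIAP <- wp$pd
  # viscosity proxy: how far the pulse has decayed two-thirds into diastole
  i_meu <- min(length(p), peak_i + round(0.66 * (length(p) - peak_i)))
  MEU <- p[i_meu] / p[peak_i]
  # dominant frequency of the segment (Hz) from the periodogram
  psd <- Mod(fft(p - mean(p)))^2
  half <- 2:floor(length(p) / 2)
  freqs <- (half - 1) * fs / length(p)
  FHR <- freqs[which.max(psd[half])]
  MPSD <- max(psd[half]) / length(p)

  MCORR <- if (with_abp && all(is.finite(abp[f0:f1]))) {
    a_seg <- ppg[f0:min(f0 + seg_len - 1L, length(ppg))]
    b_seg <- abp[f0:min(f0 + seg_len - 1L, length(abp))]
    max_xcorr(a_seg, b_seg, round(0.4 * fs))
  } else NA_real_

  Skew <- e1071::skewness(p, type = 2)
  Kurt <- e1071::kurtosis(p, type = 2)
  Entr <- pulse_entropy(p)

  widths <- purrr::map(c(10, 25, 33, 50, 66, 75) / 100, function(h) {
    lv <- h * wp$ps
    t_r <- crossing_time(p, peak_i, lv, fs, dir = 1)
    t_pk <- (peak_i - 1) / fs
    sw <- t_pk - t_r
    t_f <- crossing_time(p, peak_i, lv, fs, dir = -1)
    dw <- t_f - t_pk
    c(sw = sw, dw = dw)
  })
  sw <- vapply(widths, `[[`, numeric(1), "sw")
  dw <- vapply(widths, `[[`, numeric(1), "dw")

  out <- tibble::tibble(
    ST = ST, DT = DT, PIR = PIR, HR = HR, PAT1 = PAT1, PAT2 = PAT2,
    PAT3 = PAT3, LASI = LASI, AUI = AUI, A1 = A1, A2 = A2, A3 = A3,
    A4 = A4, IPAR = IPAR, PPGk = PPGk, dPPG_H = dPPG_H, dPPG_W = dPPG_W,
    ddPPG_PH = ddPPG_PH, ddPPG_TH = ddPPG_TH, ddPPG_W = ddPPG_W,
    ddPPG_H = ddPPG_H, SA = SA, DA = DA, areaPPG = areaPPG, IBI = IBI,
    MXAP = MXAP, MIAP = MIAP, MEU = MEU, FHR = FHR, CT = CT, MPSD = MPSD,
    MCORR = MCORR, Skew = Skew, Kurt = Kurt, Entr = Entr)
  for (i in seq_along(sw)) out[[paste0("SW", c(10, 25, 33, 50, 66, 75)[i])]] <- sw[i]
  for (i in seq_along(dw)) out[[paste0("DW", c(10, 25, 33, 50, 66, 75)[i])]] <- dw[i]
  out$ptt <- if (!is.na(PAT2)) PAT2 - ptt_offset else NA_real_
  out
}

#' Reference systolic/diastolic pressure from an ABP segment
#'
#' Detects per-beat extrema of the arterial waveform: SBP is the mean of the
#' per-beat maxima, DBP the mean of the per-beat minima.
#'
#' @param abp ABP vector (mmHg).
#' @param fs Sampling rate (Hz).
#' @return Named numeric `c(sbp = , dbp = )`.
#' @export
reference_bp <- function(abp, fs = 125) {
  # light smoothing before taking extrema: the max/min of a noisy trace is
  # a biased estimator (noise inflates the max and deflates the min)
  k <- max(1L, round(0.04 * fs))
  if (k > 1) {
    sm <- as.numeric(stats::filter(abp, rep(1 / k, k), sides = 2))
    abp <- ifelse(is.na(sm), abp, sm)
  }
  rng <- max(abp) - min(abp)
  if (!is.finite(rng) || rng < 1e-6) {
    abort("No detectable beat in the ABP segment (flat signal).",
          class = "bpci_degenerate_pulse")
  }
  thr <- rep(min(abp) + 0.5 * rng, length(abp))
  peaks <- peak_search(abp, fs, thr, refractory_s = 0.3)
  if (length(peaks) == 0) {
    abort("No detectable beat in the ABP segment.",
          class = "bpci_degenerate_pulse")
  }
  sbp <- mean(abp[peaks])
  dbp <- if (length(peaks) >= 2) {
    mean(vapply(seq_len(length(peaks) - 1L),
                function(k) min(abp[peaks[k]:peaks[k + 1]]), numeric(1)))
  } else {
    min(abp)
  }
  c(sbp = sbp, dbp = dbp)
}

#' Extract the 47-feature table from a preprocessed, segmented window
#'
#' One row per accepted beat-segment, with the 47 named features, the
#' auxiliary `ptt` column (PAT2 minus a configurable pre-ejection constant —
#' a cuff-less system has no aortic-valve signal, so pulse *arrival* time
#' stands in for transit time), the per-segment reference `sbp`/`dbp` from
#' the ABP channel (when present), and `subject_id`. Segments whose features
#' contain non-finite values are dropped and counted in the
#' `n_rejected` attribute.
#'
#' @param window Preprocessed `bp_record` (see [preprocess_window()]).
#' @param segmentation Output of [segment_window()] (must be accepted).
#' @param ptt_offset Pre-ejection constant subtracted from PAT2 (s).
#' @param with_abp Compute the ABP-dependent MCORR feature and reference
#'   pressures? Disable for deployment data without an arterial line.
#' @return Tibble of accepted segments.
#' @export
extract_features <- function(window, segmentation, ptt_offset = 0,
                             with_abp = TRUE) {
  if (!isTRUE(segmentation$accepted)) {
    abort(sprintf("Window was rejected (%s); no features to extract.",
                  segmentation$reason), class = "bpci_input_error")
  }
  fs <- record_fs(window)
  segs <- segmentation$segments
  rpeaks <- detect_rpeaks(window$ecg, fs)
  have_abp <- with_abp && any(is.finite(window$abp))
  rows <- purrr::map_dfr(seq_len(nrow(segs)), function(k) {
    fid <- segs[k, ]
    feats <- tryCatch(
      segment_features(window$ppg, window$abp, fid, segs, rpeaks, fs,
                       seg_len = fid$length, ptt_offset = ptt_offset,
                       with_abp = have_abp),
      error = function(e) NULL)
    if (is.null(feats)) return(NULL)
    if (have_abp) {
      ref <- tryCatch(
        reference_bp(window$abp[fid$start:min(fid$start + fid$length - 1L,
                                              nrow(window))], fs),
        error = function(e) c(sbp = NA_real_, dbp = NA_real_))
      feats$sbp <- ref[["sbp"]]
      feats$dbp <- ref[["dbp"]]
    }
    feats$subject_id <- record_id(window)
    feats$segment <- k
    feats$t_foot <- (fid$foot - 1) / fs   # window-relative pulse-onset time
    feats
  })
  if (nrow(rows) == 0) {
    attr(rows, "n_rejected") <- nrow(segs)
    return(rows)
  }
  # MCORR may be NA when no ABP; every other feature must be finite
  chk <- rows[, setdiff(feature_names(), "MCORR")]
  finite <- apply(as.matrix(chk), 1, function(r) all(is.finite(r)))
  out <- rows[finite, , drop = FALSE]
  attr(out, "n_rejected") <- sum(!finite)
  out
}

#' Assemble a labeled train/validation/test dataset
#'
#' Applies the blood-pressure range filter to the labels, then splits rows
#' deterministically (by `seed`) into train/validation/test fractions —
#' 80/10/10 by default. `mode = "by_subject"` keeps every subject's rows in
#' a single split.
#'
#' @param rows Feature tibble with `sbp`, `dbp`, `subject_id` columns.
#' @param split Numeric fractions summing to 1.
#' @param seed Integer seed for the shuffle.
#' @param mode `"by_sample"` or `"by_subject"`.
#' @param policy Range-filter policy (see [range_filter_policy()]).
#' @return The tibble with an added `split` factor column
#'   (`train`/`val`/`test`).
#' @export
build_dataset <- function(rows, split = c(0.8, 0.1, 0.1), seed = 1,
                          mode = c("by_sample", "by_subject"),
                          policy = range_filter_policy()) {
  mode <- match.arg(mode)
  if (nrow(rows) == 0) abort("Empty input.", class = "bpci_input_error")
  if (abs(sum(split) - 1) > 1e-8) {
    abort("`split` fractions must sum to 1.", class = "bpci_parameter_error")
  }
  rows <- apply_range_filter(rows, policy)
  rng <- local_rng(seed)
  labels <- c("train", "val", "test")
  if (mode == "by_sample") {
    n <- nrow(rows)
    counts <- diff(c(0, floor(cumsum(split) * n)))
    counts[1] <- counts[1] + (n - sum(counts))
    perm <- rng$sample(seq_len(n), n)
    assign <- character(n)
    assign[perm] <- rep(labels, times = counts)
  } else {
    subj <- unique(rows$subject_id)
    m <- length(subj)
    counts <- diff(c(0, floor(cumsum(split) * m)))
    counts[1] <- counts[1] + (m - sum(counts))
    perm <- rng$sample(seq_len(m), m)
    subj_split <- setNames(character(m), subj)
    subj_split[perm] <- rep(labels, times = counts)
    assign <- subj_split[rows$subject_id]
  }
  rows$split <- factor(assign, levels = labels)
  rows
}
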