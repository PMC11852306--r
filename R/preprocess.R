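#' Configuration for stage-1 wavelet denoising
#'
#' Stage 1 decomposes each channel with a 10-level MODWT (db8), shrinks the
#' fine detail levels d1-d6 by empirical-Bayes posterior-median thresholding
#' with a Cauchy prior, zeroes the coarse details d7-d10 together with the
#' level-10 approximation (slow drift and DC), and inverts the transform.
#' A zero-phase IIR high-pass at 0.5 Hz then suppresses residual baseline.
#'
#' @param wavelet Mother wavelet for the denoising MODWT.
#' @param level Decomposition depth.
#' @param discard_details Detail levels zeroed before reconstruction.
#' @param discard_approx Zero the approximation as well?
#' @param shrink_details Detail levels passed through Cauchy shrinkage. Set
#'   `zero_d1 = TRUE` to zero d1 outright instead of shrinking it (an
#'   alternative reading of which levels count as "high-frequency").
#' @param zero_d1 See above.
#' @param highpass_fc High-pass cutoff in Hz.
#' @param steepness Transition-band steepness in `[0.5, 1]`; mapped to the
#'   IIR filter order (steeper = higher order).
#' @return A `bp_denoise_config` list.
#' @export
denoise_config <- function(wavelet = "db8", level = 10,
                           discard_details = 7:10, discard_approx = TRUE,
                           shrink_details = 1:6, zero_d1 = FALSE,
                           highpass_fc = 0.5, steepness = 0.5) {
  if (level < max(c(discard_details, shrink_details, 1))) {
    abort("`level` must be at least the largest referenced detail level.",
          class = "bpci_parameter_error")
  }
  if (steepness < 0.5 || steepness > 1) {
    abort("`steepness` must lie in [0.5, 1].", class = "bpci_parameter_error")
  }
  structure(list(wavelet = wavelet, level = level,
                 discard_details = discard_details,
                 discard_approx = discard_approx,
                 shrink_details = shrink_details, zero_d1 = zero_d1,
                 highpass_fc = highpass_fc, steepness = steepness),
            class = "bp_denoise_config")
}

#' Wavelet-denoise a signal
#'
#' Applies the stage-1 MODWT denoiser described in [denoise_config()].
#' Output has exactly the input length; because the approximation is
#' discarded, the result is free of DC and slow baseline drift.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz (kept for interface symmetry).
#' @param cfg A [denoise_config()].
#' @return Denoised numeric vector, same length as `x`.
#' @export
denoise_signal <- function(x, fs = 125, cfg = denoise_config()) {
  w <- modwt(x, wavelet = cfg$wavelet, level = cfg$level, boundary = "reflection")
  sigma1 <- mad(w$d[[1]])   # noise scale from the finest detail level
  for (j in seq_len(cfg$level)) {
    if (j %in% cfg$discard_details) {
      w$d[[j]] <- numeric(length(w$d[[j]]))
    } else if (j %in% cfg$shrink_details) {
      if (j == 1 && cfg$zero_d1) {
        w$d[[j]] <- numeric(length(w$d[[j]]))
      } else {
        w$d[[j]] <- ebayes_shrink(w$d[[j]], sigma1 / 2^((j - 1) / 2))
      }
    }
  }
  if (cfg$discard_approx) w$a <- numeric(length(w$a))
  imodwt(w)
}

#' Zero-phase IIR high-pass filter
#'
#' Butterworth high-pass applied forward and backward (`signal::filtfilt`),
#' so fiducial timing is not shifted. The filter order grows with
#' `steepness` (0.5 maps to order 4, 1.0 to order 8). A `one_pass = TRUE`
#' mode applies the filter once (causal), trading timing fidelity for the
#' conventional single-pass response.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate (Hz).
#' @param fc Cutoff frequency in Hz, `0 < fc < fs/2`.
#' @param steepness Transition-band steepness in `[0.5, 1]`.
#' @param one_pass Apply causally once instead of forward-backward.
#' @return Filtered vector, same length as `x`.
#' @export
highpass_filter <- function(x, fs = 125, fc = 0.5, steepness = 0.5,
                            one_pass = FALSE) {
  if (fc <= 0 || fc >= fs / 2) {
    abort("`fc` must satisfy 0 < fc < fs/2.", class = "bpci_parameter_error")
  }
  ord <- round(4 + 8 * (steepness - 0.5))  # 4..8
  bf <- signal::butter(ord, fc / (fs / 2), type = "high")
  # remove the mean first: DC sits deep in the stopband anyway and centering
  # keeps the forward-backward pass free of end transients on offset signals
  xc <- x - mean(x)
  if (one_pass) {
    as.numeric(signal::filter(bf, xc))
  } else {
    as.numeric(signal::filtfilt(bf, xc))
  }
}

# rolling adaptive threshold: 0.5 x 98th percentile of the rectified signal
# over 2-s blocks, held constant within each block
adaptive_threshold <- function(x_rect, fs, block_s = 2, frac = 0.5, p = 0.98) {
  n <- length(x_rect)
  block <- max(1L, round(block_s * fs))
  starts <- seq(1L, n, by = block)
  thr <- numeric(n)
  glob <- frac * quantile(x_rect, p, names = FALSE)
  for (s in starts) {
    i <- s:min(s + block - 1L, n)
    # blend block-local and global level so silent blocks don't fire
    thr[i] <- max(frac * quantile(x_rect[i], p, names = FALSE) * 0.5 + glob * 0.5,
                  glob * 0.25)
  }
  thr
}

# three-point local maxima above threshold with a refractory period
peak_search <- function(x, fs, threshold, refractory_s = 0.3) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > threshold[cand]]
  if (length(cand) == 0) return(integer(0))
  refr <- round(refractory_s * fs)
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= refr) {
      keep <- c(keep, i)
      last <- i
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i   # same beat, taller candidate wins
      last <- i
    }
  }
  keep
}

#' Detect ECG R-peaks
#'
#' Enhances the QRS complexes by a 4-level sym4 MODWT of the (denoised) ECG,
#' reconstructing only the level-2 and level-3 details — the band where an
#' ~80 ms QRS lives at 125 Hz — then runs a three-point peak search on the
#' rectified reconstruction with an adaptive threshold (half the rolling
#' 98th percentile over 2-s blocks) and a 0.3-s refractory period.
#'
#' @param ecg Denoised ECG vector.
#' @param fs Sampling rate (Hz).
#' @param refractory_s Minimum inter-peak spacing in seconds.
#' @return Integer vector of ascending 1-based sample indices (possibly empty).
#' @export
detect_rpeaks <- function(ecg, fs = 125, refractory_s = 0.3) {
  if (all(ecg == 0) || sd(ecg) == 0) return(integer(0))
  w <- modwt(ecg, wavelet = "sym4", level = 4, boundary = "reflection")
  recon <- modwt_reconstruct(w, keep_d = c(2, 3))
  r <- abs(recon)
  thr <- adaptive_threshold(r, fs)
  peak_search(r, fs, thr, refractory_s)
}

#' Detect PPG fiducial points
#'
#' Finds, for each pulse: the systolic peak, the onset trough (pulse foot),
#' the maximum-slope point on the rising limb (first-difference argmax
#' between foot and peak), and the diastolic inflection after the peak
#' (first zero-crossing of the second difference; when no dicrotic
#' inflection exists the point where the pulse has decayed to 34% of its
#' peak-to-foot amplitude is used and flagged `fallback`).
#'
#' @param ppg Denoised PPG vector.
#' @param fs Sampling rate (Hz).
#' @return A tibble with one row per detected pulse: `peak`, `foot`,
#'   `foot_next`, `max_slope`, `inflection` (1-based indices), `fallback`
#'   (logical). Troughs bracketing each pulse are required, so the last
#'   peak without a following trough is dropped.
#' @export
detect_ppg_fiducials <- function(ppg, fs = 125) {
  # detect on a lightly smoothed trace (0.15-s moving average): stage-1
  # denoising removes part of the cardiac fundamental, and the smoothing
  # keeps the residual ripple and dicrotic bumps from spawning false peaks
  k <- max(3L, round(0.15 * fs))
  xs <- as.numeric(stats::filter(ppg, rep(1 / k, k), sides = 2))
  xs[is.na(xs)] <- 0
  r <- xs - min(xs)
  thr <- rep(0.35 * quantile(r, 0.95, names = FALSE), length(r))
  peaks <- peak_search(r, fs, thr, refractory_s = 0.4)
  # refine each peak to the raw-signal maximum nearby (smoothing shifts peaks)
  halfw <- as.integer(round(0.15 * fs))
  peaks <- vapply(peaks, function(i) {
    lo <- max(1L, i - halfw); hi <- min(length(ppg), i + halfw)
    lo - 1L + which.max(ppg[lo:hi])
  }, numeric(1))
  peaks <- sort(unique(peaks))
  r <- ppg - min(ppg)
  # suppress secondary (dicrotic) peaks: while any interval is much shorter
  # than the median beat, drop the smaller peak of the offending pair
  while (length(peaks) >= 3) {
    iv <- diff(peaks)
    short <- which(iv < 0.55 * median(iv))
    if (length(short) == 0) break
    k <- short[1]
    drop_k <- if (r[peaks[k]] < r[peaks[k + 1]]) k else k + 1L
    peaks <- peaks[-drop_k]
  }
  if (length(peaks) < 1) {
    abort("Fewer than 2 troughs detectable in the PPG.",
          class = "bpci_insufficient_beats")
  }
  # troughs: minimum between consecutive peaks; foot of first pulse = minimum
  # in the window before the first peak
  troughs <- integer(length(peaks) + 1L)
  pre <- max(1L, peaks[1] - round(0.6 * fs))
  troughs[1] <- pre - 1L + which.min(ppg[pre:peaks[1]])
  if (length(peaks) > 1) {
    for (k in seq_len(length(peaks) - 1L)) {
      i <- peaks[k]:peaks[k + 1]
      troughs[k + 1L] <- i[which.min(ppg[i])]
    }
  }
  post <- min(length(ppg), peaks[length(peaks)] + round(1.2 * fs))
  troughs[length(troughs)] <- peaks[length(peaks)] - 1L +
    which.min(ppg[peaks[length(peaks)]:post])
  if (length(unique(troughs)) < 2) {
    abort("Fewer than 2 troughs detectable in the PPG.",
          class = "bpci_insufficient_beats")
  }

  d1 <- c(diff(ppg), 0)
  d2 <- c(0, diff(d1))
  rows <- purrr::map_dfr(seq_along(peaks), function(k) {
    f0 <- troughs[k]; pk <- peaks[k]; f1 <- troughs[k + 1L]
    if (f1 <= pk || pk <= f0) return(NULL)
    ms <- f0 - 1L + which.max(d1[f0:max(f0, pk - 1L)])
    # inflection: first upward zero-crossing of the 2nd difference after the
    # peak (concave-to-convex switch marks the dicrotic notch region)
    seg <- (pk + 1L):(f1 - 1L)
    infl <- NA_integer_; fb <- FALSE
    if (length(seg) > 2) {
      lead <- seg[-length(seg)]
      # scale the zero test by the pulse amplitude so float dust on exactly
      # piecewise-linear pulses does not masquerade as a curvature crossing
      eps <- 1e-6 * max(abs(ppg[pk] - ppg[f0]), .Machine$double.eps)
      zc <- lead[d2[lead] <= eps & d2[lead + 1L] > eps]
      if (length(zc) > 0) infl <- zc[1]
    }
    if (is.na(infl)) {
      fb <- TRUE
      amp <- ppg[pk] - ppg[f0]
      dec <- seg[which(ppg[seg] - ppg[f0] <= 0.34 * amp)]
      infl <- if (length(dec) > 0) dec[1] else pk + ((f1 - pk) %/% 2)
    }
    tibble::tibble(peak = pk, foot = f0, foot_next = f1,
                   max_slope = ms, inflection = infl, fallback = fb)
  })
  rows
}

#' Segment an analysis window into beat-anchored sub-segments
#'
#' Splits a 20-s window into per-beat segments of `round(1.4 * fs)` samples,
#' each anchored at a detected pulse foot in chronological order, capped at
#' 13 segments (excess beats dropped from the end). Windows yielding fewer
#' than 10 full segments are rejected with a reason rather than an error,
#' matching the pipeline's treat-as-untrusted behavior.
#'
#' @param window A 20-s `bp_record` window (see [extract_window()]).
#' @param fiducials Output of [detect_ppg_fiducials()] on the window's PPG.
#' @param min_segments,max_segments Acceptance band for the segment count.
#' @param segment_s Segment length in seconds (default 1.4).
#' @return A list with `accepted` (logical), `reason` (string or NA), and
#'   `segments`: a tibble of `start`, `length`, and the per-segment fiducial
#'   rows.
#' @export
segment_window <- function(window, fiducials, min_segments = 10,
                           max_segments = 13, segment_s = 1.4) {
  fs <- record_fs(window)
  seg_len <- round(segment_s * fs)
  n <- nrow(window)
  ok <- fiducials$foot + seg_len - 1L <= n
  segs <- fiducials[ok, , drop = FALSE]
  if (nrow(segs) > max_segments) segs <- segs[seq_len(max_segments), , drop = FALSE]
  if (nrow(segs) < min_segments) {
    return(list(accepted = FALSE, reason = "min_segments",
                segments = tibble::tibble()))
  }
  segs$start <- segs$foot
  segs$length <- seg_len
  list(accepted = TRUE, reason = NA_character_, segments = tibble::as_tibble(segs))
}

#' Run stage-1 preprocessing on all channels of a window
#'
#' Denoises PPG and ECG (MODWT + Cauchy shrinkage + 0.5 Hz zero-phase
#' high-pass). The ABP channel is left on its original mmHg scale — removing
#' its DC would destroy the pressure calibration — apart from NaN cleaning
#' performed at load time.
#'
#' @param window A `bp_record`.
#' @param cfg A [denoise_config()].
#' @return A `bp_record` with cleaned `ppg`/`ecg`, untouched `abp`.
#' @export
preprocess_window <- function(window, cfg = denoise_config()) {
  fs <- record_fs(window)
  ppg <- highpass_filter(denoise_signal(window$ppg, fs, cfg), fs,
                         fc = cfg$highpass_fc, steepness = cfg$steepness)
  ecg <- highpass_filter(denoise_signal(window$ecg, fs, cfg), fs,
                         fc = cfg$highpass_fc, steepness = cfg$steepness)
  out <- bp_record(ppg, ecg, window$abp, fs = fs, record_id = record_id(window),
                   meta = attr(window, "meta"), truth = record_truth(window))
  attr(out, "window") <- attr(window, "window")
  out
}
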