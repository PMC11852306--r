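#' Subject profile for the synthetic waveform generator
#'
#' Describes a synthetic subject: mean heart rate and beat-interval jitter,
#' baseline pressures, the linear pulse-transit-time coupling
#' `SBP = a - b * PTT` (stiffer arteries transmit the pulse wave faster, so
#' higher systolic pressure shortens the transit time), per-channel additive
#' noise, and a list of injectable artifacts.
#'
#' @param hr_bpm Mean heart rate in beats per minute (20-240).
#' @param hr_jitter SD of beat-interval noise in seconds.
#' @param sbp0,dbp0 Baseline systolic/diastolic pressure (mmHg).
#' @param sbp_sd Between-beat SD of systolic pressure (mmHg); beats wander
#'   around `sbp0` with this spread, and PTT follows through the coupling.
#' @param pp_sd SD of pulse-pressure noise (mmHg); per-beat DBP is
#'   `SBP - pulse pressure` with this mild noise so SBP > DBP always holds.
#' @param ptt0 Transit time at baseline SBP (s).
#' @param b Coupling slope in mmHg per second (> 0); `a` is derived as
#'   `sbp0 + b * ptt0`.
#' @param noise_sd Named numeric vector of white-noise SDs per channel
#'   (`ppg`, `ecg`, `abp`), in channel units.
#' @param artifacts List of artifact specs, each
#'   `list(kind = , ...params)` with kind one of `"white_noise"`,
#'   `"baseline_wander"`, `"motion_spike"`, `"dropped_beat"`,
#'   `"inverted_pulse"`.
#'
#' @return A `bp_subject_profile` list.
#' @export
subject_profile <- function(hr_bpm = 75, hr_jitter = 0.01,
                            sbp0 = 120, dbp0 = 80,
                            sbp_sd = 4, pp_sd = 1.5,
                            ptt0 = 0.25, b = 120,
                            noise_sd = c(ppg = 0, ecg = 0, abp = 0),
                            artifacts = list()) {
  if (hr_bpm <= 20 || hr_bpm >= 240) {
    abort("`hr_bpm` must lie in (20, 240).", class = "bpci_parameter_error")
  }
  if (b <= 0) abort("Coupling slope `b` must be > 0.", class = "bpci_parameter_error")
  ns <- c(ppg = 0, ecg = 0, abp = 0)
  ns[names(noise_sd)] <- noise_sd
  if (any(ns < 0)) abort("Noise SDs must be >= 0.", class = "bpci_parameter_error")
  structure(list(hr_bpm = hr_bpm, hr_jitter = hr_jitter,
                 sbp0 = sbp0, dbp0 = dbp0, sbp_sd = sbp_sd, pp_sd = pp_sd,
                 ptt0 = ptt0, a = sbp0 + b * ptt0, b = b,
                 noise_sd = ns, artifacts = artifacts),
            class = "bp_subject_profile")
}

# biphasic QRS template: dominant positive lobe at the R time, small negative
# rebound; total width ~80 ms so sym4 MODWT detail levels 2-3 capture it.
qrs_template <- function(t_rel, width = 0.08) {
  s <- width / 6
  exp(-(t_rel)^2 / (2 * s^2)) - 0.35 * exp(-(t_rel - 2.2 * s)^2 / (2 * (1.6 * s)^2))
}

# two-bump PPG pulse on u in [0,1): systolic wave + smaller diastolic (dicrotic)
# wave, zero at both feet so the pulse onset is a clean minimum.
ppg_pulse_shape <- function(u, dicrotic = 0.35) {
  main <- exp(-(u - 0.30)^2 / (2 * 0.095^2))
  dias <- dicrotic * exp(-(u - 0.62)^2 / (2 * 0.12^2))
  (main + dias) * sin(pi * pmin(pmax(u, 0), 1))^0.25
}

# ABP intra-beat shape: 0 at beat start/end, exactly 1 at the systolic peak
# (u_peak), so per-beat max/min of the channel equal the drawn SBP/DBP.
abp_pulse_shape <- function(u, u_peak = 0.3) {
  ifelse(u < u_peak,
         sin(pi * u / (2 * u_peak))^2,
         cos(pi * (u - u_peak) / (2 * (1 - u_peak)))^2)
}

#' Generate a synthetic three-channel record with known ground truth
#'
#' Builds a synchronized PPG/ECG/ABP record: the ECG is a train of biphasic
#' QRS templates at the R-peak times; each PPG pulse foot trails its R peak by
#' that beat's pulse transit time (PTT); the ABP channel oscillates beat-wise
#' between the beat's diastolic and systolic pressure. Per-beat SBP wanders
#' around the profile baseline and PTT follows `SBP = a - b * PTT` exactly,
#' so the ground truth carries a known PTT-SBP coupling for downstream
#' consistency checks. Requested artifacts are injected last. Identical
#' `(profile, seed)` pairs produce bit-identical records.
#'
#' @param profile A [subject_profile()].
#' @param duration_s Record length in seconds (must cover at least 2 beats).
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed; all randomness derives from it.
#' @param record_id Identifier string.
#'
#' @return A [bp_record()] whose `truth` attribute holds `r_peak_times`,
#'   `pulse_foot_times`, `pulse_peak_times`, per-beat `sbp`, `dbp`, `ptt`,
#'   and the coupling `(a, b)`.
#' @export
generate_record <- function(profile = subject_profile(), duration_s = 80,
                            fs = 125, seed = 1, record_id = NULL) {
  stopifnot(inherits(profile, "bp_subject_profile"))
  beat0 <- 60 / profile$hr_bpm
  if (duration_s < 2 * beat0) {
    abort("`duration_s` must cover at least 2 beats at the profile heart rate.",
          class = "bpci_parameter_error")
  }
  rng <- local_rng(seed)
  record_id <- record_id %||% sprintf("synth-%d", seed)

  # --- beat schedule -------------------------------------------------------
  n_beats <- ceiling(duration_s / beat0) + 3L
  intervals <- beat0 + rng$norm(n_beats, sd = profile$hr_jitter)
  intervals <- pmax(intervals, 0.3)
  r_times <- cumsum(c(0.4 * beat0, intervals[-1]))
  r_times <- r_times[r_times < duration_s - 0.05]
  n_beats <- length(r_times)

  # --- per-beat pressures and transit times --------------------------------
  # slow sinusoidal drift + white noise keeps SBP physiologic and smooth
  drift_phase <- rng$unif(1, 0, 2 * pi)
  sbp <- profile$sbp0 +
    profile$sbp_sd * 0.8 * sin(2 * pi * r_times / 25 + drift_phase) +
    rng$norm(n_beats, sd = profile$sbp_sd * 0.6)
  pp <- (profile$sbp0 - profile$dbp0) + rng$norm(n_beats, sd = profile$pp_sd)
  pp <- pmax(pp, 10)
  dbp <- sbp - pp
  ptt <- (profile$a - sbp) / profile$b
  if (any(ptt <= 0) || any(ptt >= intervals[seq_len(n_beats)])) {
    abort("Infeasible profile: PTT must stay positive and below the beat interval.",
          class = "bpci_parameter_error")
  }

  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs

  # --- ECG -----------------------------------------------------------------
  ecg <- numeric(n)
  for (k in seq_len(n_beats)) {
    i <- which(abs(t - r_times[k]) <= 0.12)
    ecg[i] <- ecg[i] + qrs_template(t[i] - r_times[k])
  }

  # --- PPG and ABP, beat by beat ------------------------------------------
  foot_times <- r_times + ptt
  beat_end <- c(foot_times[-1], foot_times[n_beats] +
                  intervals[min(n_beats + 1L, length(intervals))])
  ppg <- numeric(n)
  abp <- rep(dbp[1], n)
  peak_times <- numeric(n_beats)
  for (k in seq_len(n_beats)) {
    dur <- beat_end[k] - foot_times[k]
    i <- which(t >= foot_times[k] & t < beat_end[k])
    if (length(i) == 0) next
    u <- (t[i] - foot_times[k]) / dur
    ppg[i] <- ppg[i] + ppg_pulse_shape(u)
    abp[i] <- dbp[k] + (sbp[k] - dbp[k]) * abp_pulse_shape(u)
    peak_times[k] <- foot_times[k] + 0.30 * dur
  }
  # leading samples before first foot: hold a flat diastolic run-in
  ppg <- ppg + 1.0  # optical baseline so the raw channel is strictly positive

  # --- measurement noise ---------------------------------------------------
  ns <- profile$noise_sd
  if (ns[["ppg"]] > 0) ppg <- ppg + rng$norm(n, sd = ns[["ppg"]])
  if (ns[["ecg"]] > 0) ecg <- ecg + rng$norm(n, sd = ns[["ecg"]])
  if (ns[["abp"]] > 0) abp <- abp + rng$norm(n, sd = ns[["abp"]])

  truth <- list(r_peak_times = r_times, pulse_foot_times = foot_times,
                pulse_peak_times = peak_times,
                sbp = sbp, dbp = dbp, ptt = ptt,
                a = profile$a, b = profile$b)
  rec <- bp_record(ppg, ecg, abp, fs = fs, record_id = record_id,
                   meta = list(profile = profile, seed = seed), truth = truth)
  inject_artifacts(rec, profile$artifacts, rng)
}

# Deterministic local RNG: isolates generator randomness from the global
# stream and guarantees same (profile, seed) -> same record.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else rm(".Random.seed", envir = globalenv())
    s
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- f()
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    out
  }
  list(
    norm = function(n, mean = 0, sd = 1) with_state(function() rnorm(n, mean, sd)),
    unif = function(n, min = 0, max = 1) with_state(function() runif(n, min, max)),
    sample = function(x, size) with_state(function() sample(x, size))
  )
}

# Apply artifact specs in order; an empty list is the identity.
inject_artifacts <- function(record, artifacts, rng) {
  if (length(artifacts) == 0) return(record)
  fs <- record_fs(record)
  n <- nrow(record)
  truth <- record_truth(record)
  ppg <- record$ppg; ecg <- record$ecg; abp <- record$abp
  injected <- list()
  for (a in artifacts) {
    kind <- a$kind
    if (kind == "white_noise") {
      sd <- a$sd %||% 0.1
      ch <- a$channel %||% "ppg"
      z <- rng$norm(n, sd = sd)
      if (ch == "ppg") ppg <- ppg + z else if (ch == "ecg") ecg <- ecg + z else abp <- abp + z
    } else if (kind == "baseline_wander") {
      amp <- a$amp %||% 0.5; f <- a$freq %||% 0.25
      t <- record$time
      w <- amp * sin(2 * pi * f * t + (a$phase %||% 0))
      ppg <- ppg + w
      ecg <- ecg + (a$ecg_frac %||% 0.5) * w
    } else if (kind == "motion_spike") {
      ats <- a$at_s %||% (n / fs / 2)   # one or several spike centers (s)
      width <- a$width_s %||% 0.4
      amp <- a$amp %||% 3
      for (at in ats) {
        i <- which(abs(record$time - at) <= width / 2)
        bump <- amp * exp(-((record$time[i] - at) / (width / 6))^2 / 2)
        ppg[i] <- ppg[i] + bump
        ecg[i] <- ecg[i] + bump
      }
    } else if (kind == "dropped_beat") {
      # flatten PPG and ECG around selected beats, creating a long inter-beat gap
      which_beats <- a$beats %||% {
        nb <- length(truth$r_peak_times)
        max(2L, round(nb / 2))
      }
      for (k in which_beats) {
        if (k > length(truth$r_peak_times)) next
        t0 <- truth$r_peak_times[k] - 0.15
        t1 <- (if (k < length(truth$r_peak_times)) truth$r_peak_times[k + 1] else t0 + 1) - 0.15
        i <- which(record$time >= t0 & record$time < t1)
        if (length(i) == 0) next
        ppg[i] <- mean(ppg[i])
        ecg[i] <- 0
      }
    } else if (kind == "inverted_pulse") {
      # sensor-polarity artifact: flips the optical pulse and the co-located
      # ECG stretch around their local baselines
      which_beats <- a$beats %||% max(2L, round(length(truth$pulse_foot_times) / 2))
      feet <- truth$pulse_foot_times
      for (k in which_beats) {
        if (k >= length(feet)) next
        i <- which(record$time >= feet[k] & record$time < feet[k + 1])
        if (length(i) == 0) next
        ppg[i] <- 2 * mean(ppg[i]) - ppg[i]
        ecg[i] <- 2 * mean(ecg[i]) - ecg[i]
      }
    } else {
      abort(sprintf("Unknown artifact kind '%s'.", kind),
            class = "bpci_parameter_error")
    }
    injected <- c(injected, list(a))
  }
  meta <- attr(record, "meta"); meta$artifacts <- injected
  bp_record(ppg, ecg, abp, fs = fs, record_id = record_id(record),
            meta = meta, truth = truth)
}

#' Generate a synthetic labeled feature table
#'
#' Produces an `n_samples x n_features` design in which only the first
#' `n_informative` columns carry signal about the target; remaining columns
#' are independent noise. Used to exercise feature ranking, weighted feature
#' decisions and the regression engines with a known answer.
#'
#' @param n_samples,n_features,n_informative Positive counts with
#'   `n_informative <= n_features` (0 informative gives a pure-noise target).
#' @param noise_sd SD of additive Gaussian target noise.
#' @param link `"linear"` (y = X beta) or `"nonlinear"` (smooth interactions).
#' @param seed Integer seed.
#' @param coef Optional coefficient vector of length `n_informative` for the
#'   linear link; default `3, 2, 1, ...` pattern.
#'
#' @return A tibble with columns `x1..xp`, `y`, and attributes
#'   `informative` (indices) and `coef`.
#' @export
generate_feature_table <- function(n_samples, n_features, n_informative,
                                   noise_sd = 0.5, link = c("linear", "nonlinear"),
                                   seed = 1, coef = NULL) {
  link <- match.arg(link)
  if (n_samples <= 0 || n_features <= 0 || n_informative < 0) {
    abort("Counts must be positive (n_informative may be 0).",
          class = "bpci_parameter_error")
  }
  if (n_informative > n_features) {
    abort("`n_informative` must not exceed `n_features`.",
          class = "bpci_parameter_error")
  }
  rng <- local_rng(seed)
  X <- matrix(rng$norm(n_samples * n_features), n_samples, n_features)
  if (n_informative > 0) {
    coef <- coef %||% rev(seq_len(n_informative))
    Xi <- X[, seq_len(n_informative), drop = FALSE]
    y0 <- if (link == "linear") {
      drop(Xi %*% coef)
    } else {
      rowSums(sin(Xi)) + if (n_informative >= 2) Xi[, 1] * Xi[, 2] else 0
    }
  } else {
    coef <- numeric(0)
    y0 <- numeric(n_samples)
  }
  y <- y0 + if (noise_sd > 0) rng$norm(n_samples, sd = noise_sd) else 0
  out <- tibble::as_tibble(as.data.frame(X), .name_repair = "minimal")
  names(out) <- paste0("x", seq_len(n_features))
  out$y <- y
  attr(out, "informative") <- seq_len(n_informative)
  attr(out, "coef") <- coef
  out
}
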