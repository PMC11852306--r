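test_that("waveform parameters follow the pulse-normalization identities", {
  fs <- 125
  # symmetric triangle 0 -> 1 -> 0 over one second
  tri <- c(seq(0, 1, length.out = 63), seq(1, 0, length.out = 63)[-1])
  wp <- waveform_params(tri, 1, length(tri), fs)
  expect_equal(wp$ps, 1)
  expect_equal(wp$pd, 0)
  expect_equal(wp$pm, 0.5, tolerance = 0.01)   # trapezoid area / duration
  expect_equal(wp$ppgc, 0.5, tolerance = 0.01)
  expect_equal(wp$ppgt, 1, tolerance = 0.01)
  # the shift forces min(ppgp) = 0 for arbitrary pulses
  set.seed(5)
  pulse <- synth_pulse() + 3
  wp2 <- waveform_params(pulse, 1, length(pulse), fs)
  expect_equal(min(wp2$ppgp), 0)
  expect_equal(wp2$ppgt, 1, tolerance = 0.01)
  # exact duration arithmetic
  wp3 <- waveform_params(c(0, rep(1, 124), 0.5, rep(2, 125)), 1, 126, fs)
  expect_equal(wp3$ppgt, 1)
  expect_error(waveform_params(rep(2, 100), 1, 100, fs),
               class = "bpci_degenerate_pulse")
})

test_that("every accepted segment yields the full 47-feature vector", {
  cw <- clean_window()
  fid <- detect_ppg_fiducials(cw$pre$ppg, 125)
  seg <- segment_window(cw$pre, fid)
  ft <- extract_features(cw$pre, seg)
  expect_true(all(feature_names() %in% names(ft)))
  expect_length(feature_names(), 47)
  expect_gt(nrow(ft), 0)
  core <- as.matrix(ft[, setdiff(feature_names(), "MCORR")])
  expect_true(all(is.finite(core)))
  # HR 60, no jitter worth mentioning: HR feature within 0.5 bpm everywhere
  expect_true(all(abs(ft$HR - 60) < 0.5 + 2))  # jitter default is small, not 0
})

test_that("HR and PTT features track the generator's ground truth", {
  rec <- generate_record(subject_profile(hr_bpm = 60, hr_jitter = 0,
                                         noise_sd = c(ppg = 0.005, ecg = 0.005,
                                                      abp = 0.2)),
                         duration_s = 20, seed = 77)
  pre <- preprocess_window(rec)
  fid <- detect_ppg_fiducials(pre$ppg, 125)
  ft <- extract_features(pre, segment_window(pre, fid))
  expect_true(all(abs(ft$HR - 60) < 0.5))
  # PAT3 (R peak to pulse foot) against true per-beat transit times
  tr <- attr(rec, "truth")
  truth_ptt <- vapply(ft$t_foot, function(t0)
    tr$ptt[which.min(abs(tr$pulse_foot_times - t0))], numeric(1))
  expect_gte(cor(ft$PAT3, truth_ptt), 0.95)
})

test_that("reference pressures recover the constructed ABP extrema", {
  fs <- 125
  # square-ish train oscillating 80 <-> 120
  beat <- c(rep(120, 40), rep(80, 60))
  abp <- rep(beat, 5)
  ref <- reference_bp(abp, fs)
  expect_equal(unname(ref["sbp"]), 120, tolerance = 0.5)
  expect_equal(unname(ref["dbp"]), 80, tolerance = 0.5)
  expect_error(reference_bp(rep(100, 500), fs), class = "bpci_degenerate_pulse")
  # synthetic record: per-segment reference within 1 mmHg of the truth means
  cw <- clean_window()
  fid <- detect_ppg_fiducials(cw$pre$ppg, 125)
  seg <- segment_window(cw$pre, fid)
  ft <- extract_features(cw$pre, seg)
  tr <- cw$truth
  # match truth beats by their systolic-peak times (what the per-beat ABP
  # maxima inside a 1.4-s segment actually see)
  dur <- diff(c(tr$pulse_foot_times,
                tr$pulse_foot_times[length(tr$pulse_foot_times)] + 1))
  t_pk <- tr$pulse_foot_times + 0.3 * dur
  for (k in seq_len(min(8, nrow(ft)))) {
    t0 <- ft$t_foot[k]
    beats <- which(t_pk >= t0 & t_pk < t0 + 1.4)
    expect_lt(abs(ft$sbp[k] - mean(tr$sbp[beats])), 1)
  }
})

test_that("timing and normalized-amplitude features are translation invariant", {
  cw <- clean_window()
  fid <- detect_ppg_fiducials(cw$pre$ppg, 125)
  seg <- segment_window(cw$pre, fid)
  ft0 <- extract_features(cw$pre, seg)
  shifted <- cw$pre
  shifted$ppg <- shifted$ppg + 5
  ft1 <- extract_features(shifted, segment_window(shifted,
                                                  detect_ppg_fiducials(shifted$ppg, 125)))
  n <- min(nrow(ft0), nrow(ft1))
  for (col in c("ST", "DT", "CT", "IBI", "HR", "PAT1", "PAT2", "PAT3",
                "PIR", "PPGk", "AUI", "LASI")) {
    expect_equal(ft1[[col]][1:n], ft0[[col]][1:n], tolerance = 1e-8,
                 label = col)
  }
})

test_that("dataset splitting is deterministic, proportional, and subject-pure", {
  rows <- tibble::tibble(sbp = runif(100, 90, 180), dbp = runif(100, 50, 100),
                         subject_id = rep(sprintf("s%02d", 1:20), each = 5))
  ds <- build_dataset(rows, seed = 3)
  expect_equal(as.vector(table(ds$split)), c(80, 10, 10))
  ds2 <- build_dataset(rows, seed = 3)
  expect_identical(ds$split, ds2$split)
  bs <- build_dataset(rows, seed = 3, mode = "by_subject")
  tab <- table(bs$subject_id, bs$split)
  expect_true(all(rowSums(tab > 0) == 1))   # each subject in exactly one split
  expect_error(build_dataset(rows[0, ]), class = "bpci_input_error")
  expect_error(build_dataset(rows, split = c(0.5, 0.2, 0.2)),
               class = "bpci_parameter_error")
})

test_that("pooled extraction shows the inverse PTT-SBP relation", {
  sc <- small_cohort_features()
  ft <- sc$features
  expect_gt(nrow(ft), 50)
  expect_lt(cor(ft$ptt, ft$sbp), -0.7)
  expect_false(anyNA(ft[, setdiff(feature_names(), "MCORR")]))
})
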