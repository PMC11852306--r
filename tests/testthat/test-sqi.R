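test_that("the three plausibility rules fire on the documented patterns", {
  fs <- 125
  # constant 0.5-s intervals over 20 s (HR 120): all pass
  pk <- seq(1, by = round(0.5 * fs), length.out = 40)
  expect_equal(unlist(check_rules(pk, fs, 20)[1, 1:3]),
               c(rule1 = TRUE, rule2 = TRUE, rule3 = TRUE))
  # 2.0-s intervals (HR 30): rule 1 fails
  slow <- seq(1, by = 2 * fs, length.out = 10)
  expect_false(check_rules(slow, fs, 20)$rule1)
  # a 3.5-s gap fails rule 2
  gap <- cumsum(c(1, rep(0.8 * fs, 10), 3.5 * fs))
  expect_false(check_rules(gap, fs, 20)$rule2)
  # interval ratio 2.5 fails rule 3
  rat <- cumsum(c(1, 0.5 * fs, 1.25 * fs))
  expect_false(check_rules(rat, fs, 20)$rule3)
  # fewer than 2 peaks: everything fails with a reason
  r <- check_rules(c(100), fs, 20)
  expect_false(any(unlist(r[1, 1:3])))
  expect_equal(r$reason, "insufficient_peaks")
})

test_that("template correlation matches a brute-force per-beat oracle", {
  fs <- 125
  pulse <- synth_pulse()[1:100]
  gap <- numeric(50)   # isolate beats so template windows see only one pulse
  mk <- function(scales) {
    x <- numeric(0)
    for (s in scales) x <- c(x, s * pulse, gap)
    x
  }
  peaks <- function(n) round(seq(0, n - 1) * 150 + which.max(pulse))
  # identical pulses: exactly 1
  x10 <- mk(rep(1, 10))
  expect_equal(template_correlation(x10, peaks(10), fs), 1, tolerance = 1e-9)
  # amplitude scaling leaves Pearson correlation untouched
  xs <- mk(c(rep(1, 9), 3))
  expect_equal(template_correlation(xs, peaks(10), fs), 1, tolerance = 1e-9)
  # one inverted pulse drags the mean down; verify against a direct oracle
  xi <- mk(c(rep(1, 9), -1))
  got <- template_correlation(xi, peaks(10), fs)
  width <- round(median(diff(peaks(10))))
  half <- width %/% 2
  beats <- sapply(peaks(10), function(p) {
    lo <- p - half; hi <- p + (width - half) - 1
    if (lo >= 1 && hi <= length(xi)) xi[lo:hi] else NULL
  })
  beats <- beats[!vapply(beats, is.null, logical(1))]
  tmpl <- Reduce(`+`, beats) / length(beats)
  oracle <- mean(vapply(beats, function(b) cor(b, tmpl), numeric(1)))
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_lt(got, 0.85)
  expect_error(template_correlation(pulse, 50L, fs), class = "bpci_input_error")
})

test_that("clean windows are trusted; artifact windows are not", {
  cw <- clean_window()
  res <- classify_segment(cw$pre)
  expect_equal(res$label, "trusted")
  expect_true(res$rule1 && res$rule2 && res$rule3)
  expect_gte(res$mean_template_corr, 0.8)
  # dropped beats open a long gap: rule 2 fails, template step skipped
  drop_prof <- subject_profile(
    noise_sd = c(ppg = 0.01, ecg = 0.01, abp = 0.3),
    artifacts = list(list(kind = "dropped_beat", beats = 9:11)))
  rec_d <- generate_record(drop_prof, duration_s = 20, seed = 42)
  res_d <- classify_segment(preprocess_window(rec_d))
  expect_equal(res_d$label, "untrusted")
  expect_false(res_d$rule2)
  expect_true(is.na(res_d$mean_template_corr))
  # polarity-inverted beats pass the rate rules but wreck template agreement
  inv_prof <- subject_profile(
    hr_bpm = 72, noise_sd = c(ppg = 0.02, ecg = 0.02, abp = 0.3),
    artifacts = list(list(kind = "inverted_pulse", beats = seq(3, 21, by = 2))))
  rec_i <- generate_record(inv_prof, duration_s = 20, seed = 7001)
  res_i <- classify_segment(preprocess_window(rec_i))
  expect_equal(res_i$label, "untrusted")
  expect_lt(res_i$mean_template_corr, 0.8)
  # determinism
  expect_identical(classify_segment(cw$pre), res)
})

test_that("raising the correlation threshold never gains trust", {
  cw <- clean_window()
  labels <- vapply(c(0.5, 0.8, 0.95, 0.999),
                   function(th) classify_segment(cw$pre, corr_threshold = th)$label,
                   character(1))
  trusted <- labels == "trusted"
  expect_true(all(diff(as.integer(trusted)) <= 0))
})

test_that("artifact screening separates clean from corrupted windows", {
  # seeded cohort, 30% artifact windows; sensitivity and specificity for the
  # injected labels both >= 0.9 (regression guard for the rule+template combo)
  fs <- 125
  n_win <- 200
  set.seed(314)
  is_bad <- rep(c(TRUE, FALSE), c(0.3, 0.7) * n_win)[sample(n_win)]
  truth <- character(n_win)
  got_bad <- logical(n_win)
  for (i in seq_len(n_win)) {
    arts <- if (is_bad[i]) {
      kind <- c("dropped_beat", "inverted_pulse", "motion_spike")[1 + (i %% 3)]
      switch(kind,
        dropped_beat = list(list(kind = "dropped_beat", beats = 8:10)),
        inverted_pulse = list(list(kind = "inverted_pulse",
                                   beats = seq(3, 21, by = 2))),
        motion_spike = list(list(kind = "motion_spike",
                                 at_s = c(4, 7, 10, 13, 16), amp = 5,
                                 width_s = 0.15)))
    } else {
      list()
    }
    prof <- subject_profile(hr_bpm = 58 + (i %% 35),
                            noise_sd = c(ppg = 0.02, ecg = 0.02, abp = 0.3),
                            artifacts = arts)
    rec <- generate_record(prof, duration_s = 20, fs = fs, seed = 9000 + i)
    res <- classify_segment(preprocess_window(rec))
    got_bad[i] <- res$label == "untrusted"
  }
  sens <- sum(got_bad & is_bad) / sum(is_bad)
  spec <- sum(!got_bad & !is_bad) / sum(!is_bad)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.9)
})
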