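test_that("Type A uncertainty follows the hand-computed anchors", {
  ta <- type_a(c(5, 5, 5, 5))
  expect_equal(c(ta$mean, ta$sd, ta$u), c(5, 0, 0))
  ta2 <- type_a(1:5)
  expect_equal(ta2$mean, 3)
  expect_equal(ta2$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(ta2$u, sqrt(2.5) / sqrt(5), tolerance = 1e-12)
  # homogeneity under scaling
  ta3 <- type_a(-3 * (1:5))
  expect_equal(ta3$sd, 3 * ta2$sd)
  expect_equal(ta3$u, 3 * ta2$u)
  expect_error(type_a(1), class = "bpci_input_error")
})

test_that("combined and expanded uncertainty do root-sum-square arithmetic", {
  expect_equal(combined_uncertainty(0, 0, 0), 0)
  expect_equal(combined_uncertainty(3, 4, 0), 5)
  expect_equal(combined_uncertainty(2, 2, 1), 3)
  expect_error(combined_uncertainty(-1), class = "bpci_parameter_error")
  iv <- expanded_interval(120, 2, K = 2)
  expect_equal(c(iv$lower, iv$upper), c(116, 124))
  expect_equal(iv$level, 0.95)
  iv0 <- expanded_interval(100, 0)
  expect_equal(iv0$width, 0)
  # with the 1-mmHg reference floor and K = 2, width never drops below 4
  for (ua in c(0, 0.5, 2, 7)) {
    u_c <- combined_uncertainty(ua, 0, 1)
    expect_gte(expanded_interval(100, u_c)$width, 4)
  }
})

test_that("the parametric bootstrap interval matches its sampling theory", {
  # degenerate spread: interval collapses to the mean
  b0 <- bootstrap_ci(rep(7, 10), B = 200, seed = 1)
  expect_equal(c(b0$lower, b0$center, b0$upper), c(7, 7, 7))
  # column means are exactly Gaussian here; width ~ 2 z_{0.975} sigma / sqrt(n)
  set.seed(2)
  est <- rnorm(10)
  est <- (est - mean(est)) / sqrt(mean((est - mean(est))^2))  # MLE sd = 1
  b <- bootstrap_ci(est, B = 4000, alpha = 0.025, seed = 3)
  want <- 2 * qnorm(0.975) / sqrt(10)
  expect_lt(abs(b$width - want) / want, 0.1)
  # reproducibility
  expect_identical(bootstrap_ci(est, B = 500, seed = 9),
                   bootstrap_ci(est, B = 500, seed = 9))
  expect_error(bootstrap_ci(c(1), B = 200), class = "bpci_input_error")
})

test_that("the central-limit interval has its closed form", {
  m <- montecarlo_ci(c(1, 2, 3, 4, 5), level = 0.95)
  half <- qnorm(0.975) * sqrt(2.5) / sqrt(5)
  expect_equal(m$center, 3)
  expect_equal(m$lower, 3 - half, tolerance = 1e-9)
  expect_equal(m$upper, 3 + half, tolerance = 1e-9)
  expect_equal(round(c(m$lower, m$upper), 3), c(1.614, 4.386))
  expect_equal(montecarlo_ci(rep(2, 5))$width, 0)
  # replicating the sample k-fold shrinks the width like 1/sqrt(k)
  # (up to the exact finite-sample sd correction sqrt(k(n-1)/(kn-1)))
  x <- c(1, 2, 3, 4, 5)
  w1 <- montecarlo_ci(x)$width
  w4 <- montecarlo_ci(rep(x, 4))$width
  expect_equal(w4 / w1, sqrt(4 * (5 - 1) / (4 * 5 - 1)) / 2, tolerance = 1e-9)
})

test_that("bootstrap width converges to the central-limit width", {
  set.seed(4)
  est <- rnorm(12, mean = 120, sd = 2)
  b <- bootstrap_ci(est, B = 10000, seed = 5)
  m <- montecarlo_ci(est)
  # both target the sampling distribution of the mean; the bootstrap uses
  # the MLE sd, so rescale by sqrt(n/(n-1)) before comparing
  n <- length(est)
  expect_lt(abs(b$width * sqrt(n / (n - 1)) - m$width) / m$width, 0.05)
})

test_that("per-subject tables emit one interval per method with sane geometry", {
  set.seed(8)
  d <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:6), each = 10),
    estimate = rep(seq(100, 150, length.out = 6), each = 10) + rnorm(60, sd = 2),
    sd = runif(60, 2, 4),
    reference = rep(seq(100, 150, length.out = 6), each = 10))
  cis <- subject_cis(d, target = "sbp", B = 400, seed = 2)
  expect_equal(nrow(cis), 6 * 4)
  expect_true(all(cis$lower <= cis$center & cis$center <= cis$upper))
  # expanded-uncertainty width floor with u_gamma = 1, K = 2
  expect_true(all(cis$width[cis$method == "uncer"] >= 4))
  # central-limit intervals are narrower than the expanded uncertainty
  for (s in unique(cis$subject_id)) {
    expect_lt(cis$width[cis$method == "monte" & cis$subject_id == s],
              cis$width[cis$method == "uncer" & cis$subject_id == s])
  }
  # single-estimate subjects are skipped with a warning
  d1 <- dplyr::bind_rows(d, tibble::tibble(subject_id = "s99", estimate = 120,
                                           sd = 3, reference = 120))
  expect_warning(cis1 <- subject_cis(d1, target = "sbp", B = 400, seed = 2),
                 "single estimate")
  expect_false("s99" %in% cis1$subject_id)
  sm <- ci_summary(cis)
  expect_equal(nrow(sm), 4)
  expect_true(all(sm$n_subjects == 6))
})
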