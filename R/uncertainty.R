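#' Type A standard uncertainty of repeated estimates
#'
#' Sample mean, sample SD (n-1 denominator), and the standard uncertainty
#' of the mean `u = sd / sqrt(n)`.
#'
#' @param estimates Numeric vector, length >= 2.
#' @return Named list `mean`, `sd`, `u`, `n`.
#' @export
type_a <- function(estimates) {
  n <- length(estimates)
  if (n < 2) abort("Need at least 2 estimates.", class = "bpci_input_error")
  s <- sd(estimates)
  list(mean = mean(estimates), sd = s, u = s / sqrt(n), n = n)
}

#' Combined standard uncertainty (root sum of squares)
#'
#' `u_c = sqrt(u_alpha^2 + u_beta^2 + u_gamma^2)`: the random (Type A)
#' component, the systematic bias component, and the maximum allowable
#' error of the reference instrument (about 1 mmHg for a mercury
#' sphygmomanometer, the default).
#'
#' @param u_alpha,u_beta,u_gamma Nonnegative components (mmHg).
#' @return Combined uncertainty `u_c`.
#' @export
combined_uncertainty <- function(u_alpha, u_beta = 0, u_gamma = 1) {
  if (any(c(u_alpha, u_beta, u_gamma) < 0)) {
    abort("Uncertainty components must be >= 0.", class = "bpci_parameter_error")
  }
  sqrt(u_alpha^2 + u_beta^2 + u_gamma^2)
}

new_interval <- function(center, lower, upper, level, method, n) {
  tibble::tibble(center = center, lower = lower, upper = upper,
                 width = upper - lower, level = level, method = method,
                 n_estimates = n)
}

#' Expanded-uncertainty confidence interval
#'
#' `U = K * u_c`; the interval is `x_bar +/- U`. With coverage factor
#' `K = 2` the nominal level is reported as 0.95 (Gaussian coverage of a
#' two-sigma band); other K report `2 * pnorm(K) - 1`.
#'
#' @param x_bar Center (mmHg).
#' @param u_c Combined standard uncertainty (>= 0).
#' @param K Coverage factor (> 0).
#' @param n Number of underlying estimates (metadata).
#' @return One-row interval tibble (method `"uncer"`).
#' @export
expanded_interval <- function(x_bar, u_c, K = 2, n = NA_integer_) {
  stopifnot(u_c >= 0, K > 0)
  U <- K * u_c
  level <- if (isTRUE(all.equal(K, 2))) 0.95 else 2 * pnorm(K) - 1
  new_interval(x_bar, x_bar - U, x_bar + U, level, "uncer", n)
}

#' Parametric bootstrap percentile interval for a subject mean
#'
#' Fits a Gaussian by maximum likelihood to the subject's estimates
#' (`mu_hat`, `sigma_hat` with the n denominator), draws an `n x B` matrix
#' of `mu_hat + sigma_hat * z` replicates, averages each column, sorts the
#' B column means, and takes the `alpha` and `1 - alpha` percentiles —
#' nominal coverage `1 - 2 alpha`.
#'
#' @param estimates Numeric vector, length >= 2.
#' @param B Number of bootstrap replications (>= 100).
#' @param alpha Tail fraction in (0, 0.5); default 0.025 for a 95% interval.
#' @param seed Integer seed.
#' @return One-row interval tibble (method `"boot"`).
#' @export
bootstrap_ci <- function(estimates, B = 1000, alpha = 0.025, seed = 1) {
  n <- length(estimates)
  if (n < 2) abort("Need at least 2 estimates.", class = "bpci_input_error")
  stopifnot(B >= 100, alpha > 0, alpha < 0.5)
  mu <- mean(estimates)
  sig <- sqrt(mean((estimates - mu)^2))   # MLE, n denominator
  rng <- local_rng(seed)
  if (sig == 0) {
    return(new_interval(mu, mu, mu, 1 - 2 * alpha, "boot", n))
  }
  Z <- matrix(rng$norm(n * B), n, B)
  col_means <- mu + sig * colMeans(Z)
  qs <- quantile(sort(col_means), c(alpha, 1 - alpha), names = FALSE, type = 7)
  new_interval(mu, qs[1], qs[2], 1 - 2 * alpha, "boot", n)
}

#' Central-limit Monte Carlo confidence interval
#'
#' `mu_hat +/- z_{(1+level)/2} * s / sqrt(n)` with `s` the sample SD — the
#' large-sample Gaussian interval for the subject mean.
#'
#' @param estimates Numeric vector, length >= 2.
#' @param level Nominal level (default 0.95).
#' @return One-row interval tibble (method `"monte"`).
#' @export
montecarlo_ci <- function(estimates, level = 0.95) {
  n <- length(estimates)
  if (n < 2) abort("Need at least 2 estimates.", class = "bpci_input_error")
  ta <- type_a(estimates)
  z <- qnorm((1 + level) / 2)
  half <- z * ta$u
  new_interval(ta$mean, ta$mean - half, ta$mean + half, level, "monte", n)
}

#' Per-subject confidence intervals by four methods
#'
#' For each subject (about 10 segment-level BP estimates per 20-s window),
#' emits intervals from: the GPR posterior (`mean +/- z * mean predictive
#' SD`), the parametric bootstrap, the expanded uncertainty (Type A
#' `u_alpha = sd/sqrt(n)`; `u_beta` = |mean bias| against the reference when
#' one is supplied, else 0; `u_gamma` defaults to 1 mmHg), and the
#' central-limit interval. Subjects with a single estimate are flagged and
#' skipped. Interval widths outside the clinically sensible band
#' (7-10 mmHg for SBP, 3-6 mmHg for DBP) trigger an informational message,
#' never an error.
#'
#' @param data Tibble with columns `subject_id`, `estimate`, optional `sd`
#'   (GPR predictive SD) and `reference`.
#' @param target `"sbp"` or `"dbp"` (used only for width sanity messages).
#' @param methods Subset of `c("gpr", "boot", "uncer", "monte")`.
#' @param level Nominal level.
#' @param B,seed Bootstrap replications and seed.
#' @param u_gamma Maximum allowable reference error (mmHg).
#' @param uncer_sd Use `u_alpha = sd` instead of `sd/sqrt(n)` (a broader
#'   reading of the Type A component).
#' @param warn_widths Emit the width sanity messages?
#' @return Tibble of one row per subject x method.
#' @export
subject_cis <- function(data, target = c("sbp", "dbp"),
                        methods = c("gpr", "boot", "uncer", "monte"),
                        level = 0.95, B = 1000, seed = 1, u_gamma = 1,
                        uncer_sd = FALSE, warn_widths = FALSE) {
  target <- match.arg(target)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(all(c("subject_id", "estimate") %in% names(data)))
  z <- qnorm((1 + level) / 2)
  band <- if (target == "sbp") c(7, 10) else c(3, 6)
  subjects <- split(tibble::as_tibble(data), data$subject_id)
  out <- purrr::imap_dfr(subjects, function(d, sid) {
    est <- d$estimate
    n <- length(est)
    if (n < 2) {
      warn(sprintf("Subject '%s' has a single estimate; skipped.", sid))
      return(NULL)
    }
    ta <- type_a(est)
    rows <- list()
    if ("gpr" %in% methods && "sd" %in% names(d)) {
      half <- z * mean(d$sd)
      rows$gpr <- new_interval(ta$mean, ta$mean - half, ta$mean + half,
                               level, "gpr", n)
    }
    if ("boot" %in% methods) {
      rows$boot <- bootstrap_ci(est, B = B, alpha = (1 - level) / 2,
                                seed = seed + utils::head(which(names(subjects) == sid), 1))
    }
    if ("uncer" %in% methods) {
      u_alpha <- if (uncer_sd) ta$sd else ta$u
      u_beta <- if ("reference" %in% names(d)) abs(mean(est - d$reference)) else 0
      rows$uncer <- expanded_interval(ta$mean,
                                      combined_uncertainty(u_alpha, u_beta, u_gamma),
                                      K = 2, n = n)
    }
    if ("monte" %in% methods) {
      rows$monte <- montecarlo_ci(est, level = level)
    }
    res <- dplyr::bind_rows(rows)
    res$subject_id <- sid
    res$target <- target
    res
  })
  if (warn_widths && nrow(out) > 0) {
    bad <- out$width < band[1] | out$width > band[2]
    if (any(bad)) {
      inform(sprintf(
        "%d of %d %s interval(s) fall outside the clinically sensible width band [%g, %g] mmHg.",
        sum(bad), nrow(out), toupper(target), band[1], band[2]))
    }
  }
  dplyr::relocate(out, "subject_id", "target")
}

#' Summarize per-subject intervals across a cohort
#'
#' Mean width and mean lower/upper bounds per method (the mean of
#' per-subject quantities, labeled as such), with between-subject SDs.
#'
#' @param cis Output of [subject_cis()].
#' @return Tibble of one row per target x method.
#' @export
ci_summary <- function(cis) {
  dplyr::summarise(
    dplyr::group_by(cis, .data$target, .data$method),
    mean_width = mean(.data$width), sd_width = sd(.data$width),
    mean_lower = mean(.data$lower), sd_lower = sd(.data$lower),
    mean_upper = mean(.data$upper), sd_upper = sd(.data$upper),
    n_subjects = dplyr::n(), .groups = "drop")
}
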