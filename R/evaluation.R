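#' Mean error, SD of error, and mean absolute error
#'
#' Per-record errors are `me_i = estimate_i - reference_i`; `ME` is their
#' mean, `MAE` the mean of their absolute values, and `SD` the (n-1)
#' standard deviation of the errors around `ME`.
#'
#' @param estimates,references Equal-length numeric vectors (mmHg).
#' @return Tibble row `me`, `sd`, `mae`, `n`.
#' @export
error_stats <- function(estimates, references) {
  if (length(estimates) != length(references)) {
    abort("`estimates` and `references` must have equal length.",
          class = "bpci_input_error")
  }
  stopifnot(length(estimates) >= 2)
  me_i <- estimates - references
  tibble::tibble(me = mean(me_i), sd = sd(me_i), mae = mean(abs(me_i)),
                 n = length(me_i))
}

#' AAMI/ESH device criterion
#'
#' Passes iff `|ME| <= 5` mmHg and `SD <= 8` mmHg (boundary inclusive).
#'
#' @param stats A row from [error_stats()], or any list with `me` and `sd`.
#' @return Tibble row: `pass`, `me_margin` (5 - |ME|), `sd_margin` (8 - SD).
#' @export
aami_check <- function(stats) {
  me <- stats$me; s <- stats$sd
  tibble::tibble(pass = abs(me) <= 5 && s <= 8,
                 me_margin = 5 - abs(me), sd_margin = 8 - s)
}

#' BHS cumulative-percentage grade
#'
#' Computes the percentage of absolute errors within 5, 10, and 15 mmHg
#' (inclusive thresholds) and grades A/B/C when *all three* cumulative
#' percentages meet that grade's cut-offs (A: 60/85/95, B: 50/75/90,
#' C: 40/65/85), else D.
#'
#' @param abs_errors Nonnegative absolute errors (mmHg), or pass
#'   `percentages =` directly to grade printed cumulative percentages.
#' @param percentages Optional numeric length-3 vector (p5, p10, p15).
#' @return Tibble row `p5`, `p10`, `p15`, `grade`.
#' @export
bhs_grade <- function(abs_errors = NULL, percentages = NULL) {
  if (is.null(percentages)) {
    stopifnot(length(abs_errors) >= 1, all(abs_errors >= 0))
    percentages <- vapply(c(5, 10, 15),
                          function(thr) 100 * mean(abs_errors <= thr),
                          numeric(1))
  }
  stopifnot(length(percentages) == 3)
  cuts <- list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
  grade <- "D"
  for (g in names(cuts)) {
    if (all(percentages >= cuts[[g]])) { grade <- g; break }
  }
  tibble::tibble(p5 = percentages[1], p10 = percentages[2],
                 p15 = percentages[3], grade = grade)
}

#' Bland-Altman agreement limits
#'
#' Mean difference and limits `ME +/- 2 * SD` (the conventional agreement
#' band), plus the per-point payload (mean of the pair vs difference) for
#' plotting.
#'
#' @param estimates,references Equal-length numeric vectors.
#' @return List with `stats` (`me`, `lower`, `upper`) and `points` tibble.
#' @export
bland_altman <- function(estimates, references) {
  es <- error_stats(estimates, references)
  points <- tibble::tibble(mean = (estimates + references) / 2,
                           difference = estimates - references)
  structure(list(stats = tibble::tibble(me = es$me,
                                        lower = es$me - 2 * es$sd,
                                        upper = es$me + 2 * es$sd,
                                        sd = es$sd, n = es$n),
                 points = points),
            class = "bp_bland_altman")
}

#' Full evaluation report for one prediction set
#'
#' Bundles [error_stats()], [aami_check()], [bhs_grade()] and
#' [bland_altman()] into one tibble row per target.
#'
#' @param predictions Tibble with `estimate`, `reference`, and a `target`
#'   column (`"sbp"`/`"dbp"`).
#' @return Tibble with one row per target.
#' @export
evaluate_predictions <- function(predictions) {
  stopifnot(all(c("estimate", "reference", "target") %in% names(predictions)))
  purrr::map_dfr(split(predictions, predictions$target), function(d) {
    es <- error_stats(d$estimate, d$reference)
    aami <- aami_check(es)
    bhs <- bhs_grade(abs(d$estimate - d$reference))
    tibble::tibble(target = d$target[1], es, aami_pass = aami$pass,
                   bhs_p5 = bhs$p5, bhs_p10 = bhs$p10, bhs_p15 = bhs$p15,
                   bhs_grade = bhs$grade)
  })
}
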