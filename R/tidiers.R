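#' Tidy a fitted Gaussian process model
#'
#' One row per hyperparameter (length scale(s), noise variance, signal
#' variance), on the standardized training scale.
#'
#' @param x A `bp_gpr` model.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @exportS3Method generics::tidy
tidy.bp_gpr <- function(x, ...) {
  eta_terms <- if (length(x$eta) == 1) "eta" else paste0("eta_", seq_along(x$eta))
  tibble::tibble(term = c(eta_terms, "sigma2_noise", "sigma2_signal"),
                 estimate = c(x$eta, x$s2, x$sf2))
}

#' @rdname tidy.bp_gpr
#' @exportS3Method generics::glance
glance.bp_gpr <- function(x, ...) {
  tibble::tibble(n = x$n, kernel = x$cfg$kernel, basis = x$cfg$basis,
                 log_marginal = x$log_marginal,
                 sigma2_noise = x$s2, sigma2_signal = x$sf2)
}

#' Tidy a gradient-boosted model's stage trajectory
#'
#' One row per boosting stage with the training MSE after that stage.
#'
#' @param x A `bp_gba` model.
#' @param ... Unused.
#' @return A tibble with `stage` and `train_mse`.
#' @exportS3Method generics::tidy
tidy.bp_gba <- function(x, ...) {
  tibble::tibble(stage = seq_along(x$train_mse), train_mse = x$train_mse)
}

#' @rdname tidy.bp_gba
#' @exportS3Method generics::glance
glance.bp_gba <- function(x, ...) {
  tibble::tibble(n_stages = length(x$stages), depth = x$cfg$depth,
                 shrinkage = x$cfg$shrinkage,
                 train_mse = x$train_mse[length(x$train_mse)])
}

#' Tidy a weighted-feature-decision result
#'
#' The per-subset-size CV error table, flagged at the chosen size.
#'
#' @param x A `bp_wfd` object.
#' @param ... Unused.
#' @return A tibble with `n_features`, `cv_mse`, `chosen`.
#' @exportS3Method generics::tidy
tidy.bp_wfd <- function(x, ...) {
  dplyr::mutate(x$bestmse, chosen = .data$n_features == x$n)
}

#' @rdname tidy.bp_wfd
#' @exportS3Method generics::glance
glance.bp_wfd <- function(x, ...) {
  tibble::tibble(n_selected = x$n, n_total = nrow(x$bestmse),
                 best_cv_mse = min(x$bestmse$cv_mse), folds = x$folds)
}
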