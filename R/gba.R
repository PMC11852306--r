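#' Gradient boosting configuration
#'
#' Stagewise additive regression trees fit to the negative gradient of the
#' squared-error loss. For squared loss with mean-valued leaves the exact
#' line search gives a unit step, applied with shrinkage `nu`.
#'
#' @param num_iter Number of boosting stages M (default 50).
#' @param shrinkage Learning rate nu in (0, 1].
#' @param depth Maximum tree depth (1 = stumps, default 2).
#' @param min_leaf Minimum samples per leaf.
#' @return A `bp_gba_config` list.
#' @export
gba_config <- function(num_iter = 50, shrinkage = 0.1, depth = 2, min_leaf = 5) {
  stopifnot(num_iter >= 1, shrinkage > 0, shrinkage <= 1, depth >= 1,
            min_leaf >= 1)
  structure(list(num_iter = num_iter, shrinkage = shrinkage,
                 depth = depth, min_leaf = min_leaf),
            class = "bp_gba_config")
}

#' Optimal weighted split of one feature column
#'
#' Scans the midpoints of sorted unique values of `x` and returns the
#' threshold minimizing the weighted sum of squared errors around the
#' side-wise weighted means. Ties in SSE break toward the smaller
#' threshold; the left/right values are the weighted averages of the
#' targets on each side. All `x` identical (or a side violating `min_leaf`)
#' yields a no-split sentinel.
#'
#' @param x Numeric feature column.
#' @param theta Targets (pseudo-residuals).
#' @param w Nonnegative weights (default unit).
#' @param min_leaf Minimum observations per side.
#' @return List `tau`, `zeta1`, `zeta2`, `sse`, `ok` (FALSE for no split).
#' @export
learn_split <- function(x, theta, w = rep(1, length(x)), min_leaf = 1) {
  n <- length(x)
  stopifnot(length(theta) == n, length(w) == n)
  ord <- order(x)
  xs <- x[ord]; ts <- theta[ord]; ws <- w[ord]
  wt <- cumsum(ws); wy <- cumsum(ws * ts); wyy <- cumsum(ws * ts^2)
  W <- wt[n]; Y <- wy[n]; YY <- wyy[n]
  # candidate split after position i (left = 1..i), only where x changes
  cand <- which(diff(xs) > 0)
  cand <- cand[cand >= min_leaf & (n - cand) >= min_leaf]
  if (length(cand) == 0 || W <= 0) {
    mu <- if (W > 0) Y / W else mean(theta)
    return(list(tau = NA_real_, zeta1 = mu, zeta2 = mu,
                sse = if (W > 0) YY - Y^2 / W else 0, ok = FALSE))
  }
  wl <- wt[cand]; yl <- wy[cand]; yyl <- wyy[cand]
  wr <- W - wl; yr <- Y - yl; yyr <- YY - yyl
  sse <- (yyl - yl^2 / wl) + (yyr - yr^2 / wr)
  best <- which.min(sse)            # which.min takes the first (smallest tau)
  i <- cand[best]
  list(tau = (xs[i] + xs[i + 1]) / 2,
       zeta1 = yl[best] / wl[best],
       zeta2 = yr[best] / wr[best],
       sse = sse[best], ok = TRUE)
}

# Recursive greedy regression tree on (X, theta, w); nodes stored as a list.
fit_tree <- function(X, theta, w, depth, min_leaf) {
  grow <- function(idx, d) {
    wi <- w[idx]
    mu <- sum(wi * theta[idx]) / sum(wi)
    if (d >= depth || length(idx) < 2 * min_leaf) {
      return(list(leaf = TRUE, value = mu))
    }
    best <- NULL; best_j <- 0L
    for (j in seq_len(ncol(X))) {
      s <- learn_split(X[idx, j], theta[idx], wi, min_leaf)
      if (!s$ok) next
      # strict improvement only: the ascending scan order makes ties break
      # toward the smallest feature index, and which.min inside learn_split
      # breaks within-feature ties toward the smallest threshold
      if (is.null(best) || s$sse < best$sse - 1e-12) {
        best <- s; best_j <- j
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, value = mu))
    left <- idx[X[idx, best_j] < best$tau]
    right <- idx[X[idx, best_j] >= best$tau]
    if (length(left) == 0 || length(right) == 0) {
      return(list(leaf = TRUE, value = mu))
    }
    list(leaf = FALSE, feature = best_j, tau = best$tau,
         left = grow(left, d + 1L), right = grow(right, d + 1L))
  }
  grow(seq_len(nrow(X)), 0L)
}

predict_tree <- function(node, X) {
  n <- nrow(X)
  out <- numeric(n)
  walk <- function(node, idx) {
    if (length(idx) == 0) return()
    if (node$leaf) {
      out[idx] <<- node$value
      return()
    }
    go_left <- X[idx, node$feature] < node$tau
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
  }
  walk(node, seq_len(n))
  out
}

#' Fit a gradient-boosted regression-tree model
#'
#' `F0` is the target mean; each stage fits a depth-limited tree to the
#' current residuals (the negative gradient of squared loss) and adds it
#' with step `shrinkage`. Training loss is non-increasing in the stage
#' count by construction.
#'
#' @param X Numeric matrix or data frame of features.
#' @param y Numeric targets.
#' @param cfg A [gba_config()].
#' @param weights Optional nonnegative observation weights.
#' @return A `bp_gba` model object.
#' @export
gba_fit <- function(X, y, cfg = gba_config(), weights = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort("Non-finite values in the training data.", class = "bpci_input_error")
  }
  n <- nrow(X)
  stopifnot(n == length(y), n >= 2)
  w <- weights %||% rep(1, n)
  F0 <- mean(y)
  Fhat <- rep(F0, n)
  stages <- vector("list", cfg$num_iter)
  train_mse <- numeric(cfg$num_iter)
  for (m in seq_len(cfg$num_iter)) {
    resid <- y - Fhat
    tree <- fit_tree(X, resid, w, cfg$depth, cfg$min_leaf)
    Fhat <- Fhat + cfg$shrinkage * predict_tree(tree, X)
    stages[[m]] <- tree
    train_mse[m] <- mean((y - Fhat)^2)
  }
  structure(list(F0 = F0, stages = stages, cfg = cfg,
                 p = ncol(X), feature_names = colnames(X),
                 train_mse = train_mse),
            class = "bp_gba")
}

#' Predict from a gradient-boosted model
#'
#' @param object A `bp_gba` model.
#' @param newdata Matrix or data frame with the training feature count.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.bp_gba <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$p) {
    abort(sprintf("Feature count mismatch: model has %d, data has %d.",
                  object$p, ncol(X)), class = "bpci_input_error")
  }
  out <- rep(object$F0, nrow(X))
  for (tree in object$stages) {
    out <- out + object$cfg$shrinkage * predict_tree(tree, X)
  }
  out
}

#' @export
print.bp_gba <- function(x, ...) {
  cat(sprintf("<bp_gba: %d stages, depth %d, shrinkage %g, final train MSE %.4g>\n",
              length(x$stages), x$cfg$depth, x$cfg$shrinkage,
              x$train_mse[length(x$train_mse)]))
  invisible(x)
}
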