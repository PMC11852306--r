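#' Plug-in mutual information between two numeric vectors
#'
#' Discretizes each variable into `bins` equal-frequency bins (rank-based,
#' deterministic under ties) and computes the plug-in mutual information of
#' the resulting contingency table, in nats. Symmetric in its arguments;
#' constant input gives 0.
#'
#' @param a,b Equal-length numeric vectors.
#' @param bins Number of bins per variable (default 10).
#' @return Nonnegative mutual information estimate (nats).
#' @export
estimate_mi <- function(a, b, bins = 10) {
  n <- length(a)
  stopifnot(length(b) == n)
  if (n < bins) {
    abort("Need at least `bins` observations.", class = "bpci_input_error")
  }
  bin_of <- function(x) {
    if (length(unique(x)) == 1L) return(rep(1L, n))
    r <- rank(x, ties.method = "first")
    pmin(bins, floor((r - 1) * bins / n) + 1L)
  }
  tab <- table(bin_of(a), bin_of(b))
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
}

#' Minimum-redundancy maximum-relevance feature ranking
#'
#' Greedy forward ranking by the mutual-information quotient. Phase 1 seeds
#' the ranking with the most relevant feature (largest `I(x, y)`). Phase 2
#' keeps picking, among unselected features with nonzero relevance and zero
#' redundancy to the selected set, the most relevant one. Phase 3 ranks the
#' rest by `MIQ = relevance / redundancy`, where redundancy is the mean
#' mutual information to the already-selected set, recomputed at every
#' step. Phase 4 appends zero-relevance features, by default in ascending
#' original index (deterministic); `shuffle_zero = TRUE` restores a seeded
#' random order.
#'
#' Relevance/redundancy "zero" tests use `tol` — exact zeros are rare with
#' plug-in estimators.
#'
#' @param X Feature matrix or data frame.
#' @param y Numeric target.
#' @param bins MI estimator bins.
#' @param tol Zero threshold for estimated MI.
#' @param shuffle_zero Randomize the zero-relevance tail?
#' @param seed Seed for the optional shuffle.
#' @return A `bp_mrmr` list: `ranking` (feature indices), `relevance`,
#'   and a `trace` tibble of per-step scores.
#' @export
mrmr_rank <- function(X, y, bins = 10, tol = 1e-12, shuffle_zero = FALSE,
                      seed = 1) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(p >= 1)
  relevance <- vapply(seq_len(p), function(j) estimate_mi(X[, j], y, bins),
                      numeric(1))
  # pairwise redundancy cache, filled lazily
  mi_cache <- matrix(NA_real_, p, p)
  pair_mi <- function(i, j) {
    if (is.na(mi_cache[i, j])) {
      v <- estimate_mi(X[, i], X[, j], bins)
      mi_cache[i, j] <<- v; mi_cache[j, i] <<- v
    }
    mi_cache[i, j]
  }
  selected <- integer(0)
  trace <- list()
  candidates <- seq_len(p)
  redundancy_to_S <- function(j) {
    if (length(selected) == 0) return(0)
    mean(vapply(selected, function(s) pair_mi(j, s), numeric(1)))
  }
  nonzero <- which(relevance > tol)
  if (length(nonzero) > 0) {
    # phase 1: max relevance
    first <- nonzero[which.max(relevance[nonzero])]
    selected <- first
    candidates <- setdiff(candidates, first)
    trace[[1]] <- tibble::tibble(feature = first, phase = 1L,
                                 relevance = relevance[first],
                                 redundancy = 0, miq = Inf)
    in_phase2 <- TRUE
    repeat {
      cand_rel <- candidates[relevance[candidates] > tol]
      if (length(cand_rel) == 0) break
      red <- vapply(cand_rel, redundancy_to_S, numeric(1))
      zero_red <- cand_rel[red <= tol]
      if (length(zero_red) == 0) in_phase2 <- FALSE  # phases run sequentially
      if (in_phase2 && length(zero_red) > 0) {
        # phase 2: relevant but unredundant features, by relevance
        pick <- zero_red[which.max(relevance[zero_red])]
        ph <- 2L
        miq <- Inf
      } else {
        # phase 3: mutual-information quotient
        miqs <- relevance[cand_rel] / red
        pick <- cand_rel[which.max(miqs)]
        ph <- 3L
        miq <- max(miqs)
      }
      selected <- c(selected, pick)
      candidates <- setdiff(candidates, pick)
      trace[[length(trace) + 1L]] <-
        tibble::tibble(feature = pick, phase = ph,
                       relevance = relevance[pick],
                       redundancy = redundancy_to_S(pick), miq = miq)
    }
  }
  # phase 4: zero-relevance tail
  if (length(candidates) > 0) {
    tail_idx <- sort(candidates)
    if (shuffle_zero) {
      rng <- local_rng(seed)
      tail_idx <- tail_idx[rng$sample(seq_along(tail_idx), length(tail_idx))]
    }
    for (j in tail_idx) {
      trace[[length(trace) + 1L]] <-
        tibble::tibble(feature = j, phase = 4L, relevance = relevance[j],
                       redundancy = redundancy_to_S(j), miq = 0)
    }
    selected <- c(selected, tail_idx)
  }
  structure(list(ranking = selected, relevance = relevance,
                 trace = dplyr::bind_rows(trace)),
            class = "bp_mrmr")
}

#' Weighted feature decision by cross-validated boosting error
#'
#' Ranks all features once with [mrmr_rank()], then for every prefix size
#' `n = p, p-1, ..., 1` measures the m-fold cross-validated test MSE of a
#' gradient-boosted model trained on the top-n ranked features. The same
#' fold partition (fixed by `seed`) is reused for every subset size so that
#' subset comparisons are not confounded by partition noise; set
#' `repartition = TRUE` to draw a fresh partition per size. The chosen size
#' minimizes mean CV MSE, ties breaking toward the smaller subset.
#'
#' @param X Feature matrix or data frame.
#' @param y Numeric target.
#' @param folds Number of CV folds m (default 5).
#' @param gba_cfg Boosting configuration (default `num_iter = 50`).
#' @param seed Integer seed fixing the partition.
#' @param bins MI estimator bins for the ranking.
#' @param repartition Redraw the fold partition for every subset size?
#' @return A `bp_wfd` list: `ranking`, `bestmse` tibble
#'   (`n_features`, `cv_mse`), chosen `n`, `selected` indices.
#' @export
wfd_select <- function(X, y, folds = 5, gba_cfg = gba_config(), seed = 1,
                       bins = 10, repartition = FALSE) {
  X <- as.matrix(X)
  n_obs <- nrow(X); p <- ncol(X)
  if (n_obs < folds) {
    abort("Fewer rows than folds.", class = "bpci_parameter_error")
  }
  ranking <- mrmr_rank(X, y, bins = bins)
  rng <- local_rng(seed)
  make_folds <- function() {
    perm <- rng$sample(seq_len(n_obs), n_obs)
    split(perm, rep(seq_len(folds), length.out = n_obs))
  }
  fold_idx <- make_folds()
  sizes <- seq(p, 1)
  cv_mse <- vapply(sizes, function(nf) {
    if (repartition) fold_idx <<- make_folds()
    cols <- ranking$ranking[seq_len(nf)]
    mse <- vapply(fold_idx, function(test_i) {
      train_i <- setdiff(seq_len(n_obs), test_i)
      fit <- gba_fit(X[train_i, cols, drop = FALSE], y[train_i], gba_cfg)
      mean((predict(fit, X[test_i, cols, drop = FALSE]) - y[test_i])^2)
    }, numeric(1))
    mean(mse)
  }, numeric(1))
  bestmse <- tibble::tibble(n_features = sizes, cv_mse = cv_mse)
  # argmin with ties toward the smaller subset (sizes descend, so scan for
  # the minimum and prefer later = smaller n on exact ties)
  best <- max(which(cv_mse <= min(cv_mse) + 0))
  n_star <- sizes[best]
  structure(list(ranking = ranking, bestmse = bestmse, n = n_star,
                 selected = ranking$ranking[seq_len(n_star)],
                 folds = folds, seed = seed),
            class = "bp_wfd")
}

#' @export
print.bp_wfd <- function(x, ...) {
  cat(sprintf("<bp_wfd: chose %d of %d features (CV MSE %.4g)>\n",
              x$n, nrow(x$bestmse),
              x$bestmse$cv_mse[x$bestmse$n_features == x$n]))
  invisible(x)
}
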