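# Independent brute-force oracles used to cross-check the implementations.

# exhaustive weighted split search over every midpoint of sorted unique values
oracle_split <- function(x, theta, w = rep(1, length(x))) {
  ux <- sort(unique(x))
  if (length(ux) < 2) return(NULL)
  best <- NULL
  for (i in seq_len(length(ux) - 1)) {
    tau <- (ux[i] + ux[i + 1]) / 2
    l <- x < tau
    z1 <- sum(w[l] * theta[l]) / sum(w[l])
    z2 <- sum(w[!l] * theta[!l]) / sum(w[!l])
    sse <- sum(w[l] * (theta[l] - z1)^2) + sum(w[!l] * (theta[!l] - z2)^2)
    if (is.null(best) || sse < best$sse - 1e-12) {
      best <- list(tau = tau, zeta1 = z1, zeta2 = z2, sse = sse)
    }
  }
  best
}

# brute-force relevance/redundancy ranking: seed with max relevance; exhaust
# relevant features with zero redundancy to the selected set (by relevance);
# then repeatedly take the best relevance/redundancy quotient; append
# zero-relevance features in index order
oracle_mrmr <- function(X, y, bins = 10, tol = 1e-12) {
  p <- ncol(X)
  rel <- sapply(seq_len(p), function(j) estimate_mi(X[, j], y, bins))
  mi <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i < j) mi[i, j] <- mi[j, i] <- estimate_mi(X[, i], X[, j], bins)
  }
  S <- integer(0)
  Sc <- seq_len(p)
  red <- function(j) if (length(S) == 0) 0 else mean(mi[j, S])
  if (any(rel > tol)) {
    pick <- Sc[rel[Sc] > tol][which.max(rel[Sc[rel[Sc] > tol]])]
    S <- pick; Sc <- setdiff(Sc, pick)
    repeat {   # relevant but unredundant features first
      cand <- Sc[rel[Sc] > tol & sapply(Sc, red) <= tol]
      if (length(cand) == 0) break
      pick <- cand[which.max(rel[cand])]
      S <- c(S, pick); Sc <- setdiff(Sc, pick)
    }
    repeat {   # then by mutual-information quotient
      cand <- Sc[rel[Sc] > tol]
      if (length(cand) == 0) break
      miq <- rel[cand] / sapply(cand, red)
      pick <- cand[which.max(miq)]
      S <- c(S, pick); Sc <- setdiff(Sc, pick)
    }
  }
  c(S, sort(Sc))
}
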