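# Empirical-Bayes wavelet shrinkage with a heavy-tailed Cauchy prior.
# Coefficients are modeled as z ~ N(mu, 1) with mu ~ (1-w) delta_0 + w Cauchy;
# the mixing weight w is estimated per level by marginal maximum likelihood
# and each coefficient is replaced by its posterior median. The posterior
# median is a genuine threshold rule: small coefficients go exactly to zero.

# beta(x) = f1(x)/f0(x) - 1 for the quasi-Cauchy prior, where f0 is the
# N(0,1) marginal and f1 the marginal under the prior.
beta_cauchy <- function(x) {
  phix <- dnorm(x)
  out <- rep(-0.5, length(x))
  j <- x != 0
  out[j] <- (dnorm(0) / phix[j] - 1) / x[j]^2 - 1
  # guard against overflow for very large |x|
  out[!is.finite(out)] <- .Machine$double.xmax / 2
  out
}

# Marginal ML mixing weight: solve sum_i beta(x_i) / (1 + w beta(x_i)) = 0
# for w in (eps, 1]; the score is decreasing in w, so bisection works.
ebayes_weight <- function(x, tol = 1e-8) {
  b <- beta_cauchy(x)
  b <- pmax(b, -1 + 1e-12)
  score <- function(w) sum(b / (1 + w * b))
  lo <- 1e-8
  if (score(1) >= 0) return(1)
  if (score(lo) <= 0) return(lo)
  for (i in 1:60) {
    mid <- (lo + 1) / 2
    if (score(mid) > 0) lo <- mid else {
      if (abs(score(mid)) < tol) return(mid)
      hi <- mid
      # plain bisection on [lo, hi]
      for (k in 1:60) {
        m2 <- (lo + hi) / 2
        if (score(m2) > 0) lo <- m2 else hi <- m2
      }
      return((lo + hi) / 2)
    }
  }
  lo
}

# Zero of the posterior-median equation for the quasi-Cauchy prior at
# observation z >= 0: med(z) is the value m solving g(m; z, w) = 0.
cauchy_med_zero <- function(m, z, w) {
  hh <- z - m
  dnhh <- dnorm(hh)
  yleft <- pnorm(hh) - z * dnhh + ((z * m - 1) * dnhh * pnorm(-m)) / dnorm(z)
  yright <- 1 + exp(-z^2 / 2) * (z^2 * (1 / w - 1) - 1)
  yright / 2 - yleft
}

# Posterior median for each (standardized) coefficient; vectorized bisection.
posterior_median_cauchy <- function(z, w) {
  az <- abs(z)
  out <- numeric(length(z))
  big <- az >= 20
  out[big] <- az[big] - 2 / az[big]
  j <- which(!big)
  if (length(j) > 0) {
    lo <- rep(0, length(j))
    hi <- pmax(az[j], 1)
    zz <- az[j]
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      gv <- cauchy_med_zero(mid, zz, w)
      # g is increasing in m (mass below m grows); move accordingly
      up <- gv <= 0
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    out[j] <- (lo + hi) / 2
  }
  out[out < 1e-7] <- 0
  sign(z) * out
}

# Shrink one vector of detail coefficients given the noise scale at that
# level: standardize, posterior-median threshold, scale back. The noise
# scale comes from the finest detail level (MAD-based), scaled down by
# sqrt(2) per level — for white noise the MODWT detail variance halves at
# each level, and coarser levels are signal-dominated so their own MAD
# would overestimate the noise and wipe the signal.
ebayes_shrink <- function(d, sigma) {
  if (!is.finite(sigma) || sigma <= 0) return(d)   # no measurable noise
  if (sigma < 1e-12 * max(abs(d), 1e-300)) return(d)
  z <- d / sigma
  w <- ebayes_weight(z)
  sigma * posterior_median_cauchy(z, w)
}
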