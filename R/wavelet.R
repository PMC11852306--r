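# Maximal-overlap discrete wavelet transform (undecimated, shift-invariant,
# length-preserving). Implemented from the standard pyramid recursions with
# circular filtering; callers get reflection boundary handling by mirroring
# the input to twice its length before transforming and truncating after the
# inverse, which avoids wrap-around artifacts in short analysis windows.

# scaling (low-pass) filters in reconstruction order g_0..g_{L-1}
wavelet_filters <- function(wavelet = c("db8", "sym4")) {
  wavelet <- match.arg(wavelet)
  g <- switch(wavelet,
    db8 = c(0.05441584224310401, 0.31287159091429995, 0.6756307362972898,
            0.5853546836542067, -0.015829105256349306, -0.2840155429615469,
            0.0004724845739132828, 0.12874742662047847, -0.017369301001807547,
            -0.044088253930794755, 0.013981027917398282, 0.008746094047405777,
            -0.004870352993451574, -0.00039174037337694705,
            0.0006754494064505693, -0.00011747678412476953),
    sym4 = c(0.0322231006040427, -0.012603967262037833, -0.09921954357684722,
             0.29785779560527736, 0.8037387518059161, 0.49761866763201545,
             -0.02963552764599851, -0.07576571478927333))
  L <- length(g)
  h <- rev(g) * (-1)^(seq_len(L) - 1)  # quadrature mirror wavelet filter
  list(g = g, h = h, L = L)
}

# circular filtering at level j: y_t = sum_l f_l x_{(t - 2^{j-1} l) mod N}
modwt_filt <- function(x, f, j) {
  n <- length(x)
  y <- numeric(n)
  step <- 2^(j - 1)
  idx0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    sh <- (idx0 - step * (l - 1L)) %% n
    y <- y + f[l] * x[sh + 1L]
  }
  y
}

# inverse step uses the time-reversed shifts
imodwt_filt <- function(x, f, j) {
  n <- length(x)
  y <- numeric(n)
  step <- 2^(j - 1)
  idx0 <- seq_len(n) - 1L
  for (l in seq_along(f)) {
    sh <- (idx0 + step * (l - 1L)) %% n
    y <- y + f[l] * x[sh + 1L]
  }
  y
}

#' Maximal-overlap discrete wavelet transform
#'
#' Decomposes `x` into detail coefficient vectors `d1..dJ` and the level-J
#' approximation `aJ`, all of the same length as `x` (the transform is
#' undecimated). Satisfies perfect reconstruction through [imodwt()].
#'
#' @param x Numeric vector.
#' @param wavelet `"db8"` or `"sym4"`.
#' @param level Decomposition depth J.
#' @param boundary `"reflection"` (default; mirrors `x` before a circular
#'   transform) or `"periodic"`.
#' @return List with elements `d` (list of J detail vectors), `a`
#'   (approximation), `wavelet`, `level`, `boundary`, `n` (original length).
#' @export
modwt <- function(x, wavelet = "db8", level = 4, boundary = c("reflection", "periodic")) {
  boundary <- match.arg(boundary)
  filt <- wavelet_filters(wavelet)
  if (length(x) < 2 * filt$L) {
    abort(sprintf("Input too short for MODWT with '%s': need >= %d samples.",
                  wavelet, 2 * filt$L),
          class = "bpci_length_error")
  }
  n <- length(x)
  xx <- if (boundary == "reflection") c(x, rev(x)) else x
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  v <- xx
  d <- vector("list", level)
  for (j in seq_len(level)) {
    d[[j]] <- modwt_filt(v, ht, j)
    v <- modwt_filt(v, gt, j)
  }
  list(d = d, a = v, wavelet = wavelet, level = level,
       boundary = boundary, n = n)
}

#' Inverse maximal-overlap discrete wavelet transform
#'
#' Reconstructs a signal from (possibly modified) MODWT coefficients; exact
#' inverse of [modwt()] when coefficients are untouched.
#'
#' @param w A list as returned by [modwt()].
#' @return Numeric vector of the original input length.
#' @export
imodwt <- function(w) {
  filt <- wavelet_filters(w$wavelet)
  gt <- filt$g / sqrt(2)
  ht <- filt$h / sqrt(2)
  v <- w$a
  for (j in rev(seq_len(w$level))) {
    v <- imodwt_filt(v, gt, j) + imodwt_filt(w$d[[j]], ht, j)
  }
  v[seq_len(w$n)]
}

# Reconstruction keeping only the named components (e.g. d2+d3), used for
# R-peak enhancement. Zero-phase because analysis and synthesis shifts cancel.
modwt_reconstruct <- function(w, keep_d = integer(), keep_a = FALSE) {
  w2 <- w
  for (j in seq_len(w$level)) {
    if (!(j %in% keep_d)) w2$d[[j]] <- numeric(length(w$d[[j]]))
  }
  if (!keep_a) w2$a <- numeric(length(w$a))
  imodwt(w2)
}
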