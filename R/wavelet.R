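# Continuous-wavelet machinery: Morlet CWT, cross-wavelet transform,
# wavelet coherence, red-noise and Monte Carlo significance.  Conventions
# follow the standard Torrence & Compo / Grinsted formulation with a Morlet
# mother wavelet of central frequency omega0 = 6.

#' Dyadic wavelet scale grid
#'
#' Builds the scale/period grid for a Morlet continuous wavelet transform.
#' Scales are `s0 * 2^(j * dj)` and Fourier periods are scales times the
#' Morlet Fourier factor `4 * pi / (omega0 + sqrt(2 + omega0^2))` (about
#' 1.033 for `omega0 = 6`).  The grid extends until the largest period
#' reaches `max_period`, by default half the series length, beyond which no
#' point of a series of length `n` lies inside the cone of influence.
#'
#' @param n series length (number of interactions).
#' @param dt sampling step; 1 interaction by construction here.
#' @param dj scale resolution in octave fractions (default 1/12, i.e. 12
#'   sub-octaves per power of two).
#' @param s0 smallest resolved scale, default `2 * dt`.
#' @param omega0 Morlet central frequency (default 6).
#' @param max_period largest Fourier period to resolve, default `n * dt / 2`.
#' @return an object of class `wavelet_grid` with elements `dt`, `dj`, `s0`,
#'   `omega0`, `scales`, `periods`, `fourier_factor`.
#' @export
#' @examples
#' g <- wavelet_grid(256)
#' range(g$periods)
wavelet_grid <- function(n, dt = 1, dj = 1 / 12, s0 = 2 * dt, omega0 = 6,
                         max_period = NULL) {
  stopifnot(n >= 8, dt > 0, dj > 0, s0 > 0, omega0 > 0)
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  if (is.null(max_period)) max_period <- n * dt / 2
  stopifnot(max_period > ff * s0)
  J <- max(1L, as.integer(ceiling(log2(max_period / (ff * s0)) / dj)))
  scales <- s0 * 2^((0:J) * dj)
  structure(
    list(dt = dt, dj = dj, s0 = s0, omega0 = omega0,
         scales = scales, periods = ff * scales, fourier_factor = ff),
    class = "wavelet_grid"
  )
}

same_grid <- function(a, b) {
  isTRUE(all.equal(a$scales, b$scales)) && a$dt == b$dt &&
    a$omega0 == b$omega0
}

#' Empirical-percentile transform
#'
#' Maps a series to its empirical CDF values (rank / n, average ranks for
#' ties), so each value represents a percentile of that user's own
#' distribution.  Applied before wavelet analysis to tame large spikes in
#' sentiment series while preserving rank order.
#'
#' @param x numeric vector, length at least 2, all finite.
#' @return numeric vector in `(0, 1]` with the same rank order as `x`.
#' @export
#' @examples
#' percentile_transform(c(1, 2, 3, 4))
percentile_transform <- function(x) {
  if (length(x) < 2L) stop("percentile_transform: need at least 2 values")
  if (!all(is.finite(x))) stop("percentile_transform: non-finite input")
  rank(x, ties.method = "average") / length(x)
}

#' Lag-1 autocorrelation (AR(1) coefficient) of a series
#'
#' Red-noise background estimate used by the wavelet significance tests.
#' The estimate is clipped away from +/-1 so the theoretical AR(1) spectrum
#' stays finite for strongly trending series.
#'
#' @param x numeric vector, length at least 10, non-constant.
#' @param max_abs clip bound (default 0.99).
#' @return estimated coefficient in `(-max_abs, max_abs)`.
#' @export
estimate_ar1 <- function(x, max_abs = 0.99) {
  n <- length(x)
  if (n < 10L) stop("estimate_ar1: need at least 10 observations")
  if (!all(is.finite(x))) stop("estimate_ar1: non-finite input")
  x0 <- x - mean(x)
  den <- sum(x0^2)
  if (den == 0) stop("estimate_ar1: constant series")
  r1 <- sum(x0[-1] * x0[-n]) / den
  max(min(r1, max_abs), -max_abs)
}

#' Morlet continuous wavelet transform
#'
#' FFT-based CWT with normalized Morlet daughters.  The series is
#' mean-removed and zero-padded to the next power of two at least twice the
#' series length, so the implied convolution is linear rather than circular.
#' The cone of influence uses the Morlet e-folding time `sqrt(2) * s`.
#'
#' @param x numeric series, length at least 8, finite.
#' @param grid a [wavelet_grid()]; built from `length(x)` if omitted.
#' @param ... passed to [wavelet_grid()] when `grid` is `NULL`.
#' @return an object of class `wavelet_spectrum`: complex `coefficients`
#'   (scales x time), the `grid`, per-time `coi` (largest reliable period),
#'   series length `n` and standard deviation `sd`.
#' @export
#' @examples
#' w <- morlet_cwt(sin(2 * pi * (1:128) / 16))
#' dim(w$coefficients)
morlet_cwt <- function(x, grid = NULL, ...) {
  n <- length(x)
  if (n < 8L) stop("morlet_cwt: series too short (need n >= 8)")
  if (!all(is.finite(x))) stop("morlet_cwt: non-finite input")
  if (is.null(grid)) grid <- wavelet_grid(n, ...)
  stopifnot(inherits(grid, "wavelet_grid"))
  if (n * grid$dt < 2 * grid$s0) stop("morlet_cwt: series shorter than 2*s0")
  dt <- grid$dt
  omega0 <- grid$omega0
  scales <- grid$scales

  x0 <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  xpad <- c(x0, rep(0, npad - n))
  xh <- stats::fft(xpad)

  k <- seq_len(npad) - 1L
  omega <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * dt))
  pos <- omega > 0

  # daughters in Fourier space: pi^(-1/4) sqrt(2 pi s / dt) H(w) exp(-(sw-w0)^2/2)
  ns <- length(scales)
  M <- matrix(0i, nrow = npad, ncol = ns)
  for (j in seq_len(ns)) {
    s <- scales[j]
    psi <- numeric(npad)
    psi[pos] <- pi^(-0.25) * sqrt(2 * pi * s / dt) *
      exp(-0.5 * (s * omega[pos] - omega0)^2)
    M[, j] <- xh * psi
  }
  W <- stats::mvfft(M, inverse = TRUE) / npad
  coefs <- t(W[seq_len(n), , drop = FALSE])

  d <- pmin(seq_len(n) - 1L, n - seq_len(n))
  coi <- grid$fourier_factor * sqrt(2) * dt * pmax(d, 1e-8)

  structure(
    list(coefficients = coefs, grid = grid, coi = coi, n = n,
         sd = stats::sd(x)),
    class = "wavelet_spectrum"
  )
}

#' Cross-wavelet transform
#'
#' `W^XY = W^X * Conj(W^Y)`.  Its modulus ("common power") locates
#' time-frequency regions where both series have high variance; its argument
#' is the relative phase of x with respect to y (positive angles: x leads).
#'
#' @param a,b `wavelet_spectrum` objects on the same grid and length.
#' @return an object of class `cross_spectrum` with `power`, `phase` (radians
#'   in `(-pi, pi]`), the complex `wxy`, `grid`, `coi`, `n`, and the input
#'   standard deviations.  Significance masks and coherence are filled in by
#'   [xwt_significance()] and [wtc()].
#' @export
xwt <- function(a, b) {
  stopifnot(inherits(a, "wavelet_spectrum"), inherits(b, "wavelet_spectrum"))
  if (a$n != b$n || !same_grid(a$grid, b$grid)) {
    stop("xwt: spectra are not on the same grid")
  }
  wxy <- a$coefficients * Conj(b$coefficients)
  structure(
    list(power = Mod(wxy), phase = Arg(wxy), wxy = wxy,
         grid = a$grid, coi = a$coi, n = a$n, sd_a = a$sd, sd_b = b$sd,
         coherence = NULL, sig_power = NULL, sig_coherence = NULL,
         coherence_crit = NULL),
    class = "cross_spectrum"
  )
}

# Theoretical normalized AR(1) ("red noise") spectrum at given Fourier
# periods, Gilman/Torrence-Compo form.
ar1_spectrum <- function(phi, periods, dt = 1) {
  freq <- dt / periods
  (1 - phi^2) / (1 + phi^2 - 2 * phi * cos(2 * pi * freq))
}

# Critical value z solving P(sqrt(X1 * X2) > z) = alpha for independent
# chi^2_2 variables X1, X2; the exact tail is z * K1(z) (Bessel K).
# z(0.05) = 3.999, the standard 95% cross-wavelet confidence constant.
xwt_zcrit <- function(alpha) {
  stopifnot(alpha > 0, alpha < 1)
  f <- function(z) z * besselK(z, 1) - alpha
  if (f(1e-8) < 0) return(1e-8)
  stats::uniroot(f, c(1e-8, 60), tol = 1e-10)$root
}

#' Pointwise red-noise significance of cross-wavelet power
#'
#' Tests `|W^XY|` against the product of the two theoretical AR(1) spectra.
#' Under the null, `|W^XY| / (sd_x * sd_y)` at a given scale is distributed
#' as `sqrt(P_x P_y)/2` times the square root of a product of two
#' independent chi-squared(2) variables, whose exact tail is `z K_1(z)`;
#' at `alpha = 0.05` the critical constant is the familiar 3.999.
#'
#' @param cross a [xwt()] result.
#' @param phi_a,phi_b AR(1) coefficients of the two input series, in (-1, 1).
#' @param alpha significance level in (0, 1), default 0.05.
#' @return `cross` with `sig_power` (logical matrix) filled in.
#' @export
xwt_significance <- function(cross, phi_a, phi_b, alpha = 0.05) {
  stopifnot(inherits(cross, "cross_spectrum"))
  if (!(alpha > 0 && alpha < 1)) stop("xwt_significance: alpha outside (0,1)")
  if (abs(phi_a) >= 1 || abs(phi_b) >= 1) {
    stop("xwt_significance: AR(1) coefficients must lie in (-1, 1)")
  }
  zc <- xwt_zcrit(alpha)
  pa <- ar1_spectrum(phi_a, cross$grid$periods, cross$grid$dt)
  pb <- ar1_spectrum(phi_b, cross$grid$periods, cross$grid$dt)
  crit <- (zc / 2) * sqrt(pa * pb) * cross$sd_a * cross$sd_b
  cross$sig_power <- cross$power > matrix(crit, nrow = length(crit),
                                          ncol = cross$n)
  cross
}

#' Scale-dependent smoothing of a wavelet matrix
#'
#' The coherence smoothing operator: a Gaussian filter in time whose width
#' equals the wavelet scale of each row, followed by a boxcar across scales
#' with a decorrelation width of 0.6 octaves (the standard factor for Morlet
#' wavelets).  Both passes are renormalized by the smoothed window mass so a
#' constant matrix passes through unchanged at the edges.
#'
#' @param m real matrix, scales x time, on `grid`.
#' @param grid the [wavelet_grid()] the rows correspond to.
#' @param scale_decorrelation boxcar width across scales, in octaves.
#' @return smoothed matrix of the same shape.
#' @export
smooth_spectrum <- function(m, grid, scale_decorrelation = 0.6) {
  stopifnot(is.matrix(m), nrow(m) == length(grid$scales))
  n <- ncol(m)
  npad <- 2^ceiling(log2(2 * n))
  k <- seq_len(npad) - 1L
  omega <- ifelse(k <= npad / 2, k, k - npad) * (2 * pi / (npad * grid$dt))

  P <- rbind(t(m), matrix(0, npad - n, nrow(m)))
  U <- matrix(0, npad, nrow(m))
  U[seq_len(n), ] <- 1
  Ph <- stats::mvfft(P)
  Uh <- stats::mvfft(U)
  for (j in seq_len(nrow(m))) {
    g <- exp(-0.5 * (grid$scales[j] * omega)^2)
    Ph[, j] <- Ph[, j] * g
    Uh[, j] <- Uh[, j] * g
  }
  sm <- Re(stats::mvfft(Ph, inverse = TRUE))[seq_len(n), , drop = FALSE] / npad
  wt <- Re(stats::mvfft(Uh, inverse = TRUE))[seq_len(n), , drop = FALSE] / npad
  out <- t(sm / pmax(wt, .Machine$double.eps))

  # boxcar across scales, half-width in grid rows
  hw <- max(0L, floor(scale_decorrelation / (2 * grid$dj)))
  if (hw > 0L) {
    ns <- nrow(out)
    acc <- matrix(0, ns, n)
    cnt <- numeric(ns)
    for (d in -hw:hw) {
      rows <- seq_len(ns) + d
      ok <- rows >= 1L & rows <= ns
      acc[ok, ] <- acc[ok, ] + out[rows[ok], , drop = FALSE]
      cnt[ok] <- cnt[ok] + 1
    }
    out <- acc / cnt
  }
  out
}

#' Wavelet coherence
#'
#' Squared cross-wavelet coherence
#' `R^2 = |S(W^XY / s)|^2 / (S(|W^X|^2 / s) * S(|W^Y|^2 / s))`
#' with `S` the scale-dependent smoothing operator of [smooth_spectrum()].
#' Interpretable as a squared correlation localized in time and frequency.
#'
#' @param a,b `wavelet_spectrum` objects on the same grid.
#' @param scale_decorrelation smoothing factor passed to [smooth_spectrum()].
#' @return coherence matrix in `[0, 1]`, scales x time.
#' @export
wtc <- function(a, b, scale_decorrelation = 0.6) {
  stopifnot(inherits(a, "wavelet_spectrum"), inherits(b, "wavelet_spectrum"))
  if (a$n != b$n || !same_grid(a$grid, b$grid)) {
    stop("wtc: spectra are not on the same grid")
  }
  g <- a$grid
  inv_s <- 1 / g$scales
  wxy <- a$coefficients * Conj(b$coefficients)
  num_re <- smooth_spectrum(Re(wxy) * inv_s, g, scale_decorrelation)
  num_im <- smooth_spectrum(Im(wxy) * inv_s, g, scale_decorrelation)
  den_a <- smooth_spectrum(Mod(a$coefficients)^2 * inv_s, g, scale_decorrelation)
  den_b <- smooth_spectrum(Mod(b$coefficients)^2 * inv_s, g, scale_decorrelation)
  r2 <- (num_re^2 + num_im^2) / pmax(den_a * den_b, .Machine$double.eps)
  pmin(pmax(r2, 0), 1)
}

#' Monte Carlo critical values for wavelet coherence
#'
#' Simulates `nsim` independent AR(1) pairs with the given coefficients,
#' runs each through the same CWT + coherence pipeline, pools coherence
#' values inside the cone of influence, and returns the per-scale
#' `(1 - alpha)` quantile.  Production analyses use `nsim = 2000`; reduced
#' values are appropriate for desk-scale checks.
#'
#' @param phi_a,phi_b AR(1) coefficients in (-1, 1).
#' @param n series length to simulate.
#' @param grid [wavelet_grid()]; defaults to the grid for `n`.
#' @param nsim number of Monte Carlo pairs (default 2000).
#' @param alpha significance level (default 0.05).
#' @param seed RNG seed; results are deterministic in it.
#' @param scale_decorrelation smoothing factor, as in [wtc()].
#' @return numeric vector of per-scale critical coherence values in (0, 1),
#'   with the grid attached as attribute `grid`.
#' @export
wtc_significance_mc <- function(phi_a, phi_b, n, grid = NULL, nsim = 2000,
                                alpha = 0.05, seed = 1,
                                scale_decorrelation = 0.6) {
  if (abs(phi_a) >= 1 || abs(phi_b) >= 1) {
    stop("wtc_significance_mc: AR(1) coefficients must lie in (-1, 1)")
  }
  stopifnot(alpha > 0, alpha < 1, nsim >= 10)
  if (is.null(grid)) grid <- wavelet_grid(n)
  ns <- length(grid$scales)
  reliable <- NULL
  with_seed(seed, {
    vals <- vector("list", nsim)
    for (i in seq_len(nsim)) {
      xa <- as.numeric(stats::filter(stats::rnorm(n), phi_a,
                                     method = "recursive"))
      xb <- as.numeric(stats::filter(stats::rnorm(n), phi_b,
                                     method = "recursive"))
      wa <- morlet_cwt(xa, grid)
      wb <- morlet_cwt(xb, grid)
      r2 <- wtc(wa, wb, scale_decorrelation)
      if (is.null(reliable)) reliable <- outer(grid$periods, wa$coi, "<")
      r2[!reliable] <- NA_real_
      vals[[i]] <- r2
    }
    crit <- numeric(ns)
    for (j in seq_len(ns)) {
      row <- unlist(lapply(vals, function(v) v[j, ]), use.names = FALSE)
      row <- row[is.finite(row)]
      crit[j] <- if (length(row)) stats::quantile(row, 1 - alpha, names = FALSE)
                 else NA_real_
    }
    attr(crit, "grid") <- grid
    attr(crit, "alpha") <- alpha
    crit
  })
}
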