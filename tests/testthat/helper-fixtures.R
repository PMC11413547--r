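# Shared fixtures: tiny lexicons, AR(1) simulation, a time-domain CWT used
# as the independent oracle for the FFT implementation, and a hand-built
# cross-spectrum for mask arithmetic.

tiny_lexicon <- function() {
  valence_lexicon(
    entries = c(good = 1.9, great = 3.1, bad = -2.5, awful = -2.0),
    boosters = c(very = 0.293, slightly = -0.293),
    negators = c("not", "never"),
    name = "tiny"
  )
}

sim_ar1 <- function(n, phi, sd = 1) {
  as.numeric(stats::filter(stats::rnorm(n, sd = sd), phi,
                           method = "recursive"))
}

# brute-force time-domain Morlet CWT at one scale (linear convolution with
# the sampled mother wavelet); independent of the FFT path
direct_cwt_scale <- function(x, s, dt = 1, omega0 = 6) {
  n <- length(x)
  x0 <- x - mean(x)
  vapply(seq_len(n), function(t) {
    eta <- (seq_len(n) - t) * dt / s
    psi <- pi^(-0.25) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
    sqrt(dt / s) * sum(x0 * Conj(psi))
  }, complex(1))
}

# minimal cross_spectrum carrying hand-set masks for fraction arithmetic
fake_cross <- function(sig, coi = NULL, periods = NULL) {
  ns <- nrow(sig)
  n <- ncol(sig)
  if (is.null(periods)) periods <- 2^seq(1, 5, length.out = ns)
  if (is.null(coi)) coi <- rep(max(periods) + 1, n) # everything reliable
  grid <- structure(list(dt = 1, dj = 1 / 12, s0 = 2, omega0 = 6,
                         scales = periods / 1.033, periods = periods,
                         fourier_factor = 1.033),
                    class = "wavelet_grid")
  structure(
    list(power = matrix(1, ns, n), phase = matrix(0, ns, n),
         wxy = matrix(1 + 0i, ns, n), grid = grid, coi = coi, n = n,
         sd_a = 1, sd_b = 1, coherence = matrix(0.5, ns, n),
         sig_power = sig, sig_coherence = sig, coherence_crit = NULL),
    class = "cross_spectrum"
  )
}
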