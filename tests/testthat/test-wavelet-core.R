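test_that("percentile transform is an average-rank ECDF", {
  expect_equal(percentile_transform(c(1, 2, 3, 4)), c(0.25, 0.5, 0.75, 1))
  expect_equal(percentile_transform(rep(7, 5)), rep(0.6, 5)) # mean rank / n
  set.seed(3)
  x <- rnorm(200)
  expect_identical(order(percentile_transform(x)), order(x))
  expect_error(percentile_transform(c(1, NA)), "non-finite")
  expect_error(percentile_transform(1), "at least 2")
})

test_that("the scale grid is dyadic with Morlet Fourier periods", {
  g <- wavelet_grid(256)
  expect_true(all(diff(g$scales) > 0))
  expect_equal(g$scales, g$s0 * 2^((seq_along(g$scales) - 1) * g$dj))
  ff <- 4 * pi / (g$omega0 + sqrt(2 + g$omega0^2))
  expect_equal(g$periods, g$scales * ff)
  expect_gte(max(g$periods), 128)
})

test_that("morlet_cwt localizes a cosine at its Fourier period", {
  expect_error(morlet_cwt(rnorm(4)), "too short")
  w0 <- morlet_cwt(rep(0, 64))
  expect_true(all(Mod(w0$coefficients) == 0))

  n <- 512
  w <- morlet_cwt(cos(2 * pi * seq_len(n) / 24))
  peak <- w$grid$periods[which.max(rowMeans(Mod(w$coefficients)^2))]
  expect_lt(abs(log2(peak / 24)), w$grid$dj + 1e-9) # within one dj step
  # coi is symmetric about the midpoint and peaks there
  expect_equal(w$coi, rev(w$coi))
  expect_equal(which.max(w$coi), n / 2)
})

test_that("FFT-based CWT matches direct time-domain convolution", {
  set.seed(8)
  n <- 128
  x <- rnorm(n)
  g <- wavelet_grid(n)
  w <- morlet_cwt(x, g)
  for (target in c(4, 8, 16)) {
    j <- which.min(abs(g$scales - target))
    d <- direct_cwt_scale(x, g$scales[j])
    rel <- max(Mod(w$coefficients[j, ] - d)) / max(Mod(d))
    expect_lt(rel, 1e-8)
  }
})

test_that("estimate_ar1 recovers lag-1 structure and clips degeneracies", {
  set.seed(5)
  expect_lt(abs(estimate_ar1(rnorm(4096))), 0.05)
  phis <- vapply(1:50, function(i) estimate_ar1(sim_ar1(4096, 0.7)),
                 numeric(1))
  expect_true(all(phis > 0.6 & phis < 0.8))
  expect_gt(mean(phis), 0.65)
  expect_lt(mean(phis), 0.75)
  expect_equal(estimate_ar1(seq_len(1000)), 0.99) # ramp hits the clip bound
  expect_error(estimate_ar1(rep(1, 20)), "constant")
  expect_error(estimate_ar1(1:5), "at least 10")
})

test_that("cross-spectrum of a series with itself is its power spectrum", {
  set.seed(6)
  w <- morlet_cwt(rnorm(128))
  cr <- xwt(w, w)
  expect_equal(cr$power, Mod(w$coefficients)^2)
  expect_true(all(abs(cr$phase) < 1e-12))
  w2 <- morlet_cwt(rnorm(64))
  expect_error(xwt(w, w2), "same grid")
})

test_that("a quarter-period lag shows as a 90 degree cross phase", {
  n <- 512
  tt <- seq_len(n)
  a <- morlet_cwt(sin(2 * pi * tt / 24 + pi / 2)) # leads by quarter period
  b <- morlet_cwt(sin(2 * pi * tt / 24))
  cr <- xwt(a, b)
  j <- which.min(abs(cr$grid$periods - 24))
  mid <- 100:412 # away from edges
  ph <- cr$phase[j, mid] * 180 / pi
  expect_lt(max(circ_dist_deg(ph, 90)), 10)
})

test_that("red-noise cross-power significance behaves at the limits", {
  set.seed(9)
  n <- 256
  xa <- sim_ar1(n, 0.4)
  xb <- sim_ar1(n, 0.4)
  cr <- xwt(morlet_cwt(xa), morlet_cwt(xb))
  expect_error(xwt_significance(cr, 0.4, 0.4, alpha = 1.5), "alpha")
  expect_error(xwt_significance(cr, 1.1, 0.4), "must lie in")
  tiny <- xwt_significance(cr, 0.4, 0.4, alpha = 1e-12)
  expect_equal(sum(tiny$sig_power), 0) # alpha -> 0 gives an empty mask

  # a strong shared sinusoid produces a contiguous significant band
  sh <- sin(2 * pi * seq_len(n) / 24)
  ca <- morlet_cwt(sh + 0.3 * sim_ar1(n, 0.2))
  cb <- morlet_cwt(sh + 0.3 * sim_ar1(n, 0.2))
  sig <- xwt_significance(xwt(ca, cb), 0.2, 0.2)
  j <- which.min(abs(sig$grid$periods - 24))
  expect_gt(mean(sig$sig_power[j, 40:216]), 0.95)
})

test_that("the smoothing operator preserves constants and local mass", {
  g <- wavelet_grid(128)
  ns <- length(g$scales)
  const <- matrix(3, ns, 128)
  expect_equal(smooth_spectrum(const, g), const, tolerance = 1e-10)
  # central impulse: normalized kernels redistribute but conserve mass
  imp <- matrix(0, ns, 128)
  imp[ns %/% 2, 64] <- 1
  sm <- smooth_spectrum(imp, g)
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  # smoothing is variance-contracting
  set.seed(2)
  m <- matrix(rnorm(ns * 128), ns, 128)
  expect_lt(var(as.numeric(smooth_spectrum(m, g))), var(as.numeric(m)))
})

test_that("wavelet coherence has the self, lag, and null properties", {
  set.seed(12)
  for (i in 1:3) {
    w <- morlet_cwt(rnorm(256))
    expect_lt(max(abs(wtc(w, w) - 1)), 1e-6)
  }
  # a pure time shift leaves coherence high in the shared band
  n <- 512
  base <- sin(2 * pi * seq_len(n) / 24)
  a <- morlet_cwt(base + 0.1 * rnorm(n))
  b <- morlet_cwt(sin(2 * pi * seq_len(n) / 24 + pi / 2) + 0.1 * rnorm(n))
  r2 <- wtc(a, b)
  j <- which.min(abs(a$grid$periods - 24))
  expect_gt(mean(r2[j, 100:412]), 0.9)
})

test_that("Monte Carlo coherence thresholds are in range and seeded", {
  crit1 <- wtc_significance_mc(0.3, 0.3, 64, nsim = 30, seed = 5)
  crit2 <- wtc_significance_mc(0.3, 0.3, 64, nsim = 30, seed = 5)
  expect_identical(crit1, crit2)
  ok <- !is.na(crit1)
  expect_true(any(ok))
  expect_true(all(crit1[ok] > 0 & crit1[ok] < 1))
  expect_error(wtc_significance_mc(1.2, 0.3, 64, nsim = 30), "must lie in")
  # independent white noise sits well below the 95% threshold on average
  set.seed(13)
  g <- attr(crit1, "grid")
  w1 <- morlet_cwt(rnorm(64), g)
  w2 <- morlet_cwt(rnorm(64), g)
  r2 <- wtc(w1, w2)
  rel <- outer(g$periods, w1$coi, "<")
  expect_lt(median(r2[rel]), stats::median(crit1[ok]))
})
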