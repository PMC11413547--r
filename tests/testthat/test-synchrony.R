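test_that("synchrony fractions are direct mask counts inside the coi", {
  sig <- matrix(FALSE, 6, 10)
  expect_equal(common_power_fraction(fake_cross(sig)), 0)
  expect_equal(coherence_fraction(fake_cross(sig)), 0)
  sig[] <- TRUE
  expect_equal(common_power_fraction(fake_cross(sig)), 1)
  set.seed(4)
  sig <- matrix(runif(60) < 0.3, 6, 10)
  expect_equal(common_power_fraction(fake_cross(sig)), sum(sig) / 60)
  # points at periods outside the coi are not counted
  periods <- c(2, 4, 8, 16, 32, 64)
  coi <- rep(10, 10) # only the first three rows are reliable
  cr <- fake_cross(sig, coi = coi, periods = periods)
  expect_equal(common_power_fraction(cr), sum(sig[1:3, ]) / 30)
  cr$coi <- rep(1, 10)
  expect_error(common_power_fraction(cr), "no reliable")
})

test_that("circular RP means wrap and rotate correctly", {
  deg2 <- function(angles) {
    sig <- matrix(TRUE, 1, length(angles))
    cr <- fake_cross(sig)
    cr$phase <- matrix(angles * pi / 180, 1)
    mean_rp_angle(cr)
  }
  expect_equal(deg2(c(10, -10)), 0)
  expect_equal(deg2(c(170, -170)), 180)
  # rotation equivariance
  set.seed(7)
  base <- runif(20, -90, 90)
  theta <- 35
  expect_equal(circ_dist_deg(deg2(base + theta), deg2(base) + theta), 0,
               tolerance = 1e-10)
  # no significant points -> missing value
  sig <- matrix(FALSE, 2, 5)
  expect_true(is.na(mean_rp_angle(fake_cross(sig))))
})

test_that("band fractions isolate the band containing the signal", {
  periods <- c(4, 8, 15, 24, 30, 40)
  sig <- matrix(FALSE, 6, 12)
  expect_equal(as.numeric(band_fractions(fake_cross(sig, periods = periods))),
               c(0, 0, 0))
  sig[4, ] <- TRUE # period 24 only
  bf <- band_fractions(fake_cross(sig, periods = periods))
  expect_gt(bf["low"], 0)
  expect_equal(unname(bf["medium"]), 0)
  expect_equal(unname(bf["high"]), 0)
  # a band with no grid rows is an error
  skinny <- fake_cross(sig[1:2, , drop = FALSE], periods = c(4, 8))
  expect_error(band_fractions(skinny), "no grid rows")
})

test_that("full-pipeline analysis recovers coupling and the shuffled
           baseline destroys it", {
  n <- 256
  real_wins <- vapply(1:10, function(s) {
    u <- simulate_pair(n, coupling = 0.8, phase_lag = 0, period = 24,
                       ar1_phi = 0.3, noise_sd = 1, trend_slope = 0,
                       seed = 500 + s)
    r <- analyze_pair(u, wtc_sig = "none")
    sh <- shuffled_baseline(u, seed = 900 + s, wtc_sig = "none")
    r$metrics$common_power_frac > sh$metrics$common_power_frac
  }, logical(1))
  expect_gte(sum(real_wins), 8)
})

test_that("shuffled_baseline is deterministic and in range", {
  u <- simulate_pair(128, 0.5, 0, 24, 0.3, 1, 0, seed = 3)
  a <- shuffled_baseline(u, seed = 10, wtc_sig = "none")
  b <- shuffled_baseline(u, seed = 10, wtc_sig = "none")
  expect_identical(a$metrics, b$metrics)
  expect_gte(a$metrics$common_power_frac, 0)
  expect_lte(a$metrics$common_power_frac, 1)
})

test_that("paired test matches t.test and the d_z construction", {
  set.seed(11)
  x <- rnorm(30); y <- rnorm(30)
  ours <- paired_synchrony_test(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  expect_equal(ours$df, unname(ref$parameter))
  # identical vectors: no detectable difference
  same <- paired_synchrony_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(paired_synchrony_test(rep(2, 5), rep(1, 5)), "zero variance")
  # a one-SD mean shift gives d_z near 1
  set.seed(12)
  base <- rnorm(199)
  d <- rnorm(199, mean = 1, sd = 1)
  res <- paired_synchrony_test(base + d, base)
  expect_equal(res$d_z, mean(d) / sd(d), tolerance = 1e-12)
  expect_gt(res$t, 10)
})

test_that("band ANOVA agrees with the aov() within-subject decomposition", {
  set.seed(21)
  n <- 25
  m <- cbind(low = rnorm(n, 0.5), medium = rnorm(n), high = rnorm(n))
  ours <- band_anova(m)
  long <- data.frame(y = as.numeric(m),
                     band = factor(rep(colnames(m), each = n)),
                     subj = factor(rep(seq_len(n), 3)))
  ref <- summary(aov(y ~ band + Error(subj), data = long))
  reff <- ref[["Error: Within"]][[1]]
  expect_equal(ours$F, reff["band", "F value"], tolerance = 1e-8)
  expect_equal(ours$p, reff["band", "Pr(>F)"], tolerance = 1e-8)
  expect_equal(ours$df1, 2L)
  expect_equal(ours$df2, 2L * (n - 1L))
  # identical band values per user -> F = 0
  same <- band_anova(cbind(a = m[, 1], b = m[, 1], c = m[, 1]))
  expect_equal(same$F, 0)
  # a shifted band is detected by the omnibus and pairwise tests
  shifted <- m
  shifted[, "low"] <- shifted[, "low"] + 1
  res <- band_anova(shifted)
  expect_lt(res$p, 0.001)
  lowhigh <- res$pairwise[res$pairwise$band_a == "low" &
                          res$pairwise$band_b == "high", ]
  expect_lt(lowhigh$p, 0.001)
  expect_error(band_anova(m[1:2, ]), "3 subjects")
})

test_that("metric correlations match cor() with listwise deletion", {
  set.seed(31)
  d <- data.frame(a = rnorm(40), b = rnorm(40), c = rnorm(40))
  d$b[3] <- NA
  res <- correlate_metrics(d)
  expect_equal(res$n, 39)
  cc <- d[complete.cases(d), ]
  expect_equal(res$r, cor(cc), tolerance = 1e-12)
  expect_equal(res$r["a", "a"], 1)
  expect_equal(res$p["a", "b"], cor.test(cc$a, cc$b)$p.value,
               tolerance = 1e-12)
  expect_error(correlate_metrics(d[1:2, ]), "fewer than 3")
})
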