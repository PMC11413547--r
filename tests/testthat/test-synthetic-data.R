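test_that("simulate_pair validates parameters and is deterministic", {
  expect_error(simulate_pair(4, 0.5, 0, 24, 0.3, 1, 0, 1), "n must be")
  expect_error(simulate_pair(64, 0.5, 0, 24, 1.2, 1, 0, 1), "ar1_phi")
  expect_error(simulate_pair(64, 1.5, 0, 24, 0.3, 1, 0, 1), "coupling")
  expect_error(simulate_pair(64, NA, 0, 24, 0.3, 1, 0, 1), "non-finite")
  a <- simulate_pair(128, 0.6, 0, 24, 0.3, 1, -0.002, seed = 9)
  b <- simulate_pair(128, 0.6, 0, 24, 0.3, 1, -0.002, seed = 9)
  expect_identical(a, b)
  expect_length(a$self_sentiment, 128)
  expect_length(a$peer_sentiment, 128)
  expect_true(all(is.finite(a$self_sentiment)))
  expect_true(all(is.finite(a$peer_sentiment)))
})

test_that("zero coupling yields statistically independent streams", {
  u <- simulate_pair(8192, coupling = 0, phase_lag = 0, period = 24,
                     ar1_phi = 0.3, noise_sd = 1, trend_slope = 0, seed = 4)
  expect_lt(abs(cor(u$self_sentiment, u$peer_sentiment)), 0.05)
})

test_that("full coupling with no noise reproduces the peer oscillation", {
  u <- simulate_pair(256, coupling = 1, phase_lag = 0, period = 24,
                     ar1_phi = 0.3, noise_sd = 0, trend_slope = 0, seed = 4)
  expect_equal(u$self_sentiment, u$peer_sentiment, tolerance = 1e-12)
  expect_equal(cor(u$self_sentiment, u$peer_sentiment), 1)
})

test_that("simulate_community draws valid lengths and is reproducible", {
  cfg <- sim_config(n_users = 12, n_interactions_range = c(100, 140),
                    seed = 11)
  com1 <- simulate_community(cfg)
  com2 <- simulate_community(cfg)
  expect_identical(com1, com2)
  lens <- vapply(com1, function(u) length(u$self_sentiment), integer(1))
  expect_true(all(lens >= 100 & lens <= 140))
  days <- vapply(com1, function(u) u$days_active, numeric(1))
  expect_true(all(days >= 10 & days <= 400))
  expect_length(simulate_community(sim_config(n_users = 0)), 0)
  expect_error(sim_config(coupling = 2), "coupling")
  expect_error(sim_config(n_interactions_range = c(200, 100)), "range")
})

test_that("simulated text valence drives the lexicon score monotonically", {
  lex <- default_lexicon()
  expect_gt(lexicon_score(simulate_text(1, 40, lex, seed = 1), lex), 0)
  expect_lt(lexicon_score(simulate_text(-1, 40, lex, seed = 1), lex), 0)
  grid <- c(-1, -0.5, 0, 0.5, 1)
  means <- vapply(grid, function(v) {
    mean(vapply(1:50, function(s) {
      lexicon_score(simulate_text(v, 30, lex, seed = s), lex)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  empty <- valence_lexicon(c(good = 1.5))
  expect_error(simulate_text(0, 10, empty, 1), "positive and negative")
})

test_that("corpus serialization is byte-identical under a fixed seed and
           its bookkeeping matches what is written", {
  cfg <- sim_config(n_users = 3, n_interactions_range = c(100, 110),
                    seed = 5)
  com <- simulate_community(cfg)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  b1 <- write_corpus_jsonl(com, f1, seed = 2)
  b2 <- write_corpus_jsonl(com, f2, seed = 2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(b1, b2)
  lines <- readLines(f1)
  expect_length(lines, sum(b1$n_valid + b1$n_removed + b1$n_short))
  ids <- vapply(lines, function(l) jsonlite::fromJSON(l)$user_id,
                character(1), USE.NAMES = FALSE)
  expect_equal(as.vector(table(ids)[b1$user_id]),
               b1$n_valid + b1$n_removed + b1$n_short)
})

test_that("downstream coherence increases with generating coupling", {
  # fixed critical values from a common AR(1) null keep the comparison fair
  n <- 128
  grid <- wavelet_grid(n)
  crit <- wtc_significance_mc(0.3, 0.3, n, grid, nsim = 100, seed = 77)
  mean_frac <- function(coupling) {
    mean(vapply(1:30, function(s) {
      u <- simulate_pair(n, coupling, 0, 24, 0.3, 1, 0,
                         seed = derive_seed(1000, coupling * 10, s))
      res <- analyze_pair(u, wtc_sig = crit, grid = grid)
      res$metrics$coherence_frac
    }, numeric(1)))
  }
  fr <- vapply(c(0, 0.4, 0.8), mean_frac, numeric(1))
  expect_true(all(diff(fr) >= 0))
})
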