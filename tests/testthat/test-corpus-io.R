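make_jsonl <- function(records) {
  f <- withr::local_tempfile(fileext = ".jsonl", .local_envir = parent.frame())
  writeLines(vapply(records, function(r) {
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE))
  }, character(1)), f)
  f
}

rec <- function(user = "u1", ts = 1e9, body = "three word comment",
                parent = "a parent post here", score = 1, removed = FALSE) {
  list(user_id = user, created_utc = ts, body = body, parent_body = parent,
       score = score, removed = removed)
}

test_that("read_interactions groups, sorts, and tolerates malformed lines", {
  empty <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(character(0), empty)
  expect_length(read_interactions(empty), 0)

  f <- make_jsonl(list(rec(ts = 300), rec(ts = 100), rec(ts = 200),
                       rec(user = "u2", ts = 50)))
  corpus <- read_interactions(f)
  expect_named(corpus, c("u1", "u2"))
  expect_equal(corpus$u1$records$timestamp, c(100, 200, 300))

  bad <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(as.character(jsonlite::toJSON(rec(), auto_unbox = TRUE)),
               "{not json", "also not json"), bad)
  expect_error(read_interactions(bad), "malformed")
  writeLines(c(vapply(list(rec(), rec(ts = 2e9), rec(ts = 3e9)),
                      function(r) as.character(jsonlite::toJSON(r, auto_unbox = TRUE)),
                      character(1)),
               "{not json"), bad)
  corpus <- read_interactions(bad)
  expect_equal(attr(corpus, "n_malformed"), 1L)
  expect_equal(n_records(corpus$u1), 3L)
})

test_that("filter_comments applies the word-count and deletion rules with
           one reason code per exclusion", {
  f <- make_jsonl(list(
    rec(ts = 1, body = "thanks doc"),                      # 2 words -> out
    rec(ts = 2, body = "thanks doc again"),                # exactly 3 -> in
    rec(ts = 3, body = "[removed]"),                       # sentinel -> out
    rec(ts = 4, body = "long enough comment", removed = TRUE), # flag -> out
    rec(ts = 5, body = NA),                                # missing -> out
    rec(ts = 6, body = "https://a.io b", parent = "ok then fine"), # 1 word
    rec(ts = 7, body = "perfectly fine comment here")
  ))
  h <- read_interactions(f)$u1
  n_in <- n_records(h)
  fh <- filter_comments(h)
  expect_equal(n_records(fh), 2L)
  expect_equal(n_records(fh) + nrow(fh$exclusion_log), n_in)
  expect_setequal(fh$exclusion_log$reason[fh$exclusion_log$timestamp %in% c(1, 6)],
                  "too_short")
  expect_setequal(fh$exclusion_log$reason[fh$exclusion_log$timestamp %in% c(3, 4)],
                  "removed")
  expect_equal(fh$exclusion_log$reason[fh$exclusion_log$timestamp == 5],
               "missing")
  # idempotence
  expect_identical(filter_comments(fh), fh)
})

test_that("constructed exclusions are counted exactly", {
  k <- 4; m <- 3
  records <- c(
    lapply(seq_len(k), function(i) rec(ts = i, removed = TRUE)),
    lapply(seq_len(m), function(i) rec(ts = 100 + i, body = "too short")),
    lapply(seq_len(5), function(i) rec(ts = 200 + i))
  )
  h <- read_interactions(make_jsonl(records))$u1
  fh <- filter_comments(h)
  expect_equal(nrow(fh$exclusion_log), k + m)
  expect_equal(n_records(fh), 5L)
})

test_that("eligibility uses post-exclusion counts with a hard threshold", {
  mk <- function(id, n) {
    lapply(seq_len(n), function(i) rec(user = id, ts = i))
  }
  f <- make_jsonl(c(mk("u099", 99), mk("u100", 100), mk("umod", 500)))
  corpus <- lapply(read_interactions(f), filter_comments)
  expect_equal(select_eligible_users(corpus), c("u100", "umod"))
  expect_equal(select_eligible_users(corpus, exclude_ids = "umod"), "u100")
  expect_equal(select_eligible_users(corpus, min_activity = 99),
               c("u099", "u100", "umod"))
})

test_that("to_paired_series yields aligned chronological vectors and
           covariates", {
  records <- lapply(seq_len(120), function(i) {
    rec(ts = i * 86400 / 4, body = "the doctor helped me today")
  })
  h <- filter_comments(read_interactions(make_jsonl(records))$u1)
  ps <- to_paired_series(h, sentiment_fn = function(x) rep(0.5, length(x)))
  expect_s3_class(ps, "paired_series")
  expect_length(ps$self, 120)
  expect_length(ps$peer, 120)
  expect_true(all(ps$self == 0.5))                 # constant texts
  expect_equal(ps$word_count, rep(5L, 120))
  expect_equal(ps$health_pct, rep(100 * 1 / 5, 120)) # "doctor" of 5 tokens
  expect_equal(ps$days_active_span, (120 - 1) / 4)
  short <- h
  short$records <- short$records[1:50, ]
  expect_error(to_paired_series(short, function(x) rep(0, length(x))),
               "below the 100 minimum")
})

test_that("scored series recover the generating valence signal", {
  cfg <- sim_config(n_users = 2, n_interactions_range = c(120, 120),
                    coupling = 0, noise_sd = 1.5, seed = 21)
  com <- simulate_community(cfg)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(com, f, seed = 3, removed_rate = 0, short_rate = 0)
  corpus <- lapply(read_interactions(f), filter_comments)
  texts <- unlist(lapply(corpus, function(h) {
    c(h$records$comment_text, h$records$parent_text)
  }))
  scorer <- make_compound_scorer(texts)
  ps <- to_paired_series(corpus[[1]], scorer)
  latent <- com[[1]]$self_sentiment
  expect_gt(cor(ps$self, latent), 0.5)
})

test_that("exclusion accounting reports consistent percentages", {
  acc <- exclusion_accounting(1000, 77)
  expect_equal(acc$retained, 923)
  expect_equal(acc$retention_pct + acc$excluded_pct, 100)
  expect_error(exclusion_accounting(10, 11))
})
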