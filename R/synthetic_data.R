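# Synthetic community generator.  Produces paired user/peer sentiment series
# with known frequency-specific coupling, phase lag, AR(1) noise and
# tenure-dependent trend, plus optional token-level comment text, so the
# whole analysis pipeline is testable without any platform data.

#' Simulation configuration
#'
#' Bundles and validates the generating parameters for a synthetic
#' community.  Defaults describe a moderately coupled community: series
#' lengths bracket a few hundred interactions per user (the activity scale
#' typical of long-tenured forum members), a single shared oscillation at 24
#' interactions sits inside the low-frequency analysis band, and sentiment
#' drifts slowly downward with tenure.
#'
#' @param n_users number of simulated users.
#' @param n_interactions_range integer `(min, max)`; per-user series lengths
#'   are drawn uniformly from this range.  The minimum defaults to 100,
#'   mirroring the activity eligibility threshold.
#' @param coupling fraction in `[0, 1]` of the peer oscillatory signal mixed
#'   into the user signal.
#' @param phase_lag phase of the user oscillation relative to the peer
#'   oscillation, radians at `oscillation_period`; positive values mean the
#'   user leads.
#' @param oscillation_period shared oscillation period, interaction units.
#' @param ar1_phi AR(1) coefficient of the background noise, in (-1, 1).
#' @param noise_sd innovation standard deviation of the AR(1) backgrounds
#'   and of the additive observation noise (half weight), sentiment units.
#' @param trend_slope linear sentiment drift per 1% of a user's activity
#'   (i.e. per interaction window), sentiment units.
#' @param tenure_days_range positive `(min, max)`; per-user days-active
#'   spans are drawn uniformly from this range.
#' @param seed master RNG seed; identical config + seed give bit-identical
#'   output.
#' @return an object of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_users = 5, seed = 7)
sim_config <- function(n_users = 199,
                       n_interactions_range = c(100L, 600L),
                       coupling = 0.6,
                       phase_lag = 0,
                       oscillation_period = 24,
                       ar1_phi = 0.3,
                       noise_sd = 1,
                       trend_slope = -0.002,
                       tenure_days_range = c(10, 400),
                       seed = 1L) {
  cfg <- list(n_users = as.integer(n_users),
              n_interactions_range = as.integer(n_interactions_range),
              coupling = coupling, phase_lag = phase_lag,
              oscillation_period = oscillation_period,
              ar1_phi = ar1_phi, noise_sd = noise_sd,
              trend_slope = trend_slope,
              tenure_days_range = as.numeric(tenure_days_range),
              seed = as.integer(seed))
  vals <- unlist(cfg[c("coupling", "phase_lag", "oscillation_period",
                       "ar1_phi", "noise_sd", "trend_slope")])
  if (!all(is.finite(vals))) stop("sim_config: non-finite parameter")
  if (cfg$n_users < 0) stop("sim_config: n_users must be >= 0")
  if (length(cfg$n_interactions_range) != 2L ||
      any(cfg$n_interactions_range < 8L) ||
      diff(cfg$n_interactions_range) < 0) {
    stop("sim_config: invalid n_interactions_range")
  }
  if (cfg$coupling < 0 || cfg$coupling > 1) {
    stop("sim_config: coupling must lie in [0, 1]")
  }
  if (abs(cfg$ar1_phi) >= 1) stop("sim_config: |ar1_phi| must be < 1")
  if (cfg$noise_sd < 0) stop("sim_config: noise_sd must be >= 0")
  if (cfg$oscillation_period <= 0) {
    stop("sim_config: oscillation_period must be > 0")
  }
  if (length(cfg$tenure_days_range) != 2L ||
      any(cfg$tenure_days_range <= 0) || diff(cfg$tenure_days_range) < 0) {
    stop("sim_config: invalid tenure_days_range")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate one paired user/peer sentiment series
#'
#' The peer stream is an AR(1) background plus a unit-amplitude sinusoid at
#' `period`.  The user stream mixes a phase-shifted copy of the peer
#' oscillation (weight `coupling`) with an independent AR(1) background
#' (weight `1 - coupling`), a linear tenure trend, and additive Gaussian
#' observation noise.  The phase lag is applied only to the oscillatory
#' component, so the relative-phase ground truth at `period` is exactly
#' `phase_lag` (user leading for positive values).
#'
#' @param n series length, at least 8.
#' @param coupling,phase_lag,period,ar1_phi,noise_sd,trend_slope see
#'   [sim_config()]; `period` is the oscillation period.
#' @param seed RNG seed.
#' @param user_id optional identifier stored on the result.
#' @param days_active optional tenure span in days stored on the result.
#' @return an object of class `simulated_user`: `user_id`,
#'   `self_sentiment`, `peer_sentiment` (equal-length finite vectors),
#'   `days_active`, and `true_params` (the generating values).
#' @export
#' @examples
#' u <- simulate_pair(128, coupling = 0.8, phase_lag = pi / 2, period = 24,
#'                    ar1_phi = 0.3, noise_sd = 1, trend_slope = 0, seed = 1)
#' length(u$self_sentiment)
simulate_pair <- function(n, coupling, phase_lag, period, ar1_phi, noise_sd,
                          trend_slope, seed, user_id = "user",
                          days_active = 100) {
  pars <- c(n = n, coupling = coupling, phase_lag = phase_lag,
            period = period, ar1_phi = ar1_phi, noise_sd = noise_sd,
            trend_slope = trend_slope)
  if (!all(is.finite(pars))) stop("simulate_pair: non-finite parameter")
  if (n < 8) stop("simulate_pair: n must be >= 8")
  if (abs(ar1_phi) >= 1) stop("simulate_pair: |ar1_phi| must be < 1")
  if (coupling < 0 || coupling > 1) {
    stop("simulate_pair: coupling must lie in [0, 1]")
  }
  if (noise_sd < 0 || period <= 0) stop("simulate_pair: invalid parameter")

  with_seed(seed, {
    tt <- seq_len(n)
    osc_peer <- sin(2 * pi * tt / period)
    osc_self <- sin(2 * pi * tt / period + phase_lag)
    ar_peer <- as.numeric(stats::filter(stats::rnorm(n, sd = noise_sd),
                                        ar1_phi, method = "recursive"))
    ar_self <- as.numeric(stats::filter(stats::rnorm(n, sd = noise_sd),
                                        ar1_phi, method = "recursive"))
    wpos <- if (n > 1) 100 * (tt - 1) / (n - 1) else 0 # percent of activity
    self <- coupling * osc_self + (1 - coupling) * ar_self +
      trend_slope * wpos + stats::rnorm(n, sd = noise_sd / 2)
    peer <- ar_peer + osc_peer
    structure(
      list(user_id = user_id, self_sentiment = self, peer_sentiment = peer,
           days_active = days_active, true_params = as.list(pars)),
      class = "simulated_user"
    )
  })
}

#' Simulate a community of paired sentiment series
#'
#' Per-user series lengths and tenures are drawn from the config ranges;
#' each user's own RNG stream is seeded by [derive_seed()] from the master
#' seed and the user index, so a community is reproducible as a whole and
#' user-by-user.
#'
#' @param config a [sim_config()].
#' @return a list of `simulated_user` objects (possibly empty), with the
#'   config attached as attribute `config`.
#' @export
#' @examples
#' com <- simulate_community(sim_config(n_users = 3, seed = 2))
#' length(com)
simulate_community <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_users == 0L) {
    return(structure(list(), config = config))
  }
  users <- vector("list", config$n_users)
  for (i in seq_len(config$n_users)) {
    s_len <- derive_seed(config$seed, i, 1)
    n_i <- with_seed(s_len, {
      r <- config$n_interactions_range
      r[1] + sample.int(r[2] - r[1] + 1L, 1L) - 1L
    })
    days_i <- with_seed(derive_seed(config$seed, i, 2), {
      r <- config$tenure_days_range
      stats::runif(1, r[1], r[2])
    })
    users[[i]] <- simulate_pair(
      n = n_i, coupling = config$coupling, phase_lag = config$phase_lag,
      period = config$oscillation_period, ar1_phi = config$ar1_phi,
      noise_sd = config$noise_sd, trend_slope = config$trend_slope,
      seed = derive_seed(config$seed, i, 3),
      user_id = sprintf("user%04d", i), days_active = days_i
    )
  }
  structure(users, config = config)
}

# neutral filler vocabulary for generated comments; includes a few
# health-related tokens so the health-language covariate is exercised
sim_filler_words <- function() {
  c("the", "and", "then", "today", "because", "about", "really", "maybe",
    "people", "forum", "thread", "reply", "again", "still", "always",
    "doctor", "pain", "medication", "treatment", "symptoms", "therapy")
}

#' Generate comment text with a target valence
#'
#' Draws a token stream from a valence lexicon so that the expected lexicon
#' score increases monotonically with `valence`: each token is a neutral
#' filler with fixed probability, otherwise a positive-entry word with
#' probability `(1 + valence) / 2` and a negative-entry word otherwise.
#'
#' @param valence target valence in `[-1, 1]`.
#' @param n_words number of tokens, at least 1.
#' @param lexicon a [valence_lexicon()] with at least one positive and one
#'   negative entry.
#' @param seed RNG seed.
#' @param filler_prob probability that a token is a neutral filler.
#' @return a single text string.
#' @export
#' @examples
#' simulate_text(1, 10, default_lexicon(), seed = 1)
simulate_text <- function(valence, n_words, lexicon, seed,
                          filler_prob = 0.45) {
  stopifnot(inherits(lexicon, "valence_lexicon"))
  if (!is.finite(valence) || valence < -1 || valence > 1) {
    stop("simulate_text: valence must lie in [-1, 1]")
  }
  if (n_words < 1) stop("simulate_text: n_words must be >= 1")
  pos <- names(lexicon$entries)[lexicon$entries > 0]
  neg <- names(lexicon$entries)[lexicon$entries < 0]
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("simulate_text: lexicon needs positive and negative entries")
  }
  with_seed(seed, {
    fill <- stats::runif(n_words) < filler_prob
    posdraw <- stats::runif(n_words) < (1 + valence) / 2
    words <- character(n_words)
    words[fill] <- sample(sim_filler_words(), sum(fill), replace = TRUE)
    words[!fill & posdraw] <- sample(pos, sum(!fill & posdraw), replace = TRUE)
    words[!fill & !posdraw] <- sample(neg, sum(!fill & !posdraw),
                                      replace = TRUE)
    paste(words, collapse = " ")
  })
}

#' Serialize a simulated community as a JSON-Lines interaction corpus
#'
#' Writes one record per interaction in the same format [read_interactions()]
#' parses: `user_id`, `created_utc`, `body`, `parent_body`, `score`,
#' `removed`.  Comment text is generated from each latent sentiment value
#' via [simulate_text()] (latent values are squashed to `[-1, 1]` with
#' `tanh(x / 1.5)` before use as text valence).  A small fraction of extra
#' invalid records (moderator-removed, or under the word-count floor) is
#' interleaved so ingestion filters are exercised; they are additional to
#' the `n` valid interactions of each user.
#'
#' @param community result of [simulate_community()].
#' @param path output file path.
#' @param lexicon [valence_lexicon()] used for text generation.
#' @param seed RNG seed for text and timestamps.
#' @param removed_rate,short_rate expected fractions of injected removed /
#'   too-short records, relative to the valid count.
#' @param n_words_range token-count range for generated comments.
#' @return invisibly, a data.frame of per-user bookkeeping: `user_id`,
#'   `n_valid`, `n_removed`, `n_short`.
#' @export
write_corpus_jsonl <- function(community, path, lexicon = default_lexicon(),
                               seed = 1, removed_rate = 0.02,
                               short_rate = 0.02,
                               n_words_range = c(12L, 40L)) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  book <- vector("list", length(community))
  base_utc <- 1262304000 # 2010-01-01, arbitrary corpus epoch
  for (i in seq_along(community)) {
    u <- community[[i]]
    n <- length(u$self_sentiment)
    s_user <- derive_seed(seed, i, 11)
    rec <- with_seed(s_user, {
      n_rm <- stats::rbinom(1, n, removed_rate)
      n_sh <- stats::rbinom(1, n, short_rate)
      ntot <- n + n_rm + n_sh
      ts <- base_utc + sort(stats::runif(ntot, 0, u$days_active * 86400))
      kind <- sample(c(rep("valid", n), rep("removed", n_rm),
                       rep("short", n_sh)))
      list(n_rm = n_rm, n_sh = n_sh, ts = ts, kind = kind,
           nw = n_words_range[1] +
             sample.int(n_words_range[2] - n_words_range[1] + 1L, ntot,
                        replace = TRUE) - 1L,
           score = stats::rpois(ntot, 3))
    })
    vi <- 0L
    for (k in seq_along(rec$kind)) {
      kind <- rec$kind[k]
      if (kind == "valid") {
        vi <- vi + 1L
        body <- simulate_text(tanh(u$self_sentiment[vi] / 1.5), rec$nw[k],
                              lexicon, derive_seed(seed, i, k, 1))
        parent <- simulate_text(tanh(u$peer_sentiment[vi] / 1.5), rec$nw[k],
                                lexicon, derive_seed(seed, i, k, 2))
        removed <- FALSE
      } else if (kind == "removed") {
        body <- "[removed]"
        parent <- "this thread was locked by the moderators"
        removed <- TRUE
      } else {
        body <- "thanks again"
        parent <- simulate_text(0, rec$nw[k], lexicon,
                                derive_seed(seed, i, k, 3))
        removed <- FALSE
      }
      line <- jsonlite::toJSON(
        list(user_id = u$user_id, created_utc = rec$ts[k], body = body,
             parent_body = parent, score = rec$score[k], removed = removed),
        auto_unbox = TRUE, digits = NA
      )
      writeLines(as.character(line), con)
    }
    book[[i]] <- data.frame(user_id = u$user_id, n_valid = n,
                            n_removed = rec$n_rm, n_short = rec$n_sh,
                            stringsAsFactors = FALSE)
  }
  invisible(do.call(rbind, book))
}
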