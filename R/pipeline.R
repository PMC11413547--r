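# End-to-end orchestration: simulate -> ingest -> score -> wavelet
# synchrony -> trajectory, with a consolidated report.  Every stage's
# randomness derives from the single config seed, so a run's config
# reproduces its outputs byte for byte.

#' Pipeline configuration
#'
#' Collects every stage parameter with reduced-cost defaults suitable for a
#' desk-scale run (20 users, 200 Monte Carlo initializations).
#' `paper_scale = TRUE` switches to the full-study profile (199 users, 2000
#' initializations); expect a long runtime.
#'
#' @param seed master seed driving all stages.
#' @param n_users community size.
#' @param sim a [sim_config()]; built from `seed`/`n_users` if omitted.
#' @param text generate and score comment text (`TRUE`, the full path) or
#'   analyze the latent sentiment series directly (`FALSE`).
#' @param min_words,min_activity ingestion filters.
#' @param alpha significance level for wavelet masks.
#' @param nsim Monte Carlo initializations for coherence significance.
#' @param n_windows trajectory windows per user.
#' @param bands frequency-band definition.
#' @param shuffle_strategy `"self"` or `"both"` (see [shuffled_baseline()]).
#' @param days_active tenure regressor: `"span"` or `"distinct"`.
#' @param out_dir optional directory for per-stage artifacts (corpus
#'   JSON-Lines, exclusion and metric CSVs, JSON report).
#' @param paper_scale use the full-study profile.
#' @param input optional path to an existing JSON-Lines corpus; when given,
#'   the simulate stage is skipped.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, n_users = 20, sim = NULL, text = TRUE,
                            min_words = 3, min_activity = 100, alpha = 0.05,
                            nsim = 200, n_windows = 100,
                            bands = default_bands(),
                            shuffle_strategy = "self",
                            days_active = "span",
                            out_dir = NULL, paper_scale = FALSE,
                            input = NULL) {
  if (paper_scale) {
    n_users <- 199
    nsim <- 2000
  }
  if (is.null(sim)) sim <- sim_config(n_users = n_users, seed = seed)
  structure(
    list(seed = as.integer(seed), n_users = as.integer(n_users), sim = sim,
         text = isTRUE(text), min_words = min_words,
         min_activity = min_activity, alpha = alpha, nsim = as.integer(nsim),
         n_windows = as.integer(n_windows), bands = bands,
         shuffle_strategy = shuffle_strategy, days_active = days_active,
         out_dir = out_dir, paper_scale = isTRUE(paper_scale),
         input = input),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' Top-level keys override [pipeline_config()] arguments; a `sim` block
#' overrides [sim_config()] arguments.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  sim_args <- raw$sim
  raw$sim <- NULL
  if (!is.null(sim_args)) {
    if (is.null(sim_args$seed)) sim_args$seed <- raw$seed %||% 1
    raw$sim <- do.call(sim_config, sim_args)
  }
  do.call(pipeline_config, raw)
}

stage_msg <- function(...) message("[sentsync] ", sprintf(...))

pipeline_fail <- function(stage, e) {
  stop(sprintf("pipeline stage '%s' failed: %s", stage,
               conditionMessage(e)), call. = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate (unless an input corpus is
#' given), ingest and filter, sentiment scoring, per-user wavelet synchrony
#' with shuffled baselines, group tests, band ANOVA, metric correlations,
#' and the growth-curve model -- and returns a consolidated report.  When
#' `config$out_dir` is set, per-stage artifacts are written there.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `run_report`: a list with `config_digest`,
#'   `counts`, `exclusions`, `agreement`, `metrics` (per-user data.frame),
#'   `tests` (paired real-vs-shuffled tests), `band_anova_power`,
#'   `band_anova_coherence`, `metric_correlations`, `rp_angle_mean_deg`,
#'   `growth`, and `descriptives`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  # -- simulate ------------------------------------------------------------
  corpus_path <- config$input
  community <- NULL
  book <- NULL
  if (is.null(corpus_path)) {
    stage_msg("simulate: %d users, coupling %.2f, seed %d",
              config$sim$n_users, config$sim$coupling, config$sim$seed)
    community <- tryCatch(simulate_community(config$sim),
                          error = function(e) pipeline_fail("simulate", e))
    if (config$text) {
      corpus_path <- file.path(out_dir %||% tempdir(), "corpus.jsonl")
      book <- write_corpus_jsonl(community, corpus_path,
                                 seed = derive_seed(config$seed, 7))
    }
  }

  # -- ingest + score ------------------------------------------------------
  if (config$text || !is.null(config$input)) {
    stage_msg("ingest: %s", corpus_path)
    series <- tryCatch({
      corpus <- read_interactions(corpus_path)
      corpus <- lapply(corpus, filter_comments, min_words = config$min_words)
      eligible <- select_eligible_users(corpus,
                                        min_activity = config$min_activity)
      corpus <- corpus[eligible]
      excl <- exclusion_table(corpus)
      stage_msg("score: %d eligible users, %d retained comments",
                length(eligible), sum(excl$retained))
      texts <- unlist(lapply(corpus, function(h) {
        c(h$records$comment_text, h$records$parent_text)
      }), use.names = FALSE)
      scorer <- make_compound_scorer(texts)
      ser <- lapply(corpus, to_paired_series, sentiment_fn = scorer,
                    min_length = config$min_activity)
      attr(ser, "exclusions") <- excl
      attr(ser, "agreement") <- attr(scorer, "agreement")
      ser
    }, error = function(e) pipeline_fail("ingest/score", e))
    exclusions <- attr(series, "exclusions")
    agreement <- attr(series, "agreement")
  } else {
    stage_msg("ingest: using latent sentiment series directly")
    series <- community
    exclusions <- NULL
    agreement <- NULL
  }
  if (length(series) < 3L) {
    pipeline_fail("ingest/score",
                  simpleError("fewer than 3 analyzable users"))
  }

  # -- synchrony -----------------------------------------------------------
  stage_msg("synchrony: %d users, nsim = %d", length(series), config$nsim)
  met_rows <- vector("list", length(series))
  for (i in seq_along(series)) {
    pr <- series[[i]]
    res <- tryCatch(
      analyze_pair(pr, alpha = config$alpha, wtc_sig = "mc",
                   nsim = config$nsim, bands = config$bands,
                   seed = derive_seed(config$seed, i, 21)),
      error = function(e) pipeline_fail("synchrony", e))
    sh <- tryCatch(
      shuffled_baseline(pr, seed = derive_seed(config$seed, i, 22),
                        strategy = config$shuffle_strategy,
                        alpha = config$alpha, wtc_sig = "mc",
                        nsim = config$nsim, bands = config$bands),
      error = function(e) pipeline_fail("synchrony", e))
    m <- res$metrics; ms <- sh$metrics
    met_rows[[i]] <- data.frame(
      user_id = if (!is.null(pr$user_id)) pr$user_id else sprintf("u%03d", i),
      n = m$n,
      common_power = m$common_power_frac,
      coherence = m$coherence_frac,
      rp_angle_deg = m$rp_angle_deg,
      pearson_r = m$pearson_r,
      common_power_shuffled = ms$common_power_frac,
      coherence_shuffled = ms$coherence_frac,
      cp_low = m$band_common_power["low"],
      cp_medium = m$band_common_power["medium"],
      cp_high = m$band_common_power["high"],
      coh_low = m$band_coherence["low"],
      coh_medium = m$band_coherence["medium"],
      coh_high = m$band_coherence["high"],
      stringsAsFactors = FALSE
    )
  }
  metrics <- do.call(rbind, met_rows)
  rownames(metrics) <- NULL

  tests <- list(
    common_power = paired_synchrony_test(metrics$common_power,
                                         metrics$common_power_shuffled),
    coherence = paired_synchrony_test(metrics$coherence,
                                      metrics$coherence_shuffled)
  )
  anova_power <- band_anova(metrics[, c("cp_low", "cp_medium", "cp_high")])
  anova_coh <- band_anova(metrics[, c("coh_low", "coh_medium", "coh_high")])
  correlations <- correlate_metrics(metrics[, c("pearson_r", "coherence",
                                                "coherence_shuffled",
                                                "common_power",
                                                "common_power_shuffled")])

  # -- trajectory ----------------------------------------------------------
  stage_msg("trajectory: %d windows per user", config$n_windows)
  growth <- tryCatch({
    wt <- windowed_table(series, metrics$common_power,
                         n_windows = config$n_windows,
                         days_active = config$days_active)
    fit_growth_model(wt)
  }, error = function(e) pipeline_fail("trajectory", e))

  counts <- list(
    n_users = length(series),
    n_interactions = sum(metrics$n),
    n_excluded = if (!is.null(exclusions)) {
      sum(exclusions$removed + exclusions$missing + exclusions$too_short)
    } else 0L
  )
  counts$accounting <- exclusion_accounting(
    counts$n_interactions + counts$n_excluded, counts$n_excluded)

  report <- structure(
    list(config_digest = config_digest(config),
         counts = counts, exclusions = exclusions, agreement = agreement,
         metrics = metrics, tests = tests,
         band_anova_power = anova_power, band_anova_coherence = anova_coh,
         metric_correlations = correlations,
         rp_angle_mean_deg = circ_mean_deg(metrics$rp_angle_deg),
         growth = growth,
         descriptives = NULL),
    class = "run_report"
  )
  report$descriptives <- describe_corpus(report, series)

  if (!is.null(out_dir)) {
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    if (!is.null(exclusions)) {
      utils::write.csv(exclusions, file.path(out_dir, "exclusions.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(report_body(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# stable serializable body of a report (no model objects)
report_body <- function(report) {
  g <- report$growth
  list(
    config_digest = report$config_digest,
    counts = report$counts[c("n_users", "n_interactions", "n_excluded")],
    retention_pct = report$counts$accounting$retention_pct,
    agreement = report$agreement,
    tests = report$tests,
    band_anova_power = report$band_anova_power[c("F", "df1", "df2", "p")],
    band_anova_coherence = report$band_anova_coherence[c("F", "df1", "df2",
                                                         "p")],
    rp_angle_mean_deg = report$rp_angle_mean_deg,
    growth = list(coefficients = g$coefficients, sigma2 = g$sigma2,
                  tau00 = g$tau00, icc = g$icc,
                  r2_marginal = g$r2_marginal,
                  r2_conditional = g$r2_conditional,
                  n_users = g$n_users, n_obs = g$n_obs),
    descriptives = report$descriptives
  )
}

# deterministic digest of the serializable part of a config
config_digest <- function(config) {
  s <- jsonlite::toJSON(config[c("seed", "n_users", "text", "min_words",
                                 "min_activity", "alpha", "nsim",
                                 "n_windows", "shuffle_strategy",
                                 "days_active", "paper_scale")],
                        auto_unbox = TRUE, digits = NA)
  sim <- config$sim
  s2 <- jsonlite::toJSON(unclass(sim), auto_unbox = TRUE, digits = NA)
  x <- paste0(s, "|", s2)
  # small rolling hash; stdlib-only stand-in for a cryptographic digest
  h <- 0
  for (ch in utf8ToInt(x)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%010d", h)
}

#' Descriptive statistics table for a processed corpus
#'
#' Means and standard deviations of the per-user activity, sentiment,
#' feedback and synchrony summaries: comments per user, comments per day,
#' days active, sentiment of personal and peer comments, replies received
#' from peers, comment score, common power and coherence.  Quantities the
#' supplied corpus does not carry (e.g. comment scores for latent-series
#' runs) are reported as `NA`.
#'
#' @param report a `run_report`.
#' @param series the list of per-user series the report was built from
#'   (optional; enables the sentiment and tenure rows).
#' @return data.frame with columns `variable`, `mean`, `sd`.
#' @export
describe_corpus <- function(report, series = NULL) {
  m <- report$metrics
  if (is.null(m) || nrow(m) == 0L) stop("describe_corpus: empty corpus")
  msd <- function(x) {
    x <- x[is.finite(x)]
    if (length(x) == 0L) c(NA_real_, NA_real_) else c(mean(x), stats::sd(x))
  }
  rows <- list(
    c("Comments made per user", msd(m$n)),
    c("Comments made per day", msd(per_user_stat(series, function(s) {
      da <- s$days_active_span %||% s$days_active
      if (is.null(da) || !is.finite(da) || da <= 0) NA_real_
      else length(series_self(s)) / da
    }))),
    c("Number of days active in the community",
      msd(per_user_stat(series, function(s) {
        s$days_active_span %||% s$days_active %||% NA_real_
      }))),
    c("Sentiment of personal comments",
      msd(per_user_stat(series, function(s) mean(series_self(s))))),
    c("Sentiment of peer comments",
      msd(per_user_stat(series, function(s) mean(series_peer(s))))),
    c("Number of replies received from peers", c(NA_real_, NA_real_)),
    c("Comment score (upvotes-downvotes)", c(NA_real_, NA_real_)),
    c("Common power (%XWT)", msd(m$common_power)),
    c("Coherence (%WTC)", msd(m$coherence))
  )
  out <- data.frame(
    variable = vapply(rows, `[[`, character(1), 1),
    mean = as.numeric(vapply(rows, `[[`, character(1), 2)),
    sd = as.numeric(vapply(rows, `[[`, character(1), 3)),
    stringsAsFactors = FALSE
  )
  out
}

series_self <- function(s) s$self %||% s$self_sentiment
series_peer <- function(s) s$peer %||% s$peer_sentiment

per_user_stat <- function(series, f) {
  if (is.null(series)) return(numeric(0))
  vapply(series, function(s) as.numeric(f(s)), numeric(1))
}

#' @export
print.run_report <- function(x, ...) {
  cat("sentsync run report (config ", x$config_digest, ")\n", sep = "")
  cat(sprintf("  users analyzed: %d   interactions: %d (excluded: %d, retention %.2f%%)\n",
              x$counts$n_users, x$counts$n_interactions, x$counts$n_excluded,
              x$counts$accounting$retention_pct))
  if (!is.null(x$agreement)) {
    cat(sprintf("  scorer agreement: alpha = %.2f, r = %.2f\n",
                x$agreement$alpha, x$agreement$r))
  }
  tp <- x$tests$common_power
  tc <- x$tests$coherence
  cat(sprintf("  common power:  real %.4f vs shuffled %.4f  (t(%d) = %.2f, p = %.2g, d_av = %.2f)\n",
              tp$mean_real, tp$mean_shuffled, tp$df, tp$t, tp$p, tp$d_av))
  cat(sprintf("  coherence:     real %.4f vs shuffled %.4f  (t(%d) = %.2f, p = %.2g, d_av = %.2f)\n",
              tc$mean_real, tc$mean_shuffled, tc$df, tc$t, tc$p, tc$d_av))
  cat(sprintf("  mean RP angle: %.1f deg\n", x$rp_angle_mean_deg))
  ba <- x$band_anova_power
  cat(sprintf("  band ANOVA (common power): F(%d, %d) = %.2f, p = %.2g\n",
              ba$df1, ba$df2, ba$F, ba$p))
  cat("  growth model:\n")
  print(x$growth)
  invisible(x)
}
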