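# JSON-Lines corpus ingestion: read, validate, filter and chronologically
# assemble interaction records into per-user paired sentiment series,
# applying the eligibility and exclusion rules of the analysis design
# (deleted content removed, comments under 3 words removed, users with
# fewer than 100 valid interactions excluded).

new_user_history <- function(user_id, records, exclusion_log = NULL) {
  if (is.null(exclusion_log)) {
    exclusion_log <- data.frame(timestamp = numeric(0),
                                reason = character(0),
                                stringsAsFactors = FALSE)
  }
  structure(list(user_id = user_id, records = records,
                 exclusion_log = exclusion_log),
            class = "user_history")
}

#' Number of retained records in a user history
#' @param history a `user_history`.
#' @return integer count.
#' @export
n_records <- function(history) nrow(history$records)

#' Read a JSON-Lines interaction corpus
#'
#' Parses one JSON object per line with fields `user_id`, `created_utc`,
#' `body`, `parent_body`, `score`, and optional `removed`; unknown fields
#' are ignored.  Records are grouped by user and sorted chronologically
#' (stable for ties).  Malformed lines are counted and skipped; more than
#' half malformed lines is treated as a corrupt stream and raises an error.
#'
#' @param path file path (or connection) to a UTF-8 JSON-Lines stream.
#' @return a named list of `user_history` objects, sorted by user id, with
#'   attribute `n_malformed`.
#' @export
read_interactions <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  n_bad <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    r <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    ok <- !is.null(r) && is.list(r) &&
      !is.null(r$user_id) && nzchar(as.character(r$user_id)[1]) &&
      !is.null(r$created_utc) && is.finite(as.numeric(r$created_utc)[1])
    if (!ok) {
      n_bad <- n_bad + 1L
      next
    }
    recs[[i]] <- data.frame(
      user_id = as.character(r$user_id)[1],
      timestamp = as.numeric(r$created_utc)[1],
      comment_text = if (is.null(r$body)) NA_character_
                     else as.character(r$body)[1],
      parent_text = if (is.null(r$parent_body)) NA_character_
                    else as.character(r$parent_body)[1],
      score = if (is.null(r$score)) NA_integer_
              else as.integer(round(as.numeric(r$score)[1])),
      removed_flag = isTRUE(as.logical(r$removed)[1]),
      stringsAsFactors = FALSE
    )
  }
  if (length(lines) > 0 && n_bad > length(lines) / 2) {
    stop("read_interactions: more than 50% of lines are malformed")
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    out <- list()
    attr(out, "n_malformed") <- n_bad
    return(out)
  }
  tab <- do.call(rbind, recs)
  out <- lapply(split(tab, tab$user_id), function(d) {
    d <- d[order(d$timestamp), , drop = FALSE]
    rownames(d) <- NULL
    new_user_history(d$user_id[1], d)
  })
  out <- out[order(names(out))]
  attr(out, "n_malformed") <- n_bad
  out
}

#' Filter a user history by deletion status and word count
#'
#' Moves records to the exclusion log when they are flagged removed (or
#' carry a deleted-content sentinel body), have missing comment or parent
#' text, or fall under the word-count floor.  Each excluded record carries
#' exactly one reason code, with precedence removed > missing > too_short.
#' Chronological order is preserved and the operation is idempotent.
#'
#' @param history a `user_history`.
#' @param min_words minimum comment word count (default 3; a 3-word comment
#'   is retained).
#' @param deleted_sentinels body strings treated as deleted content.
#' @return the filtered `user_history` with an appended `exclusion_log`.
#' @export
filter_comments <- function(history, min_words = 3,
                            deleted_sentinels = c("[deleted]", "[removed]")) {
  stopifnot(inherits(history, "user_history"))
  d <- history$records
  if (nrow(d) == 0L) return(history)
  removed <- d$removed_flag | (!is.na(d$comment_text) &
                               trimws(d$comment_text) %in% deleted_sentinels)
  missing <- !removed & (is.na(d$comment_text) | !nzchar(trimws(d$comment_text)) |
                         is.na(d$parent_text) | !nzchar(trimws(d$parent_text)))
  wc <- word_count(d$comment_text)
  short <- !removed & !missing & wc < min_words
  drop <- removed | missing | short
  reason <- ifelse(removed, "removed", ifelse(missing, "missing", "too_short"))
  log_new <- data.frame(timestamp = d$timestamp[drop],
                        reason = reason[drop], stringsAsFactors = FALSE)
  history$records <- d[!drop, , drop = FALSE]
  rownames(history$records) <- NULL
  history$exclusion_log <- rbind(history$exclusion_log, log_new)
  history
}

#' Select users meeting the activity eligibility threshold
#'
#' Users qualify when their post-exclusion record count is at least
#' `min_activity` and their id is not in `exclude_ids` (moderators,
#' automatic-reply accounts).  Counting uses retained records only, so
#' [filter_comments()] should run first, matching the design in which
#' deleted content does not count toward eligibility.
#'
#' @param corpus list of `user_history` objects.
#' @param min_activity minimum retained interactions (default 100).
#' @param exclude_ids character vector of user ids to drop outright.
#' @return character vector of eligible user ids in deterministic
#'   (lexicographic) order.
#' @export
select_eligible_users <- function(corpus, min_activity = 100,
                                  exclude_ids = character(0)) {
  ids <- vapply(corpus, function(h) h$user_id, character(1))
  counts <- vapply(corpus, n_records, integer(1))
  keep <- counts >= min_activity & !(ids %in% exclude_ids)
  sort(unname(ids[keep]))
}

#' Assemble a filtered history into a paired sentiment series
#'
#' Applies a sentiment function to the comment and parent texts of each
#' retained record, yielding two equal-length chronological vectors (self
#' and peer sentiment) plus covariates: word count, health-word percentage,
#' timestamps, and tenure measured both as span (last minus first day,
#' the default regressor downstream) and as count of distinct active days.
#'
#' @param history a filtered `user_history`.
#' @param sentiment_fn function mapping a character vector to numeric
#'   sentiment scores (typically a corpus-standardized compound scorer, see
#'   [make_compound_scorer()]).
#' @param min_length minimum retained series length; shorter users raise an
#'   error flagged with the user id so callers can drop and log them.
#' @param health_lexicon health token set for the covariate.
#' @return an object of class `paired_series`: `user_id`, `self`, `peer`,
#'   `timestamps`, `word_count`, `health_pct`, `days_active_span`,
#'   `days_active_distinct`, `n`.
#' @export
to_paired_series <- function(history, sentiment_fn, min_length = 100,
                             health_lexicon = default_health_lexicon()) {
  stopifnot(inherits(history, "user_history"), is.function(sentiment_fn))
  d <- history$records
  if (nrow(d) < min_length) {
    stop(sprintf("to_paired_series: user '%s' has %d records, below the %d minimum",
                 history$user_id, nrow(d), min_length))
  }
  toks <- tokenize(d$comment_text)
  wc <- vapply(toks, length, integer(1))
  hp <- vapply(toks, function(t) {
    if (length(t) == 0L) return(NA_real_)
    100 * sum(t %in% health_lexicon) / length(t)
  }, numeric(1))
  span <- (max(d$timestamp) - min(d$timestamp)) / 86400
  distinct <- length(unique(floor(d$timestamp / 86400)))
  structure(
    list(user_id = history$user_id,
         self = as.numeric(sentiment_fn(d$comment_text)),
         peer = as.numeric(sentiment_fn(d$parent_text)),
         timestamps = d$timestamp,
         word_count = wc, health_pct = hp,
         days_active_span = span, days_active_distinct = distinct,
         n = nrow(d)),
    class = "paired_series"
  )
}

#' Build a corpus-standardized compound sentiment scorer
#'
#' Scores the supplied reference texts with both lexicon scorers, freezes
#' the corpus means and standard deviations, and returns a closure mapping
#' any character vector to compound scores standardized against that
#' reference corpus.  The reference should be all retained comment and
#' parent texts of all analyzed users.
#'
#' @param reference_texts character vector spanning the analyzed corpus.
#' @param lexicon_a,lexicon_b the two scorer lexicons.
#' @return a function `character -> numeric`, with the agreement statistics
#'   of the reference corpus attached as attribute `agreement`.
#' @export
make_compound_scorer <- function(reference_texts,
                                 lexicon_a = default_lexicon(),
                                 lexicon_b = default_posneg_lexicon()) {
  ref <- score_comments(reference_texts, lexicon_a, lexicon_b)
  ma <- mean(ref$raw_a); sa <- stats::sd(ref$raw_a)
  mb <- mean(ref$raw_b); sb <- stats::sd(ref$raw_b)
  if (sa == 0 || sb == 0) {
    stop("make_compound_scorer: a scorer is constant over the reference corpus")
  }
  f <- function(texts) {
    sc <- score_comments(texts, lexicon_a, lexicon_b)
    ((sc$raw_a - ma) / sa + (sc$raw_b - mb) / sb) / 2
  }
  attr(f, "agreement") <- scorer_agreement(ref$raw_a, ref$raw_b)
  f
}

#' Exclusion accounting for a processed corpus
#'
#' Retention bookkeeping: given total collected and excluded interaction
#' counts, returns the retained count and the retained/excluded
#' percentages.
#'
#' @param n_total total interactions collected.
#' @param n_excluded interactions excluded by the filters.
#' @return list with `retained`, `retention_pct`, `excluded_pct`.
#' @export
#' @examples
#' exclusion_accounting(73876, 5670)
exclusion_accounting <- function(n_total, n_excluded) {
  stopifnot(n_total > 0, n_excluded >= 0, n_excluded <= n_total)
  retained <- n_total - n_excluded
  list(retained = retained,
       retention_pct = 100 * retained / n_total,
       excluded_pct = 100 * n_excluded / n_total)
}

#' Tabulate exclusion logs across a corpus
#'
#' @param corpus list of `user_history` objects (after filtering).
#' @return data.frame with one row per user: retained, and counts per
#'   exclusion reason.
#' @export
exclusion_table <- function(corpus) {
  rows <- lapply(corpus, function(h) {
    log <- h$exclusion_log
    data.frame(user_id = h$user_id,
               retained = n_records(h),
               removed = sum(log$reason == "removed"),
               missing = sum(log$reason == "missing"),
               too_short = sum(log$reason == "too_short"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
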