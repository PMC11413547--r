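# Lexicon sentiment scoring.  Two pluggable scorers: a rule-based valence
# scorer with negation/booster handling and tanh-style normalization to
# [-1, 1] (scorer A), and a positive/negative word-ratio scorer on a
# -100..100 tone-like scale (scorer B).  Their z-standardized average is
# the compound score carried through the analysis.

#' Construct a valence lexicon
#'
#' @param entries named numeric vector, token -> valence (finite).
#' @param boosters named numeric vector, token -> intensity increment;
#'   negative increments are dampeners.
#' @param negators character vector of negating tokens.
#' @param name lexicon label.
#' @return an object of class `valence_lexicon`.
#' @export
valence_lexicon <- function(entries, boosters = numeric(0),
                            negators = character(0), name = "custom") {
  stopifnot(is.numeric(entries), !is.null(names(entries)))
  if (!all(is.finite(entries))) stop("valence_lexicon: non-finite valence")
  if (any(names(entries) %in% negators)) {
    stop("valence_lexicon: token appears in both entries and negators")
  }
  structure(list(entries = entries, boosters = boosters,
                 negators = unique(negators), name = name),
            class = "valence_lexicon")
}

#' Read a valence lexicon from tabular text files
#'
#' `path` must be a tab-separated file with columns `token` and `valence`
#' (or `polarity`).  Optional companion files supply boosters (`token`,
#' `increment`) and negators (one token per line).
#'
#' @param path lexicon TSV path.
#' @param boosters_path,negators_path optional companion files.
#' @param name lexicon label; defaults to the file name.
#' @return a [valence_lexicon()].
#' @export
read_lexicon <- function(path, boosters_path = NULL, negators_path = NULL,
                         name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  vcol <- intersect(c("valence", "polarity"), names(tab))[1]
  if (is.na(vcol) || !("token" %in% names(tab))) {
    stop("read_lexicon: need columns 'token' and 'valence'/'polarity'")
  }
  entries <- stats::setNames(as.numeric(tab[[vcol]]), tab$token)
  boosters <- numeric(0)
  if (!is.null(boosters_path)) {
    bt <- utils::read.delim(boosters_path, stringsAsFactors = FALSE)
    boosters <- stats::setNames(as.numeric(bt$increment), bt$token)
  }
  negators <- character(0)
  if (!is.null(negators_path)) {
    negators <- readLines(negators_path, warn = FALSE)
    negators <- negators[nzchar(negators)]
  }
  valence_lexicon(entries, boosters, negators, name)
}

lexicon_file <- function(f) {
  system.file("extdata", f, package = "sentsync", mustWork = TRUE)
}

#' Bundled default lexicons
#'
#' `default_lexicon()` is the bundled rule-based valence lexicon (scorer A):
#' graded valences on a -4..+4 scale with booster and negator lists.
#' `default_posneg_lexicon()` is the bundled binary positive/negative word
#' list behind the ratio scorer (scorer B).  `default_health_lexicon()` is a
#' small overridable set of health-related tokens for the health-language
#' covariate.
#'
#' @return a [valence_lexicon()], or a character vector for the health set.
#' @export
default_lexicon <- function() {
  read_lexicon(lexicon_file("valence_lexicon.tsv"),
               boosters_path = lexicon_file("boosters.tsv"),
               negators_path = lexicon_file("negators.txt"),
               name = "sentsync-valence")
}

#' @rdname default_lexicon
#' @export
default_posneg_lexicon <- function() {
  read_lexicon(lexicon_file("posneg_lexicon.tsv"), name = "sentsync-posneg")
}

#' @rdname default_lexicon
#' @export
default_health_lexicon <- function() {
  w <- readLines(lexicon_file("health_words.txt"), warn = FALSE)
  w[nzchar(w)]
}

#' Rule-based valence score of one text
#'
#' Sums matched token valences with contextual adjustments: a negator in the
#' three preceding tokens flips the valence and damps it by
#' `negation_factor`; boosters in the three preceding tokens add their
#' increment in the direction of the valence, attenuated with distance
#' (x0.95 at two tokens back, x0.90 at three).  The raw sum `s` is
#' compressed to `[-1, 1]` by `s / sqrt(s^2 + norm_const)`.  Text with no
#' lexicon matches scores 0.
#'
#' @param text a single string, non-empty after tokenization.
#' @param lexicon a [valence_lexicon()].
#' @param negation_factor signed damping factor applied on negation.
#' @param norm_const normalization constant (default 15).
#' @return score in `[-1, 1]`.
#' @export
#' @examples
#' lex <- default_lexicon()
#' lexicon_score("the advice was good", lex)
#' lexicon_score("the advice was not good", lex)
lexicon_score <- function(text, lexicon, negation_factor = -0.74,
                          norm_const = 15) {
  stopifnot(inherits(lexicon, "valence_lexicon"), length(text) == 1L)
  toks <- tokenize(text)[[1]]
  if (length(toks) == 0L) stop("lexicon_score: empty token stream")
  idx <- match(toks, names(lexicon$entries))
  total <- 0
  for (k in which(!is.na(idx))) {
    v <- unname(lexicon$entries[idx[k]])
    if (k > 1L) {
      dist_w <- c(1, 0.95, 0.90)
      prev <- rev(toks[max(1L, k - 3L):(k - 1L)]) # nearest first
      for (d in seq_along(prev)) {
        b <- lexicon$boosters[prev[d]]
        if (!is.na(b)) v <- v + sign(v) * unname(b) * dist_w[d]
      }
      if (any(prev %in% lexicon$negators)) v <- v * negation_factor
    }
    total <- total + v
  }
  total / sqrt(total^2 + norm_const)
}

#' Positive/negative word-ratio score of one text
#'
#' Scorer B: `100 * (pos - neg) / (pos + neg + 1)` where `pos` and `neg`
#' count matched positive- and negative-polarity tokens.  The -100..100
#' scale resembles summary tone variables of closed-dictionary tools; only
#' the standardized version enters the compound score, so the scale itself
#' carries no meaning downstream.
#'
#' @param text a single string, non-empty after tokenization.
#' @param lexicon a [valence_lexicon()]; entry signs define polarity.
#' @return score in `(-100, 100)`.
#' @export
ratio_score <- function(text, lexicon = default_posneg_lexicon()) {
  stopifnot(inherits(lexicon, "valence_lexicon"), length(text) == 1L)
  toks <- tokenize(text)[[1]]
  if (length(toks) == 0L) stop("ratio_score: empty token stream")
  v <- lexicon$entries[match(toks, names(lexicon$entries))]
  pos <- sum(v > 0, na.rm = TRUE)
  neg <- sum(v < 0, na.rm = TRUE)
  100 * (pos - neg) / (pos + neg + 1)
}

#' Percentage of health-related words in one text
#'
#' @param text a single string with at least one token.
#' @param health_lexicon character vector of health tokens.
#' @return percentage in `[0, 100]`.
#' @export
#' @examples
#' health_word_pct("the doctor increased my medication", default_health_lexicon())
health_word_pct <- function(text, health_lexicon = default_health_lexicon()) {
  toks <- tokenize(text)[[1]]
  if (length(toks) == 0L) stop("health_word_pct: zero tokens")
  100 * sum(toks %in% health_lexicon) / length(toks)
}

#' Compound sentiment score from two scorers
#'
#' Element-wise mean of the z-scored scorer outputs.  Standardization is
#' over the full vectors supplied, which should span all retained comments
#' of all analyzed users so user trajectories stay comparable.
#'
#' @param raw_a,raw_b numeric vectors of equal length (at least 2), each
#'   non-constant.
#' @return numeric vector of compound scores (mean approximately 0 over the
#'   standardization corpus).
#' @export
#' @examples
#' compound_score(c(1, 2, 3), c(10, 30, 20))
compound_score <- function(raw_a, raw_b) {
  if (length(raw_a) != length(raw_b)) stop("compound_score: length mismatch")
  if (length(raw_a) < 2L) stop("compound_score: need at least 2 values")
  sa <- stats::sd(raw_a)
  sb <- stats::sd(raw_b)
  if (sa == 0 || sb == 0) stop("compound_score: constant input vector")
  ((raw_a - mean(raw_a)) / sa + (raw_b - mean(raw_b)) / sb) / 2
}

#' Agreement between the two sentiment scorers
#'
#' Cronbach's alpha of the two-item scale formed by the z-scored scorer
#' outputs, plus their Pearson correlation.  For two standardized items
#' alpha reduces to `2 r / (1 + r)`.
#'
#' @param raw_a,raw_b numeric vectors of equal length (at least 3).
#' @return list with elements `alpha` and `r`.
#' @export
scorer_agreement <- function(raw_a, raw_b) {
  if (length(raw_a) != length(raw_b)) {
    stop("scorer_agreement: length mismatch")
  }
  if (length(raw_a) < 3L) stop("scorer_agreement: need at least 3 values")
  if (stats::sd(raw_a) == 0 || stats::sd(raw_b) == 0) {
    stop("scorer_agreement: zero variance")
  }
  za <- as.numeric(scale(raw_a))
  zb <- as.numeric(scale(raw_b))
  k <- 2
  alpha <- (k / (k - 1)) *
    (1 - (stats::var(za) + stats::var(zb)) / stats::var(za + zb))
  list(alpha = alpha, r = stats::cor(raw_a, raw_b))
}

#' Score a vector of comments with both scorers and covariates
#'
#' Batch convenience wrapper: runs [lexicon_score()], [ratio_score()],
#' [word_count()] and [health_word_pct()] over a character vector.
#'
#' @param texts character vector of non-empty comments.
#' @param lexicon_a scorer-A [valence_lexicon()].
#' @param lexicon_b scorer-B [valence_lexicon()].
#' @param health_lexicon character vector of health tokens.
#' @return data.frame with columns `raw_a`, `raw_b`, `word_count`,
#'   `health_pct`.
#' @export
score_comments <- function(texts, lexicon_a = default_lexicon(),
                           lexicon_b = default_posneg_lexicon(),
                           health_lexicon = default_health_lexicon()) {
  n <- length(texts)
  out <- data.frame(raw_a = numeric(n), raw_b = numeric(n),
                    word_count = integer(n), health_pct = numeric(n))
  for (i in seq_len(n)) {
    out$raw_a[i] <- lexicon_score(texts[i], lexicon_a)
    out$raw_b[i] <- ratio_score(texts[i], lexicon_b)
    toks <- tokenize(texts[i])[[1]]
    out$word_count[i] <- length(toks)
    out$health_pct[i] <- 100 * sum(toks %in% health_lexicon) / length(toks)
  }
  out
}
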