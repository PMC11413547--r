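#' @keywords internal
"_PACKAGE"

#' Derive a reproducible child seed
#'
#' Mixes a master seed with one or more integer keys (user index, stage id,
#' replicate number, ...) into a new seed in `[1, 2^31 - 2]`.  Used
#' throughout so that a single master seed deterministically drives every
#' source of randomness in a run, and regenerating one user does not disturb
#' the streams of the others.
#'
#' @param seed master seed (integer-valued scalar).
#' @param ... integer keys mixed into the seed in order.
#' @return a single integer seed.
#' @export
#' @examples
#' derive_seed(1, 5)
#' derive_seed(1, 5, 2)
derive_seed <- function(seed, ...) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime used by Lehmer generators
  h <- (abs(as.numeric(seed)) %% m)
  for (k in c(...)) {
    stopifnot(is.finite(k))
    h <- (h * 48271 + abs(as.numeric(k)) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Tokenize comment text
#'
#' Lower-cases, strips URLs and non-ASCII symbols (emoji and the like), then
#' splits on whitespace.  This is the tokenizer behind the minimum-word-count
#' eligibility rule, the lexicon scorers, and the health-language covariate,
#' so all of them agree on what counts as a word.
#'
#' @param text character vector.
#' @return a list of character vectors, one per input element.
#' @export
#' @examples
#' tokenize("Check https://example.org -- GOOD advice!")
tokenize <- function(text) {
  text <- ifelse(is.na(text), "", text)
  text <- tolower(text)
  text <- gsub("(https?://|www\\.)\\S+", " ", text)
  text <- iconv(text, to = "ASCII", sub = " ")
  # keep apostrophes inside words ("don't"), drop other punctuation
  text <- gsub("[^a-z0-9' ]", " ", text)
  text <- gsub("'{2,}", " ", text)
  toks <- strsplit(trimws(gsub("\\s+", " ", text)), " ", fixed = TRUE)
  lapply(toks, function(t) t[nzchar(t) & t != "'"])
}

#' Count words in comment text
#'
#' @param text character vector.
#' @return integer vector of token counts.
#' @export
word_count <- function(text) {
  vapply(tokenize(text), length, integer(1))
}

#' Circular mean of angles in degrees
#'
#' Resultant-vector mean direction, the standard first trigonometric moment
#' of directional statistics.  Returns `NA` for empty input.
#'
#' @param deg numeric vector of angles in degrees.
#' @return mean direction in degrees, wrapped to `(-180, 180]`.
#' @export
#' @examples
#' circ_mean_deg(c(170, -170)) # 180, not 0
circ_mean_deg <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0L) return(NA_real_)
  rad <- deg * pi / 180
  ang <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Absolute circular distance between angles in degrees
#'
#' @param a,b numeric vectors of angles in degrees (recycled).
#' @return element-wise distance in `[0, 180]`.
#' @export
#' @examples
#' circ_dist_deg(170, -170) # 20
circ_dist_deg <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
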