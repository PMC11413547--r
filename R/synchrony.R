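# Per-user synchrony statistics reduced from cross-wavelet spectra, the
# shuffled permutation baseline, and the group-level tests (paired t with
# effect sizes, repeated-measures band ANOVA, Pearson-vs-wavelet
# correlations).

#' Frequency-band definition
#'
#' Default analysis bands in interaction units: low-frequency fluctuations
#' unfolding over 20 to 32 interactions (closed interval), medium over 10
#' to 20 (right-open), and high under 10 interactions.
#'
#' @param low,medium,high numeric `(min, max)` period intervals.
#' @return object of class `band_definition`.
#' @export
default_bands <- function(low = c(20, 32), medium = c(10, 20),
                          high = c(0, 10)) {
  structure(list(low = low, medium = medium, high = high),
            class = "band_definition")
}

# points at periods inside the cone of influence
reliable_mask <- function(cross) {
  outer(cross$grid$periods, cross$coi, "<")
}

band_rows <- function(grid, band, interval) {
  p <- grid$periods
  if (identical(band, "low")) {
    which(p >= interval[1] & p <= interval[2]) # closed on stated endpoints
  } else {
    which(p >= interval[1] & p < interval[2])
  }
}

frac_of_mask <- function(sig, reliable) {
  m <- sum(reliable)
  if (m == 0L) stop("synchrony: no reliable (inside-coi) points")
  sum(sig & reliable) / m
}

#' Fraction of the cross-wavelet plot with significant common power
#'
#' Significant points divided by total points, counting only points at
#' periods inside the cone of influence.
#'
#' @param cross a `cross_spectrum` with `sig_power` filled in (see
#'   [xwt_significance()]).
#' @return fraction in `[0, 1]`.
#' @export
common_power_fraction <- function(cross) {
  stopifnot(inherits(cross, "cross_spectrum"))
  if (is.null(cross$sig_power)) stop("common_power_fraction: no sig_power mask")
  frac_of_mask(cross$sig_power, reliable_mask(cross))
}

#' Fraction of the coherence plot with significant coherence
#'
#' @param cross a `cross_spectrum` with `sig_coherence` filled in.
#' @return fraction in `[0, 1]`.
#' @export
coherence_fraction <- function(cross) {
  stopifnot(inherits(cross, "cross_spectrum"))
  if (is.null(cross$sig_coherence)) {
    stop("coherence_fraction: no sig_coherence mask")
  }
  frac_of_mask(cross$sig_coherence, reliable_mask(cross))
}

#' Mean circular relative-phase angle over significant common power
#'
#' Unweighted circular mean (atan2 of averaged unit phase vectors) of the
#' cross-spectrum phase over points that are significant and inside the
#' cone of influence, in degrees.  Returns `NA` when no point qualifies.
#'
#' @param cross a `cross_spectrum` with `sig_power` filled in.
#' @param mask optional logical matrix replacing `sig_power & reliable`.
#' @return angle in degrees, `(-180, 180]`, or `NA`.
#' @export
mean_rp_angle <- function(cross, mask = NULL) {
  stopifnot(inherits(cross, "cross_spectrum"))
  if (is.null(mask)) {
    if (is.null(cross$sig_power)) stop("mean_rp_angle: no sig_power mask")
    mask <- cross$sig_power & reliable_mask(cross)
  }
  ph <- cross$phase[mask]
  if (length(ph) == 0L) return(NA_real_)
  circ_mean_deg(ph * 180 / pi)
}

#' Per-band synchrony fractions
#'
#' Computes the inside-coi significant fraction of a mask within each
#' frequency band's period rows, plus the per-band circular mean relative
#' phase.
#'
#' @param cross a `cross_spectrum` with significance masks filled in.
#' @param bands a [default_bands()] definition.
#' @param which_mask `"power"` or `"coherence"`.
#' @return named numeric vector `c(low=, medium=, high=)`, with per-band RP
#'   angles attached as attribute `rp` when `which_mask = "power"`.
#' @export
band_fractions <- function(cross, bands = default_bands(),
                           which_mask = c("power", "coherence")) {
  which_mask <- match.arg(which_mask)
  sig <- if (which_mask == "power") cross$sig_power else cross$sig_coherence
  if (is.null(sig)) stop("band_fractions: significance mask not filled in")
  reliable <- reliable_mask(cross)
  out <- numeric(0)
  rp <- numeric(0)
  for (b in names(bands)) {
    rows <- band_rows(cross$grid, b, bands[[b]])
    if (length(rows) == 0L) {
      stop(sprintf("band_fractions: no grid rows in band '%s'", b))
    }
    rel_b <- reliable[rows, , drop = FALSE]
    sig_b <- sig[rows, , drop = FALSE]
    out[b] <- if (sum(rel_b) == 0L) NA_real_ else sum(sig_b & rel_b) / sum(rel_b)
    if (which_mask == "power") {
      ph <- cross$phase[rows, , drop = FALSE][sig_b & rel_b]
      rp[b] <- if (length(ph)) circ_mean_deg(ph * 180 / pi) else NA_real_
    }
  }
  if (which_mask == "power") attr(out, "rp") <- rp
  out
}

# accept paired_series, simulated_user, or a plain list(self, peer)
get_pair <- function(x) {
  if (inherits(x, "paired_series")) {
    list(self = x$self, peer = x$peer)
  } else if (inherits(x, "simulated_user")) {
    list(self = x$self_sentiment, peer = x$peer_sentiment)
  } else if (is.list(x) && !is.null(x$self) && !is.null(x$peer)) {
    list(self = as.numeric(x$self), peer = as.numeric(x$peer))
  } else {
    stop("expected a paired_series, simulated_user, or list(self, peer)")
  }
}

#' Full per-user synchrony analysis
#'
#' Runs the complete pipeline on one paired series: percentile transform of
#' both streams, Morlet CWT, cross-wavelet transform with AR(1) red-noise
#' significance, wavelet coherence with Monte Carlo significance, and the
#' per-user summary metrics (whole-plot and per-band fractions, circular
#' relative phase, Pearson correlation).
#'
#' @param pair a `paired_series`, `simulated_user`, or `list(self, peer)`.
#' @param alpha significance level (default 0.05).
#' @param wtc_sig coherence significance: `"mc"` (Monte Carlo critical
#'   values, the production path), `"none"` (skip coherence significance,
#'   for power-only analyses), or a precomputed per-scale critical vector
#'   from [wtc_significance_mc()] on a matching grid.
#' @param nsim Monte Carlo initializations when `wtc_sig = "mc"` (2000 for
#'   production, smaller for desk-scale runs).
#' @param seed RNG seed for the Monte Carlo step.
#' @param bands band definition for per-band metrics.
#' @param grid optional [wavelet_grid()]; defaults to the grid for the
#'   series length.
#' @return list with elements `cross` (the annotated `cross_spectrum`) and
#'   `metrics` (class `synchrony_metrics`): `common_power_frac`,
#'   `coherence_frac`, `rp_angle_deg`, `band_common_power`,
#'   `band_coherence`, `band_rp`, `pearson_r`, `n`.
#' @export
analyze_pair <- function(pair, alpha = 0.05, wtc_sig = "mc", nsim = 2000,
                         seed = 1, bands = default_bands(), grid = NULL) {
  p <- get_pair(pair)
  n <- length(p$self)
  stopifnot(n == length(p$peer), n >= 16)
  u <- percentile_transform(p$self)
  v <- percentile_transform(p$peer)
  if (is.null(grid)) grid <- wavelet_grid(n)
  wa <- morlet_cwt(u, grid)
  wb <- morlet_cwt(v, grid)
  cross <- xwt(wa, wb)
  cross <- xwt_significance(cross, estimate_ar1(u), estimate_ar1(v), alpha)
  do_coh <- !identical(wtc_sig, "none")
  if (do_coh) {
    cross$coherence <- wtc(wa, wb)
    crit <- if (is.numeric(wtc_sig)) {
      wtc_sig
    } else {
      wtc_significance_mc(estimate_ar1(u), estimate_ar1(v), n, grid,
                          nsim = nsim, alpha = alpha, seed = seed)
    }
    stopifnot(length(crit) == length(grid$scales))
    cross$coherence_crit <- crit
    cm <- matrix(ifelse(is.na(crit), Inf, crit), length(crit), n)
    cross$sig_coherence <- cross$coherence > cm
  }
  bf_p <- band_fractions(cross, bands, "power")
  metrics <- structure(list(
    common_power_frac = common_power_fraction(cross),
    coherence_frac = if (do_coh) coherence_fraction(cross) else NA_real_,
    rp_angle_deg = mean_rp_angle(cross),
    band_common_power = as.numeric(bf_p),
    band_coherence = if (do_coh) as.numeric(band_fractions(cross, bands,
                                                           "coherence"))
                     else rep(NA_real_, length(bands)),
    band_rp = as.numeric(attr(bf_p, "rp")),
    pearson_r = stats::cor(p$self, p$peer),
    n = n
  ), class = "synchrony_metrics")
  names(metrics$band_common_power) <- names(bands)
  names(metrics$band_coherence) <- names(bands)
  names(metrics$band_rp) <- names(bands)
  list(cross = cross, metrics = metrics)
}

#' Shuffled-baseline synchrony metrics
#'
#' Runs the identical pipeline ([analyze_pair()]) on an order-destroyed
#' version of the paired observations.  The default strategy permutes the
#' user's self series while leaving the peer series in chronological order,
#' which destroys alignment while preserving both marginal distributions;
#' `"both"` permutes the two series independently.
#'
#' @param pair as in [analyze_pair()].
#' @param seed RNG seed for the permutation (and the Monte Carlo step).
#' @param strategy `"self"` or `"both"`.
#' @param ... passed to [analyze_pair()].
#' @return the shuffled-data result of [analyze_pair()].
#' @export
shuffled_baseline <- function(pair, seed, strategy = c("self", "both"), ...) {
  strategy <- match.arg(strategy)
  p <- get_pair(pair)
  n <- length(p$self)
  sh <- with_seed(seed, {
    s <- p$self[sample.int(n)]
    q <- if (strategy == "both") p$peer[sample.int(n)] else p$peer
    list(self = s, peer = q)
  })
  analyze_pair(sh, seed = derive_seed(seed, 101), ...)
}

#' Paired t test of real versus shuffled synchrony
#'
#' Two-tailed paired t test with both common effect-size conventions: `d_av`
#' (mean difference over the average of the two standard deviations) and
#' `d_z` (mean difference over the standard deviation of the differences).
#'
#' @param real,shuffled numeric metric vectors of equal length (>= 3),
#'   paired by user.
#' @return list with `t`, `df`, `p`, `d_av`, `d_z`, `mean_real`,
#'   `mean_shuffled`.
#' @export
paired_synchrony_test <- function(real, shuffled) {
  if (length(real) != length(shuffled)) {
    stop("paired_synchrony_test: length mismatch")
  }
  ok <- is.finite(real) & is.finite(shuffled)
  real <- real[ok]; shuffled <- shuffled[ok]
  n <- length(real)
  if (n < 3L) stop("paired_synchrony_test: need at least 3 complete pairs")
  d <- real - shuffled
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (all(d == 0)) {
      # identical vectors: no evidence of any difference
      return(list(t = 0, df = n - 1L, p = 1, d_av = 0, d_z = 0,
                  mean_real = mean(real), mean_shuffled = mean(shuffled)))
    }
    stop("paired_synchrony_test: zero variance of differences")
  }
  tval <- mean(d) / (sdd / sqrt(n))
  list(t = tval, df = n - 1L, p = 2 * stats::pt(-abs(tval), n - 1),
       d_av = mean(d) / ((stats::sd(real) + stats::sd(shuffled)) / 2),
       d_z = mean(d) / sdd,
       mean_real = mean(real), mean_shuffled = mean(shuffled))
}

#' One-way repeated-measures ANOVA across frequency bands
#'
#' Within-subject decomposition: `F = MS_band / MS_error` with
#' `df = (k - 1, (k - 1)(n - 1))` after removing the subject stratum,
#' followed by pairwise paired t tests between bands.  Conventional
#' repeated-measures error degrees of freedom are reported (see the
#' `df_note` element).
#'
#' @param metrics numeric matrix or data.frame, users x bands, complete
#'   cases only.
#' @return list with `F`, `df1`, `df2`, `p`, `pairwise` (data.frame of
#'   paired t results per band pair), `band_means`, and `df_note`.
#' @export
band_anova <- function(metrics) {
  m <- as.matrix(metrics)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("band_anova: need at least 2 bands")
  if (n < 3L) stop("band_anova: need at least 3 subjects")
  if (is.null(colnames(m))) colnames(m) <- paste0("band", seq_len(k))
  grand <- mean(m)
  ss_band <- n * sum((colMeans(m) - grand)^2)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_band - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  ms_band <- ss_band / df1
  ms_err <- ss_err / df2
  Fval <- if (ms_err == 0) 0 else ms_band / ms_err
  pairs <- utils::combn(colnames(m), 2)
  pw <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    tt <- paired_synchrony_test(m[, a], m[, b])
    data.frame(band_a = a, band_b = b, t = tt$t, df = tt$df, p = tt$p,
               stringsAsFactors = FALSE)
  })
  list(F = Fval, df1 = df1, df2 = df2,
       p = stats::pf(Fval, df1, df2, lower.tail = FALSE),
       pairwise = do.call(rbind, pw),
       band_means = colMeans(m),
       df_note = "conventional repeated-measures df: (k-1, (k-1)(n-1))")
}

#' Correlations between Pearson and wavelet synchrony metrics
#'
#' Pairwise Pearson correlations (with two-sided p values) between the
#' per-user metric columns, using listwise deletion of incomplete rows.
#'
#' @param metrics data.frame or matrix of aligned per-user metric columns
#'   (e.g. pearson_r, coherence, coherence_shuffled, common_power,
#'   common_power_shuffled).
#' @return list with matrices `r` and `p`, and the post-deletion `n`.
#' @export
correlate_metrics <- function(metrics) {
  m <- as.matrix(metrics)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3L) stop("correlate_metrics: fewer than 3 complete cases")
  k <- ncol(m)
  r <- stats::cor(m)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) {
        p[i, j] <- stats::cor.test(m[, i], m[, j])$p.value
      }
    }
  }
  list(r = r, p = p, n = n)
}
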