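# Interaction-window transform and the mixed-effects growth-curve model of
# windowed sentiment: window index as the fixed growth term, per-user random
# intercepts, synchrony / tenure / language covariates, and the two- and
# three-way moderation terms, with variance components, ICC and
# marginal/conditional R-squared.

#' Proportional interaction-window means
#'
#' Partitions a chronological series into `n_windows` contiguous,
#' near-equal segments (when the length is not divisible, the earliest
#' windows receive the extra observations) and returns each segment's mean.
#' The segment-size-weighted mean of the output equals the series mean
#' exactly.
#'
#' @param x numeric vector with `length(x) >= n_windows`.
#' @param n_windows number of windows (default 100, i.e. each window is 1%
#'   of the user's activity).
#' @return numeric vector of `n_windows` window means, with the segment
#'   sizes attached as attribute `sizes`.
#' @export
#' @examples
#' window_transform(1:10, 4)
window_transform <- function(x, n_windows = 100) {
  n <- length(x)
  if (n_windows < 1L) stop("window_transform: n_windows must be >= 1")
  if (n < n_windows) {
    stop(sprintf("window_transform: series length %d below n_windows = %d",
                 n, n_windows))
  }
  base <- n %/% n_windows
  extra <- n %% n_windows
  sizes <- rep.int(base, n_windows)
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  idx <- rep.int(seq_len(n_windows), sizes)
  out <- as.numeric(tapply(x, idx, mean))
  attr(out, "sizes") <- sizes
  out
}

#' Build the windowed analysis table for the growth model
#'
#' One row per user per window: windowed mean sentiment, window index, and
#' the per-user covariates (common-power synchrony estimate, days active,
#' mean word count, mean health-word percentage).
#'
#' @param series list of `paired_series` objects.
#' @param common_power numeric vector of per-user common-power fractions,
#'   aligned with `series`.
#' @param n_windows windows per user (default 100).
#' @param days_active `"span"` (last minus first day; default) or
#'   `"distinct"` (count of distinct active days).
#' @return data.frame with columns `user_id`, `window`, `sentiment`,
#'   `common_power`, `days_active`, `word_count`, `health_pct`.
#' @export
windowed_table <- function(series, common_power, n_windows = 100,
                           days_active = c("span", "distinct")) {
  days_active <- match.arg(days_active)
  stopifnot(length(series) == length(common_power))
  rows <- vector("list", length(series))
  for (i in seq_along(series)) {
    s <- series[[i]]
    w <- window_transform(series_self(s), n_windows)
    da <- if (days_active == "span") s$days_active_span
          else s$days_active_distinct
    if (is.null(da)) da <- s$days_active # simulated users carry a scalar
    rows[[i]] <- data.frame(
      user_id = s$user_id, window = seq_len(n_windows), sentiment = w,
      common_power = common_power[i], days_active = da,
      word_count = mean(s$word_count %||% NA_real_),
      health_pct = mean(s$health_pct %||% NA_real_),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zscore: constant or non-finite column")
  (x - mean(x)) / s
}

#' Fit the mixed-effects growth-curve model of windowed sentiment
#'
#' Fits `sentiment ~ window * common_power * days_active + health_pct +
#' word_count + (1 | user_id)` with all continuous variables z-scored over
#' the analysis table, so coefficients are standardized betas.  Reports
#' Wald 95% confidence intervals, Satterthwaite p values, the variance
#' components (residual `sigma2`, random-intercept `tau00`), the intraclass
#' correlation `tau00 / (tau00 + sigma2)`, and marginal / conditional
#' R-squared under the standard variance-partition definition for
#' random-intercept models (fixed-effects variance over total, and fixed
#' plus random over total).
#'
#' @param data a [windowed_table()] (columns `user_id`, `window`,
#'   `sentiment`, `common_power`, `days_active`, `word_count`,
#'   `health_pct`).  Covariate columns that are constant across the table
#'   are dropped from the model with a message.
#' @param conf_level confidence level for the Wald intervals.
#' @param p_method `"satterthwaite"` (default) for Satterthwaite
#'   denominator degrees of freedom, or `"wald"` for normal-approximation
#'   p values (much faster; appropriate for large simulation studies).
#' @return an object of class `growth_fit`: `coefficients` (data.frame with
#'   `term`, `beta`, `ci_low`, `ci_high`, `p`), `sigma2`, `tau00`, `icc`,
#'   `r2_marginal`, `r2_conditional`, `n_users`, `n_obs`, and the fitted
#'   `model`.
#' @export
fit_growth_model <- function(data, conf_level = 0.95,
                             p_method = c("satterthwaite", "wald")) {
  p_method <- match.arg(p_method)
  needed <- c("user_id", "window", "sentiment")
  if (!all(needed %in% names(data))) {
    stop("fit_growth_model: missing required columns")
  }
  if (length(unique(data$user_id)) < 2L) {
    stop("fit_growth_model: need at least 2 users")
  }
  d <- data.frame(user_id = factor(data$user_id))
  d$sentiment <- zscore(data$sentiment)
  d$window <- zscore(data$window)
  covars <- c("common_power", "days_active", "health_pct", "word_count")
  keep <- character(0)
  for (v in covars) {
    if (!is.null(data[[v]]) && stats::sd(data[[v]]) > 0 &&
        all(is.finite(data[[v]]))) {
      d[[v]] <- zscore(data[[v]])
      keep <- c(keep, v)
    } else {
      message("fit_growth_model: dropping constant/absent covariate ", v)
    }
  }
  rhs <- "window"
  if (all(c("common_power", "days_active") %in% keep)) {
    rhs <- "window * common_power * days_active"
  } else if ("common_power" %in% keep) {
    rhs <- "window * common_power"
  } else if ("days_active" %in% keep) {
    rhs <- "window * days_active"
  }
  extra <- setdiff(keep, c("common_power", "days_active"))
  form <- stats::as.formula(paste(
    "sentiment ~", paste(c(rhs, extra), collapse = " + "), "+ (1 | user_id)"
  ))
  ctrl <- lme4::lmerControl(check.conv.singular =
                              lme4::.makeCC(action = "message", tol = 1e-4))
  fit <- tryCatch(
    if (p_method == "satterthwaite") {
      lmerTest::lmer(form, data = d, control = ctrl)
    } else {
      lme4::lmer(form, data = d, control = ctrl)
    },
    error = function(e) stop("fit_growth_model: model did not converge: ",
                             conditionMessage(e))
  )
  sm <- summary(fit)
  co <- sm$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  pcol <- if ("Pr(>|t|)" %in% colnames(co)) co[, "Pr(>|t|)"]
          else 2 * stats::pnorm(-abs(co[, "Estimate"] / co[, "Std. Error"]))
  coefs <- data.frame(
    term = rownames(co),
    beta = co[, "Estimate"],
    ci_low = co[, "Estimate"] - z * co[, "Std. Error"],
    ci_high = co[, "Estimate"] + z * co[, "Std. Error"],
    p = pcol,
    row.names = NULL, stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau00 <- vc$vcov[vc$grp == "user_id"][1]
  sigma2 <- vc$vcov[vc$grp == "Residual"][1]
  X <- stats::model.matrix(fit)
  var_f <- stats::var(as.numeric(X %*% lme4::fixef(fit)))
  total <- var_f + tau00 + sigma2
  structure(
    list(coefficients = coefs, sigma2 = sigma2, tau00 = tau00,
         icc = tau00 / (tau00 + sigma2),
         r2_marginal = var_f / total,
         r2_conditional = (var_f + tau00) / total,
         n_users = length(unique(d$user_id)), n_obs = nrow(d),
         model = fit),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, digits = 3, ...) {
  cat("Mixed-effects growth-curve fit\n")
  cat(sprintf("  users: %d   observations: %d\n", x$n_users, x$n_obs))
  co <- x$coefficients
  co$beta <- round(co$beta, digits)
  co$ci_low <- round(co$ci_low, digits)
  co$ci_high <- round(co$ci_high, digits)
  co$p <- signif(co$p, 2)
  print(co, row.names = FALSE)
  cat(sprintf("  sigma2 = %.3f  tau00 = %.3f  ICC = %.3f\n",
              x$sigma2, x$tau00, x$icc))
  cat(sprintf("  marginal R2 = %.3f  conditional R2 = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

growth_coef <- function(fit, term) {
  co <- fit$coefficients
  i <- match(term, co$term)
  if (is.na(i)) 0 else co$beta[i]
}

#' Model-implied sentiment-versus-window slopes over a moderator grid
#'
#' Evaluates the fitted model's sentiment-per-window slope (in standardized
#' units) at grid points of the two moderators, common power and days
#' active: `slope = b_w + b_wc * cp + b_wd * days + b_wcd * cp * days`.
#' Grid points beyond +/-3 SD are flagged as extrapolation.
#'
#' @param fit a [fit_growth_model()] result.
#' @param common_power,days_active numeric grids in SD units (defaults
#'   +/-1).
#' @return data.frame with `common_power`, `days_active`, `slope`,
#'   `extrapolated`.
#' @export
interaction_surface <- function(fit, common_power = c(-1, 1),
                                days_active = c(-1, 1)) {
  stopifnot(inherits(fit, "growth_fit"))
  g <- expand.grid(common_power = common_power, days_active = days_active)
  b_w <- growth_coef(fit, "window")
  b_wc <- growth_coef(fit, "window:common_power")
  b_wd <- growth_coef(fit, "window:days_active")
  b_wcd <- growth_coef(fit, "window:common_power:days_active")
  g$slope <- b_w + b_wc * g$common_power + b_wd * g$days_active +
    b_wcd * g$common_power * g$days_active
  g$extrapolated <- abs(g$common_power) > 3 | abs(g$days_active) > 3
  g
}

#' Simulate a windowed analysis table from known growth-model parameters
#'
#' Generates data directly from the random-intercept growth model:
#' standard-normal per-user covariates, z-scored window index, fixed
#' effects from `beta`, per-user intercepts with variance `tau00`, and
#' residuals with variance `sigma2`.  Used for parameter-recovery and
#' coverage checks of [fit_growth_model()].
#'
#' @param n_users,n_windows table dimensions.
#' @param beta named vector of standardized fixed effects; recognized names
#'   are `window`, `common_power`, `days_active`, `health_pct`,
#'   `word_count`, `window:common_power`, `window:days_active`,
#'   `common_power:days_active`, `window:common_power:days_active`.
#'   Omitted terms are zero.
#' @param tau00 random-intercept variance.
#' @param sigma2 residual variance.
#' @param seed RNG seed.
#' @return a data.frame shaped like [windowed_table()].
#' @export
simulate_growth_data <- function(n_users = 199, n_windows = 100,
                                 beta = c(window = -0.02), tau00 = 0.07,
                                 sigma2 = 0.88, seed = 1) {
  b <- function(nm) if (nm %in% names(beta)) unname(beta[nm]) else 0
  with_seed(seed, {
    w <- as.numeric(scale(seq_len(n_windows)))
    rows <- vector("list", n_users)
    for (i in seq_len(n_users)) {
      cp <- stats::rnorm(1); da <- stats::rnorm(1)
      hp <- stats::rnorm(1); wc <- stats::rnorm(1)
      u0 <- stats::rnorm(1, sd = sqrt(tau00))
      mu <- b("window") * w + b("common_power") * cp + b("days_active") * da +
        b("health_pct") * hp + b("word_count") * wc +
        b("window:common_power") * w * cp + b("window:days_active") * w * da +
        b("common_power:days_active") * cp * da +
        b("window:common_power:days_active") * w * cp * da
      y <- mu + u0 + stats::rnorm(n_windows, sd = sqrt(sigma2))
      rows[[i]] <- data.frame(
        user_id = sprintf("user%04d", i), window = seq_len(n_windows),
        sentiment = y, common_power = cp, days_active = da,
        health_pct = hp, word_count = wc, stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
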