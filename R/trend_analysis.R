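#' Fit a log-linear trend to CSTD
#'
#' Ordinary least squares of the natural log of concentration on sampling
#' year. A negative slope yields an apparent CSTD halving time
#' `ln(2)/|slope|`; a positive slope a CSTD doubling time. These are
#' properties of the sampled population and calendar window, not of the
#' chemical's elimination: the apparent halving time equals the intake
#' halving time only under conditions the [recommendations()] engine
#' checks, and it never equals the intrinsic elimination half-life.
#'
#' Replicate records sharing a sampling year are first collapsed to their
#' geometric mean (the exponential-fit convention in the monitoring
#' literature); optionally records are weighted by sample size `n`.
#'
#' @param series A [cstd_series()].
#' @param window Optional length-2 year window restricting the fit.
#' @param weight_by_n Weight records by their `n` column (default FALSE).
#' @param pool_years Collapse replicate years to geometric means before
#'   fitting (default TRUE).
#' @param periods Optional [classify_periods()] labels for the same
#'   series; fits whose window touches the transition period then carry a
#'   validity warning in the returned object.
#' @param slope_epsilon Absolute slopes below this (1/year) are reported
#'   as an infinite half-life/doubling time.
#' @return Object of class `cstd_trend` with components `slope` (1/year,
#'   natural-log scale), `intercept`, `half_life_or_doubling` (years),
#'   `direction` (`"halving"` or `"doubling"`), `se_slope`, `r_squared`,
#'   `n_points`, `window`, `warnings`, and the underlying `lm` fit.
#' @examples
#' s <- cstd_series(2000:2010, 30, 100 * 2^(-(2000:2010 - 2000) / 5))
#' fit <- fit_loglinear(s)
#' summary(fit)
#' @export
fit_loglinear <- function(series, window = NULL, weight_by_n = FALSE,
                          pool_years = TRUE, periods = NULL,
                          slope_epsilon = 1e-10) {
  stopifnot(inherits(series, "cstd_series"))
  d <- as.data.frame(series)
  if (!is.null(window)) {
    stopifnot(length(window) == 2)
    d <- d[d$year >= window[1] & d$year <= window[2], , drop = FALSE]
  }
  bad <- !is.finite(d$conc) | d$conc <= 0
  if (any(bad)) {
    warning(sprintf("%d record(s) with non-positive concentration rejected",
                    sum(bad)))
    d <- d[!bad, , drop = FALSE]
  }
  if (nrow(d) < 2) stop("need at least 2 positive-concentration records to fit")
  if (pool_years && anyDuplicated(d$year)) {
    w <- if (weight_by_n) ifelse(is.na(d$n), 1, d$n) else rep(1, nrow(d))
    agg <- lapply(split(seq_len(nrow(d)), d$year), function(ii) {
      c(year = d$year[ii[1]],
        lc = stats::weighted.mean(log(d$conc[ii]), w[ii]),
        n = sum(w[ii]))
    })
    agg <- do.call(rbind, agg)
    d <- data.frame(year = agg[, "year"], lc = agg[, "lc"], n = agg[, "n"])
  } else {
    d <- data.frame(year = d$year, lc = log(d$conc),
                    n = ifelse(is.na(d$n), 1, d$n))
  }
  fit <- if (weight_by_n) stats::lm(lc ~ year, data = d, weights = d$n)
         else stats::lm(lc ~ year, data = d)
  co <- stats::coef(fit)
  # noise-free model curves are a routine input; the resulting
  # "essentially perfect fit" warning from summary.lm is expected
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  slope <- unname(co["year"])
  hl <- if (abs(slope) < slope_epsilon) Inf else log(2) / abs(slope)
  warns <- character(0)
  if (!is.null(periods)) {
    stopifnot(inherits(periods, "period_labels"))
    lab <- periods$label[match(round(d$year, 9), round(periods$year, 9))]
    if (any(lab == "transition", na.rm = TRUE))
      warns <- c(warns, paste(
        "fit window includes transition-period records:",
        "an apparent halving/doubling time fitted there is not interpretable"))
  }
  structure(
    list(slope = slope,
         intercept = unname(co["(Intercept)"]),
         half_life_or_doubling = hl,
         direction = if (slope < 0) "halving" else "doubling",
         se_slope = unname(sm$coefficients["year", "Std. Error"]),
         r_squared = sm$r.squared,
         n_points = nrow(d),
         window = range(d$year),
         warnings = warns,
         lm = fit),
    class = "cstd_trend"
  )
}

#' @export
print.cstd_trend <- function(x, ...) {
  cat(sprintf("Log-linear CSTD trend over %.4f-%.4f (%d points)\n",
              x$window[1], x$window[2], x$n_points))
  cat(sprintf("  slope %.5g /y  ->  apparent CSTD %s time %.4g y  (R^2 = %.4f)\n",
              x$slope, x$direction, x$half_life_or_doubling, x$r_squared))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
summary.cstd_trend <- function(object, ...) {
  out <- list(
    slope = object$slope,
    se_slope = object$se_slope,
    intercept = object$intercept,
    r_squared = object$r_squared,
    n_points = object$n_points,
    window = object$window,
    direction = object$direction,
    t_half_cstd = if (object$direction == "halving")
      object$half_life_or_doubling else NA_real_,
    t_double_cstd = if (object$direction == "doubling")
      object$half_life_or_doubling else NA_real_,
    warnings = object$warnings)
  class(out) <- "summary.cstd_trend"
  out
}

#' @export
print.summary.cstd_trend <- function(x, ...) {
  cat("Apparent CSTD trend (log-linear fit)\n")
  cat(sprintf("  window        : %.4f-%.4f (%d points)\n",
              x$window[1], x$window[2], x$n_points))
  cat(sprintf("  slope (ln/y)  : %.5g (SE %.3g)\n", x$slope, x$se_slope))
  if (x$direction == "halving")
    cat(sprintf("  CSTD halving time : %.4g y\n", x$t_half_cstd))
  else
    cat(sprintf("  CSTD doubling time: %.4g y\n", x$t_double_cstd))
  cat(sprintf("  R^2           : %.4f\n", x$r_squared))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
coef.cstd_trend <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.cstd_trend <- function(object, year, ...) {
  if (missing(year)) return(exp(stats::fitted(object$lm)))
  exp(object$intercept + object$slope * year)
}

#' @export
residuals.cstd_trend <- function(object, ...) stats::residuals(object$lm)

#' @export
plot.cstd_trend <- function(x, ...) {
  d <- stats::model.frame(x$lm)
  graphics::plot(d$year, exp(d$lc), log = "y", xlab = "year",
                 ylab = "concentration (ng/g lipid)", ...)
  yy <- seq(min(d$year), max(d$year), length.out = 100)
  graphics::lines(yy, predict(x, yy), col = 2)
  invisible(x)
}

#' Label CSTD records as pre-ban, transition or post-ban
#'
#' Records before the ban year are pre-ban; the transition period starts
#' at the ban and lasts `max(min_transition, transition_factor *
#' t_half_elim)` years when the elimination half-life is known (slow
#' eliminators flatten out for longer), otherwise `min_transition` years
#' with an explicit caveat that the elimination half-life is unknown;
#' everything later is post-ban.
#'
#' @param series A [cstd_series()].
#' @param ban_year Year of the ban/phaseout.
#' @param t_half_elim Elimination half-life in years, or NULL if unknown.
#' @param min_transition Minimum transition length, years (default 10).
#' @param transition_factor Multiplier on `t_half_elim` (default 2).
#' @return Object of class `period_labels`: data-frame-like list with
#'   `year`, `label` (factor: pre-ban/transition/post-ban), plus
#'   `transition_bounds` and `elim_unknown` attributes.
#' @export
classify_periods <- function(series, ban_year, t_half_elim = NULL,
                             min_transition = 10, transition_factor = 2) {
  stopifnot(inherits(series, "cstd_series"))
  elim_unknown <- is.null(t_half_elim) || is.na(t_half_elim)
  delta <- if (elim_unknown) min_transition
           else max(min_transition, transition_factor * t_half_elim)
  lab <- ifelse(series$year < ban_year, "pre-ban",
                ifelse(series$year < ban_year + delta, "transition",
                       "post-ban"))
  structure(
    list(year = series$year,
         label = factor(lab, levels = c("pre-ban", "transition", "post-ban")),
         transition_bounds = c(ban_year, ban_year + delta),
         ban_year = ban_year,
         elim_unknown = elim_unknown),
    class = "period_labels"
  )
}

#' @export
print.period_labels <- function(x, ...) {
  cat(sprintf("Period labels: ban %s, transition %s-%s%s\n",
              format(x$ban_year), format(x$transition_bounds[1]),
              format(x$transition_bounds[2]),
              if (x$elim_unknown)
                " (elimination half-life unknown; minimum transition length used)"
              else ""))
  print(table(x$label))
  invisible(x)
}

#' Age-concentration diagnostic for slow eliminators
#'
#' Within a single post-ban sampling year, regresses log concentration on
#' donor age. A significantly positive age slope is possible only when
#' the elimination half-life exceeds the intake halving time, so the flag
#' indicates a slowly eliminated chemical for which the apparent CSTD
#' halving time must not be read as the intake trend (and the inverse
#' half-life tool must not be applied). The check is meaningful only in
#' the post-ban period: before and during the transition, age profiles do
#' not separate slow from rapid eliminators, and the function refuses to
#' run there.
#'
#' @param cross_section A [cstd_series()] sampled in one calendar year at
#'   three or more distinct ages.
#' @param period Period label of that year: must be `"post-ban"`.
#' @param level One-sided significance level for the positive-slope test.
#' @param slope_epsilon Minimal slope (1/year of age) counted as an
#'   increase; guards against flagging numerically flat series whose
#'   zero residual variance makes the t-test degenerate.
#' @return Object of class `age_trend` with `slope` (1/year of age),
#'   `se`, `p_value` (one-sided, increase), `flag` (TRUE when a positive
#'   age trend is indicated, meaning elimination is slower than the
#'   intake decline), `n`.
#' @export
age_trend_check <- function(cross_section, period, level = 0.05,
                            slope_epsilon = 1e-9) {
  stopifnot(inherits(cross_section, "cstd_series"))
  period <- as.character(period)
  if (!identical(period, "post-ban"))
    stop(paste("age-concentration diagnostic refused: it is valid only for",
               "post-ban cross-sections (age profiles do not separate slow",
               "from rapid eliminators in the pre-ban and transition periods)"))
  if (length(unique(round(cross_section$year, 6))) != 1)
    stop("cross-section must come from a single sampling year")
  if (length(unique(cross_section$age)) < 3)
    stop("need at least 3 distinct ages")
  fit <- stats::lm(log(conc) ~ age, data = as.data.frame(cross_section))
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })$coefficients
  slope <- sm["age", "Estimate"]
  se <- sm["age", "Std. Error"]
  p_one <- stats::pt(slope / se, df = fit$df.residual, lower.tail = FALSE)
  structure(
    list(slope = slope, se = se, p_value = p_one,
         flag = is.finite(p_one) && p_one < level && slope > slope_epsilon,
         level = level, n = nrow(cross_section),
         year = cross_section$year[1]),
    class = "age_trend"
  )
}

#' @export
print.age_trend <- function(x, ...) {
  cat(sprintf(
    "Age-concentration check (year %s, n = %d): slope %.4g /y of age (SE %.3g), one-sided p = %.3g\n",
    format(x$year), x$n, x$slope, x$se, x$p_value))
  cat(if (x$flag)
    "  flag: concentrations increase with age -> elimination slower than intake decline indicated\n"
    else "  no positive age trend indicated\n")
  invisible(x)
}
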