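.RULE_TEXT <- c(
  R1 = paste("Pre-ban period: the doubling time of the CSTD equals the",
             "doubling time of intake (t2CSTD = t2in) and is completely",
             "independent of the elimination half-life."),
  R2 = paste("Transition period: fitting an apparent CSTD halving time is",
             "technically possible but not meaningful; it should not be",
             "reported as a trend estimate."),
  R3 = paste("Transition period: if elimination is faster than the intake",
             "decline (t1/2elim < t1/2in), the CSTD halving time identifies",
             "the intake halving time (t1/2CSTD = t1/2in) from about 10",
             "years after the ban onward."),
  R4 = paste("Transition/post-ban: the inverse (static-model) half-life",
             "tool is applicable to late-transition and post-ban data when",
             "elimination is faster than the intake decline."),
  R5 = paste("Post-ban period: with indications that elimination is slower",
             "than the intake decline (t1/2elim > t1/2in) or a long",
             "elimination half-life in general (roughly >= 10 years), the",
             "inverse half-life tool must not be applied; the CSTD halving",
             "time is then only an upper limit of the intake halving time.")
)

.recommendation <- function(id, verdict, rationale, triggers) {
  list(id = id, verdict = verdict, rule = unname(.RULE_TEXT[id]),
       rationale = rationale, triggers = triggers)
}

#' Validity verdicts for a CSTD fit and tool result
#'
#' Applies the five decision rules for interpreting CSTD doubling/halving
#' times to a fitted trend: which calendar period the fit window covers,
#' how the elimination half-life compares with the intake halving time,
#' and whether the post-ban age-concentration diagnostic flags slow
#' elimination. Every applicable rule yields exactly one verdict in
#' `valid` / `invalid` / `caution`, with the triggering quantities
#' attached. When the intake halving time is unknown it is proxied by the
#' post-ban CSTD halving time — which is only its upper limit — and any
#' verdict that relies on the proxy is downgraded to `caution`.
#'
#' An apparent CSTD halving time is never an elimination half-life; every
#' report carries that reminder.
#'
#' @param fit A [fit_loglinear()] result.
#' @param periods [classify_periods()] labels for the fitted series.
#' @param t_half_elim Elimination half-life in years, or NULL if unknown.
#' @param t_half_in Intake halving time in years, or NULL if unknown.
#' @param age_flag An [age_trend_check()] result, a logical, or NULL when
#'   no age cross-section is available.
#' @param elim_long_threshold "Long elimination half-life" cutoff for the
#'   do-not-apply-the-tool rule (years, default 10).
#' @param early_transition_years Length of the initial transition window
#'   in which fitted halving times are rejected outright (default 10).
#' @return Object of class `cstd_recommendations`: list of verdict
#'   records plus a `note` that the CSTD halving time never equals the
#'   elimination half-life.
#' @examples
#' s <- cstd_series(1950:1968, 30, 2^((1950:1968 - 1970) / 7))
#' fit <- fit_loglinear(s)
#' per <- classify_periods(s, 1970, 3)
#' recommendations(fit, per, t_half_elim = 3, t_half_in = 7)
#' @export
recommendations <- function(fit, periods, t_half_elim = NULL,
                            t_half_in = NULL, age_flag = NULL,
                            elim_long_threshold = 10,
                            early_transition_years = 10) {
  stopifnot(inherits(fit, "cstd_trend"), inherits(periods, "period_labels"))
  win <- fit$window
  ban <- periods$ban_year
  in_win <- periods$year >= win[1] & periods$year <= win[2]
  present <- unique(as.character(periods$label[in_win]))
  flag_raised <- if (inherits(age_flag, "age_trend")) isTRUE(age_flag$flag)
                 else isTRUE(age_flag)
  flag_available <- !is.null(age_flag)

  # ordering of elimination vs intake decline; proxied (upper-limit) intake
  # halving time downgrades dependent verdicts to caution
  proxied <- FALSE
  th_in <- t_half_in
  if (is.null(th_in) && fit$direction == "halving" &&
      "post-ban" %in% present) {
    th_in <- fit$half_life_or_doubling
    proxied <- TRUE
  }
  ordering <- if (flag_raised) "slower"
    else if (!is.null(t_half_elim) && !is.null(th_in)) {
      if (t_half_elim < th_in) "faster" else "slower"
    } else "unknown"
  soften <- function(v) if (proxied && v == "valid") "caution" else v

  trig <- list(periods_in_window = present,
               t_half_elim = t_half_elim,
               t_half_in = t_half_in,
               t_half_in_proxy = if (proxied) th_in else NULL,
               age_flag = if (flag_available) flag_raised else NA,
               t_half_or_double_cstd = fit$half_life_or_doubling,
               direction = fit$direction,
               years_since_ban = win[2] - ban)

  out <- list()
  mixed <- length(present) > 1

  if (mixed)
    out <- c(out, list(.recommendation(
      "R2", "caution",
      paste("fit window mixes periods", paste(present, collapse = " + "),
            "- split the window and fit each period separately"),
      trig)))

  if (identical(present, "pre-ban")) {
    out <- c(out, list(.recommendation(
      "R1",
      if (fit$direction == "doubling") "valid" else "caution",
      if (fit$direction == "doubling")
        sprintf(paste("pre-ban rising fit: the CSTD doubling time %.4g y",
                      "estimates the intake doubling time, for any",
                      "elimination half-life"), fit$half_life_or_doubling)
      else "pre-ban window but non-rising fit: check the data",
      trig)))
  }

  if (identical(present, "transition")) {
    early_end <- ban + early_transition_years
    if (win[2] <= early_end) {
      out <- c(out, list(.recommendation(
        "R2", "invalid",
        paste("fit confined to the first", early_transition_years,
              "years after the ban: apparent halving/doubling times there",
              "are artifacts of the flattening trend"),
        trig)))
    } else if (ordering == "faster") {
      out <- c(out, list(
        .recommendation("R3", soften("valid"),
          "late-transition fit with rapid elimination: the CSTD halving time identifies the intake halving time",
          trig),
        .recommendation("R4", soften("valid"),
          "inverse half-life tool applicable to this late-transition window",
          trig)))
    } else if (ordering == "slower") {
      out <- c(out, list(.recommendation(
        "R2", "invalid",
        "slowly eliminated chemical: apparent halving times are not meaningful anywhere in the transition period",
        trig)))
    } else {
      out <- c(out, list(.recommendation(
        "R2", "caution",
        "late-transition fit but the elimination half-life is unknown: result meaningful only if elimination is faster than the intake decline",
        trig)))
    }
  }

  if ("post-ban" %in% present && !mixed) {
    r5 <- (ordering == "slower") ||
      (!is.null(t_half_elim) && t_half_elim >= elim_long_threshold) ||
      flag_raised
    if (r5) {
      out <- c(out, list(.recommendation(
        "R5", "invalid",
        paste("indications of slow elimination",
              "(elimination half-life above the intake halving time,",
              "a long elimination half-life, or a positive age trend):",
              "inverse tool results rejected; the CSTD halving time",
              sprintf("%.4g y is only an upper limit of the intake halving time",
                      fit$half_life_or_doubling)),
        trig)))
    } else if (ordering == "faster") {
      out <- c(out, list(
        .recommendation("R3", soften("valid"),
          "post-ban fit with rapid elimination: the CSTD halving time equals the intake halving time",
          trig),
        .recommendation("R4", soften("valid"),
          "inverse half-life tool applicable to this post-ban window",
          trig)))
    } else {
      out <- c(out, list(.recommendation(
        "R5", "caution",
        "elimination half-life unknown and no age cross-section: treat the CSTD halving time as an upper limit of the intake halving time only",
        trig)))
    }
  }

  structure(
    list(recommendations = out,
         note = paste("an apparent CSTD halving time is a property of the",
                      "population and calendar window; it never equals the",
                      "intrinsic elimination half-life")),
    class = "cstd_recommendations"
  )
}

#' @export
print.cstd_recommendations <- function(x, ...) {
  cat("CSTD interpretation verdicts\n")
  for (r in x$recommendations) {
    cat(sprintf("  [%s] %s\n", r$id, toupper(r$verdict)))
    cat("      rule     :", r$rule, "\n")
    cat("      rationale:", r$rationale, "\n")
  }
  cat("  note:", x$note, "\n")
  invisible(x)
}

#' Extract verdicts as a data frame
#'
#' @param x A [recommendations()] result.
#' @return data.frame with columns `id`, `verdict`.
#' @export
verdicts <- function(x) {
  stopifnot(inherits(x, "cstd_recommendations"))
  data.frame(id = vapply(x$recommendations, `[[`, character(1), "id"),
             verdict = vapply(x$recommendations, `[[`, character(1), "verdict"),
             stringsAsFactors = FALSE)
}
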