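#' Estimate the intrinsic elimination half-life from CSTD and intake data
#'
#' Inverse estimator built on the static PPK model: given a CSTD series
#' and a population intake time series, it (a) fits the apparent CSTD
#' halving time by log-linear regression and (b) estimates the intrinsic
#' elimination half-life as the value whose static forward simulation —
#' each sampled individual integrated from birth over the (log-linearly
#' interpolated) intake series — best matches the observed log
#' concentrations in least squares. The search is a 1-D bounded
#' minimization on the log of the elimination half-life.
#'
#' With `co_estimate_scale = TRUE` a common multiplicative scale between
#' predicted and observed concentrations is profiled out, making the
#' estimate invariant to joint rescaling of concentrations and intakes;
#' the elimination half-life is then identified from the *shape* of the
#' series only, which requires data whose sampled lives straddle a change
#' in the intake trend. With it off, the absolute intake level anchors
#' the estimate (the convention of the original spreadsheet-style tool).
#'
#' The estimator inherits the static model's assumptions (no mother-to-
#' child transfer, constant body). Fed data from a population where
#' elimination is slower than the intake decline, it *underestimates*
#' the elimination half-life; [recommendations()] and [age_trend_check()]
#' encode when the result must be rejected.
#'
#' @param cstd A [cstd_series()] with at least 3 records; must not lie
#'   entirely before the ban (`ban_year`, when supplied) since the
#'   estimator is undefined for purely rising data.
#' @param intake An [intake_series()] spanning (ideally) each sampled
#'   individual's life; outside its range the terminal log-slope is
#'   extended, with a warning.
#' @param body A [static_body()].
#' @param sampling_age Age of the sampled individuals, years; used for
#'   records whose `age` is missing.
#' @param bounds Search interval for the elimination half-life, years.
#' @param co_estimate_scale Profile out a common concentration scale
#'   (default TRUE).
#' @param absorbed_fraction Absorbed fraction passed to the forward model.
#' @param ban_year Optional ban year used only to refuse purely pre-ban
#'   input.
#' @return Object of class `halflife_tool` with `t_half_cstd`,
#'   `t_half_elim_est`, `objective`, `scale`, `converged`, `fit` (the
#'   underlying [fit_loglinear()] object) and an echo of the inputs.
#' @examples
#' body <- static_body()
#' chem <- chemical_params(3)
#' sc <- exposure_scenario(1970, 7, 7, peak_intake = 1)
#' cstd <- static_cstd(body, chem, sc, 30, seq(1975, 2005, by = 5))
#' intk <- intake_series(1900:2010, exposure_multiplier(sc, 1900:2010))
#' estimate_elim_halflife(cstd, intk, body, 30)
#' @export
estimate_elim_halflife <- function(cstd, intake, body, sampling_age,
                                   bounds = c(0.05, 100),
                                   co_estimate_scale = TRUE,
                                   absorbed_fraction = 1,
                                   ban_year = NULL) {
  stopifnot(inherits(cstd, "cstd_series"), inherits(intake, "intake_series"),
            inherits(body, "static_body"))
  if (nrow(cstd) < 3) stop("need at least 3 CSTD records")
  if (!is.null(ban_year) && all(cstd$year < ban_year))
    stop(paste("CSTD window lies entirely before the ban: the elimination",
               "half-life estimator is undefined for purely pre-ban data"))
  ages <- ifelse(is.na(cstd$age), sampling_age, cstd$age)
  births <- cstd$year - ages

  # warn once (not per optimizer step) about intake extrapolation
  span <- range(intake$year)
  if (min(births) < span[1] || max(cstd$year) > span[2])
    warning(sprintf(
      "intake series [%s, %s] does not span all sampled lives [%s, %s]; terminal log-slopes extended",
      format(span[1]), format(span[2]), format(min(births)),
      format(max(cstd$year))))

  lobs <- log(cstd$conc)
  forward <- function(th_elim) {
    chem <- chemical_params(th_elim, absorbed_fraction)
    vapply(seq_len(nrow(cstd)), function(i)
      .concentration_static_intake(body, chem, intake, births[i],
                                   cstd$year[i], warn_extrapolation = FALSE),
      numeric(1))
  }
  objective <- function(log_th) {
    lpred <- log(forward(exp(log_th)))
    r <- lobs - lpred
    if (co_estimate_scale) r <- r - mean(r)
    sum(r^2)
  }
  opt <- stats::optimize(objective, log(bounds), tol = 1e-8)
  th_hat <- exp(opt$minimum)
  lr <- diff(log(bounds))
  converged <- opt$minimum > log(bounds[1]) + 0.005 * lr &&
               opt$minimum < log(bounds[2]) - 0.005 * lr
  lpred <- log(forward(th_hat))
  scale <- if (co_estimate_scale) exp(mean(lobs - lpred)) else 1

  fit <- fit_loglinear(cstd)
  structure(
    list(t_half_cstd = fit$half_life_or_doubling,
         cstd_direction = fit$direction,
         t_half_elim_est = th_hat,
         objective = opt$objective,
         scale = scale,
         converged = converged,
         bounds = bounds,
         co_estimate_scale = co_estimate_scale,
         fit = fit,
         body = body,
         sampling_age = sampling_age,
         n_records = nrow(cstd)),
    class = "halflife_tool"
  )
}

#' @export
print.halflife_tool <- function(x, ...) {
  cat("Elimination half-life estimate (static-model inversion)\n")
  cat(sprintf("  apparent CSTD %s time : %.4g y\n",
              x$cstd_direction, x$t_half_cstd))
  cat(sprintf("  elimination half-life : %.4g y%s\n", x$t_half_elim_est,
              if (!x$converged) "  [optimum at search bound - not converged]"
              else ""))
  cat(sprintf("  records %d, residual SS %.4g, scale %.4g, search [%g, %g] y\n",
              x$n_records, x$objective, x$scale, x$bounds[1], x$bounds[2]))
  invisible(x)
}

#' @export
summary.halflife_tool <- function(object, ...) {
  out <- list(
    t_half_cstd = object$t_half_cstd,
    cstd_direction = object$cstd_direction,
    t_half_elim_est = object$t_half_elim_est,
    objective = object$objective,
    scale = object$scale,
    converged = object$converged,
    co_estimate_scale = object$co_estimate_scale,
    body_weight = object$body$body_weight,
    lipid_fraction = object$body$lipid_fraction,
    sampling_age = object$sampling_age,
    n_records = object$n_records)
  class(out) <- "summary.halflife_tool"
  out
}

#' @export
print.summary.halflife_tool <- function(x, ...) {
  cat("Static-model inverse estimate\n")
  cat(sprintf("  CSTD %s time      : %.4g y (apparent, population-specific)\n",
              x$cstd_direction, x$t_half_cstd))
  cat(sprintf("  elimination half-life est.: %.4g y (converged: %s)\n",
              x$t_half_elim_est, x$converged))
  cat(sprintf("  body %.3g kg / lipid %.3g; sampling age %.3g y; %d records\n",
              x$body_weight, x$lipid_fraction, x$sampling_age, x$n_records))
  invisible(x)
}

#' @export
coef.halflife_tool <- function(object, ...) {
  c(t_half_cstd = object$t_half_cstd,
    t_half_elim_est = object$t_half_elim_est)
}
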