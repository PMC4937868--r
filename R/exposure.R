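#' Chemical parameters
#'
#' The two chemical-specific constants of the one-compartment model: the
#' intrinsic elimination half-life (how fast the body metabolizes and
#' excretes the chemical) and the fraction of gross intake that is
#' absorbed. Intake estimates for POPs are usually reported as absorbed
#' dose, hence the default absorbed fraction of 1.
#'
#' @param t_half_elim Intrinsic elimination half-life in years (> 0).
#' @param absorbed_fraction Fraction of intake absorbed, in (0, 1].
#' @return Object of class `chemical_params` with derived rate constant
#'   `k_elim = ln(2)/t_half_elim` (1/year).
#' @export
chemical_params <- function(t_half_elim, absorbed_fraction = 1) {
  if (t_half_elim <= 0) stop("t_half_elim must be positive")
  if (absorbed_fraction <= 0 || absorbed_fraction > 1)
    stop("absorbed_fraction must be in (0, 1]")
  structure(
    list(t_half_elim = t_half_elim,
         absorbed_fraction = absorbed_fraction,
         k_elim = log(2) / t_half_elim),
    class = "chemical_params"
  )
}

#' @export
print.chemical_params <- function(x, ...) {
  cat(sprintf(
    "Chemical: elimination half-life %.3g y (k_elim = %.4g /y), absorbed fraction %.3g\n",
    x$t_half_elim, x$k_elim, x$absorbed_fraction))
  invisible(x)
}

#' Piecewise-exponential population intake scenario
#'
#' Population intake rises exponentially with doubling time `t_double_in`
#' until `ban_year`, peaks there at `peak_intake`, and declines
#' exponentially with halving time `t_half_in` afterwards. The pre-ban
#' branch extends indefinitely into the past (intake -> 0), so no market
#' introduction year is needed. `age_factor` optionally scales the per-kg
#' dietary intake by age (default: constant 1); milk intake by breastfed
#' infants is handled mechanistically by the dynamic model, not here.
#'
#' @param ban_year Calendar year of the ban/phaseout (intake peak).
#' @param t_double_in Pre-ban intake doubling time, years (> 0).
#' @param t_half_in Post-ban intake halving time, years (> 0).
#' @param peak_intake Intake at the ban year, ng/kg body weight/day (>= 0).
#' @param age_factor Optional function(age) -> dimensionless multiplier.
#' @return Object of class `exposure_scenario`.
#' @examples
#' sc <- exposure_scenario(1970, 7, 7)
#' exposure_multiplier(sc, c(1963, 1970, 1977))  # 0.5 1.0 0.5
#' @export
exposure_scenario <- function(ban_year, t_double_in, t_half_in,
                              peak_intake = 1, age_factor = NULL) {
  if (t_double_in <= 0) stop("t_double_in must be positive")
  if (t_half_in <= 0) stop("t_half_in must be positive")
  if (peak_intake < 0) stop("peak_intake must be >= 0")
  if (!is.null(age_factor) && !is.function(age_factor))
    stop("age_factor must be NULL or a function of age")
  structure(
    list(ban_year = ban_year,
         t_double_in = t_double_in,
         t_half_in = t_half_in,
         peak_intake = peak_intake,
         age_factor = age_factor),
    class = "exposure_scenario"
  )
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf(
    "Exposure scenario: ban %s; doubling time %.3g y (pre-ban), halving time %.3g y (post-ban); peak %.3g ng/kg/d\n",
    format(x$ban_year), x$t_double_in, x$t_half_in, x$peak_intake))
  if (!is.null(x$age_factor)) cat("  with age-dependent intake factor\n")
  invisible(x)
}

#' Normalized intake multiplier at a calendar year
#'
#' Equals `2^((year - ban_year)/t_double_in)` before the ban and
#' `2^(-(year - ban_year)/t_half_in)` after it; exactly 1 at the ban year.
#' `log2` of the multiplier is piecewise linear in year with slopes
#' `+1/t_double_in` and `-1/t_half_in`.
#'
#' @param scenario An [exposure_scenario()].
#' @param year Calendar year(s), vectorized.
#' @return Dimensionless multiplier(s), strictly positive.
#' @export
exposure_multiplier <- function(scenario, year) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  dt <- year - scenario$ban_year
  ifelse(dt <= 0,
         2^(dt / scenario$t_double_in),
         2^(-dt / scenario$t_half_in))
}

#' Absolute dietary intake rate of an individual
#'
#' Gross (pre-absorption) dietary intake in ng/day:
#' `peak_intake * exposure_multiplier(year) * age_factor(age) * body weight`.
#' Absorption is applied by the pharmacokinetic modules, not here.
#'
#' @param scenario An [exposure_scenario()].
#' @param year Calendar year(s).
#' @param age Age(s) in years (>= 0).
#' @param bw Body weight(s) in kg (> 0).
#' @return Intake rate(s) in ng/day.
#' @export
intake_rate <- function(scenario, year, age, bw) {
  if (any(bw <= 0)) stop("body weight must be positive")
  if (any(age < 0)) stop("age must be non-negative")
  af <- if (is.null(scenario$age_factor)) 1 else scenario$age_factor(age)
  scenario$peak_intake * exposure_multiplier(scenario, year) * af * bw
}
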