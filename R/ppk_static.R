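#' Static body: fixed body and lipid weight
#'
#' The body assumed by the static PPK model: constant body weight and lipid
#' fraction over the whole life, no transfer of chemical from mother to
#' child. Under these assumptions the one-compartment mass balance has a
#' closed-form solution.
#'
#' @param body_weight Body weight, kg (> 0).
#' @param lipid_fraction Body lipid fraction, in (0, 1).
#' @return Object of class `static_body` with derived `lipid_mass` in g.
#' @export
static_body <- function(body_weight = 60, lipid_fraction = 0.30) {
  if (body_weight <= 0) stop("body_weight must be positive")
  if (lipid_fraction <= 0 || lipid_fraction >= 1)
    stop("lipid_fraction must be in (0, 1)")
  structure(
    list(body_weight = body_weight,
         lipid_fraction = lipid_fraction,
         lipid_mass = body_weight * lipid_fraction * 1000),
    class = "static_body"
  )
}

#' @export
print.static_body <- function(x, ...) {
  cat(sprintf("Static body: %.3g kg, lipid fraction %.3g (lipid mass %.4g g)\n",
              x$body_weight, x$lipid_fraction, x$lipid_mass))
  invisible(x)
}

# days per year used to convert ng/day source terms to ng/year
.DAYS_PER_YEAR <- 365.25

# Exact propagation of dC/dt = u0 * exp(g (t - a)) - k_e C over one segment
# of length dt:
#   C(a+dt) = C(a) e^{-k_e dt} + u0 (e^{g dt} - e^{-k_e dt}) / (g + k_e)
# obtained from the convolution integral of the exponential forcing with the
# first-order decay kernel. When g + k_e ~ 0 (elimination rate equal to the
# decline rate of the forcing) the quotient degenerates and the analytic
# limit u0 * dt * e^{-k_e dt} is used instead of dividing by ~0.
.propagate_segment <- function(C0, u0, g, k_e, dt, tol = 1e-10) {
  s <- g + k_e
  if (abs(s) < tol) {
    C0 * exp(-k_e * dt) + u0 * dt * exp(-k_e * dt)
  } else {
    C0 * exp(-k_e * dt) + u0 * (exp(g * dt) - exp(-k_e * dt)) / s
  }
}

# Propagate across a piecewise-exponential forcing given as knot times and
# log-slopes: segments data.frame(start, end, u_start, g). Segments must
# tile [birth, sampling] in order.
.propagate_segments <- function(segments, k_e) {
  C <- 0
  for (i in seq_len(nrow(segments))) {
    dt <- segments$end[i] - segments$start[i]
    if (dt <= 0) next
    C <- .propagate_segment(C, segments$u_start[i], segments$g[i], k_e, dt)
  }
  C
}

# Build forcing segments (in concentration units, ng/g lipid/year) for a
# parametric scenario over [from, to]: split at the ban year.
.scenario_segments <- function(body, chem, scenario, from, to) {
  u_of <- function(year) {
    chem$absorbed_fraction * scenario$peak_intake *
      exposure_multiplier(scenario, year) * body$body_weight *
      .DAYS_PER_YEAR / body$lipid_mass
  }
  k_up <- log(2) / scenario$t_double_in
  k_dn <- -log(2) / scenario$t_half_in
  knots <- c(from, if (scenario$ban_year > from && scenario$ban_year < to)
    scenario$ban_year, to)
  data.frame(
    start = knots[-length(knots)],
    end = knots[-1],
    u_start = u_of(knots[-length(knots)]),
    g = ifelse(knots[-length(knots)] < scenario$ban_year, k_up, k_dn)
  )
}

#' Closed-form concentration of the static PPK model
#'
#' Exact solution of the static one-compartment mass balance
#' \deqn{dC/dt = u E(t) - k_{elim} C,\qquad C(\mathrm{birth}) = 0,}
#' where `C` is the lipid-normalized concentration (ng/g lipid),
#' `u = absorbed_fraction * peak_intake * body_weight * 365.25 / lipid_mass`
#' and `E(t)` is the piecewise-exponential intake multiplier of the
#' scenario. Lives straddling the ban year are propagated segment by
#' segment (decay-propagated pre-ban solution plus the post-ban convolution
#' term); the degenerate case `k_elim = ln 2 / t_half_in` uses the analytic
#' limit rather than a division by zero.
#'
#' For a life entirely after the ban this reduces to
#' `C(ts) = u E(ts) (1 - exp(-(k_elim - k_in) A)) / (k_elim - k_in)` with
#' `A` the age at sampling and `k_in = ln 2 / t_half_in` — proportional to
#' `E(ts)` at fixed age, for every elimination rate.
#'
#' @param body A [static_body()].
#' @param chem A [chemical_params()].
#' @param scenario An [exposure_scenario()].
#' @param birth_year Birth year of the (static) individual.
#' @param sampling_year Sampling year (>= birth_year); vectorized.
#' @return Concentration(s) in ng/g lipid.
#' @export
concentration_static <- function(body, chem, scenario, birth_year, sampling_year) {
  stopifnot(inherits(body, "static_body"), inherits(chem, "chemical_params"),
            inherits(scenario, "exposure_scenario"))
  if (any(sampling_year < birth_year))
    stop("sampling_year must be >= birth_year")
  vapply(sampling_year, function(ts) {
    if (ts == birth_year) return(0)
    segs <- .scenario_segments(body, chem, scenario, birth_year, ts)
    .propagate_segments(segs, chem$k_elim)
  }, numeric(1))
}

# Static forward solution driven by a tabulated intake series (log-linear
# between knots, i.e. piecewise exponential). Used by the half-life tool.
.concentration_static_intake <- function(body, chem, intake, birth_year,
                                         sampling_year,
                                         warn_extrapolation = TRUE) {
  if (sampling_year <= birth_year) return(0)
  yr <- intake$year
  knots <- sort(unique(c(birth_year, yr[yr > birth_year & yr < sampling_year],
                         sampling_year)))
  I0 <- intake_at(intake, knots[-length(knots)],
                  warn_extrapolation = warn_extrapolation)
  I1 <- intake_at(intake, knots[-1], warn_extrapolation = FALSE)
  dt <- diff(knots)
  conv <- chem$absorbed_fraction * body$body_weight * .DAYS_PER_YEAR /
    body$lipid_mass
  segs <- data.frame(start = knots[-length(knots)], end = knots[-1],
                     u_start = conv * I0,
                     g = (log(I1) - log(I0)) / dt)
  .propagate_segments(segs, chem$k_elim)
}

#' Static-model CSTD: one static individual per sampling year
#'
#' Evaluates the closed-form static concentration for a cross-sectional
#' design: at each sampling year an individual of age `target_age` (born
#' `sampling_year - target_age`, concentration zero at birth) is sampled.
#' Once every sampled life lies entirely after the ban, the log-slope of
#' this series equals `-ln 2 / t_half_in` exactly, independent of the
#' elimination half-life — the analytic core of the static model's claim
#' that post-ban CSTD halving times measure the intake trend.
#'
#' @inheritParams concentration_static
#' @param target_age Age of the sampled individuals, years.
#' @param sampling_years Sampling years.
#' @return A [cstd_series()].
#' @export
static_cstd <- function(body, chem, scenario, target_age, sampling_years) {
  conc <- vapply(sampling_years, function(ts)
    concentration_static(body, chem, scenario, ts - target_age, ts),
    numeric(1))
  cstd_series(sampling_years, target_age, conc)
}
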