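#' Age-dependent growth model
#'
#' Defines body weight and body lipid fraction as piecewise-linear functions
#' of age, anchored at a small set of ages. Beyond the last anchor both
#' curves are constant (adult plateau). The defaults are female reference
#' values; both curves matter because a growing lipid pool dilutes the body
#' burden even when the burden itself is constant.
#'
#' @param anchor_ages Ascending ages (years) at which the curves are anchored.
#' @param body_weight Body weight (kg) at each anchor age.
#' @param lipid_fraction Body lipid fraction (dimensionless, in (0,1)) at
#'   each anchor age.
#' @return An object of class `growth_model`.
#' @examples
#' gm <- growth_model()
#' body_weight(gm, c(0, 0.5, 30))
#' lipid_fraction(gm, 30)
#' @export
growth_model <- function(anchor_ages = c(0, 1, 5, 10, 15, 20),
                         body_weight = c(3.5, 10, 20, 35, 55, 60),
                         lipid_fraction = c(0.25, 0.20, 0.18, 0.22, 0.27, 0.30)) {
  stopifnot(length(anchor_ages) == length(body_weight),
            length(anchor_ages) == length(lipid_fraction))
  if (is.unsorted(anchor_ages, strictly = TRUE))
    stop("anchor_ages must be strictly ascending")
  if (any(body_weight <= 0))
    stop("body weight must be positive at every anchor")
  if (any(lipid_fraction <= 0 | lipid_fraction >= 1))
    stop("lipid fraction must lie in (0, 1) at every anchor")
  structure(
    list(anchor_ages = as.numeric(anchor_ages),
         body_weight = as.numeric(body_weight),
         lipid_fraction = as.numeric(lipid_fraction)),
    class = "growth_model"
  )
}

#' Constant-body growth model
#'
#' Degenerate growth model with age-independent body weight and lipid
#' fraction; the body assumed by the static PPK model.
#'
#' @param body_weight Body weight in kg.
#' @param lipid_fraction Body lipid fraction in (0,1).
#' @return A `growth_model` whose curves are flat.
#' @export
constant_growth <- function(body_weight = 60, lipid_fraction = 0.30) {
  growth_model(anchor_ages = c(0, 1),
               body_weight = rep(body_weight, 2),
               lipid_fraction = rep(lipid_fraction, 2))
}

#' @export
print.growth_model <- function(x, ...) {
  cat("Growth model (piecewise linear, constant beyond last anchor)\n")
  print(data.frame(age = x$anchor_ages, body_weight_kg = x$body_weight,
                   lipid_fraction = x$lipid_fraction), row.names = FALSE)
  invisible(x)
}

# linear interpolation with flat extrapolation past the last anchor;
# rule = 2 also holds the first anchor's value for (impossible) age < min
.interp <- function(xs, ys, age) {
  stats::approx(xs, ys, xout = age, rule = 2)$y
}

#' Body weight at a given age
#'
#' @param growth A [growth_model()].
#' @param age Age(s) in years (vectorized); must be non-negative.
#' @return Body weight(s) in kg.
#' @export
body_weight <- function(growth, age) {
  stopifnot(inherits(growth, "growth_model"))
  if (any(age < 0)) stop("age must be non-negative")
  .interp(growth$anchor_ages, growth$body_weight, age)
}

#' Body lipid fraction at a given age
#'
#' @inheritParams body_weight
#' @return Lipid fraction(s), dimensionless.
#' @export
lipid_fraction <- function(growth, age) {
  stopifnot(inherits(growth, "growth_model"))
  if (any(age < 0)) stop("age must be non-negative")
  .interp(growth$anchor_ages, growth$lipid_fraction, age)
}

#' Body lipid mass at a given age
#'
#' Lipid mass in grams: body weight (kg) x lipid fraction x 1000. This is
#' the denominator of every lipid-normalized concentration in the package.
#'
#' @inheritParams body_weight
#' @return Lipid mass(es) in g.
#' @export
lipid_mass <- function(growth, age) {
  body_weight(growth, age) * lipid_fraction(growth, age) * 1000
}

#' Reproduction and lactation schedule
#'
#' One child per individual; the child is born when the mother reaches
#' `age_at_childbirth` and is breastfed for `breastfeeding_duration` years,
#' during which the mother secretes `milk_lipid_output` grams of milk lipid
#' per day. Milk lipid is assumed to be in concentration equilibrium with
#' the mother's body lipid. The default 25 g lipid/day corresponds to about
#' 700 g milk/day at 3.5% lipid.
#'
#' @param age_at_childbirth Mother's age at delivery, years (> 0).
#' @param breastfeeding_duration Years of lactation (>= 0).
#' @param milk_lipid_output Milk lipid secretion, g lipid/day (>= 0).
#' @return An object of class `reproduction_schedule`.
#' @export
reproduction_schedule <- function(age_at_childbirth = 30,
                                  breastfeeding_duration = 0.5,
                                  milk_lipid_output = 25) {
  if (age_at_childbirth <= 0) stop("age_at_childbirth must be positive")
  if (breastfeeding_duration < 0) stop("breastfeeding_duration must be >= 0")
  if (milk_lipid_output < 0) stop("milk_lipid_output must be >= 0")
  structure(
    list(age_at_childbirth = age_at_childbirth,
         breastfeeding_duration = breastfeeding_duration,
         milk_lipid_output = milk_lipid_output),
    class = "reproduction_schedule"
  )
}

#' Build a mother-to-child lineage
#'
#' Chains `n_generations` individuals: the founder is born in
#' `founder_birth_year`, and each subsequent individual is born when their
#' mother reaches the schedule's childbirth age. The lineage is the unit
#' the dynamic PPK simulator integrates, so that an individual of any
#' target age exists at the sampling years of interest.
#'
#' @param founder_birth_year Decimal calendar year of the founder's birth.
#' @param n_generations Number of individuals in the chain (>= 1).
#' @param schedule A [reproduction_schedule()].
#' @param growth A [growth_model()] shared by all members.
#' @return An object of class `lineage`: list with `birth_years`, `mother`
#'   (index of each member's mother, NA for the founder), `schedule`,
#'   `growth`.
#' @examples
#' ln <- build_lineage(1910, 3)
#' ln$birth_years  # 1910 1940 1970
#' @export
build_lineage <- function(founder_birth_year, n_generations,
                          schedule = reproduction_schedule(),
                          growth = growth_model()) {
  if (n_generations < 1) stop("n_generations must be >= 1")
  birth_years <- founder_birth_year +
    schedule$age_at_childbirth * (seq_len(n_generations) - 1)
  structure(
    list(birth_years = birth_years,
         mother = c(NA_integer_, seq_len(n_generations - 1)),
         schedule = schedule,
         growth = growth),
    class = "lineage"
  )
}

#' @export
print.lineage <- function(x, ...) {
  cat(sprintf("Lineage of %d generation(s); births %s\n",
              length(x$birth_years),
              paste(format(x$birth_years), collapse = ", ")))
  invisible(x)
}

#' Locate the lineage member closest to a target age in a sampling year
#'
#' Returns the member whose age at `sampling_year` is closest to
#' `target_age`; ties are broken toward the older candidate. The returned
#' record always carries the member's actual age so that non-exact matches
#' are visible to the caller.
#'
#' @param lineage A [build_lineage()] result.
#' @param sampling_year Decimal calendar year.
#' @param target_age Desired age in years.
#' @param tol Ages within `tol` years count as an exact match.
#' @return List with `index`, `birth_year`, `age` (actual age at sampling),
#'   and `exact` (logical).
#' @export
individual_at <- function(lineage, sampling_year, target_age, tol = 1e-8) {
  stopifnot(inherits(lineage, "lineage"))
  if (length(lineage$birth_years) == 0) stop("lineage is empty")
  ages <- sampling_year - lineage$birth_years
  alive <- ages >= 0
  if (!any(alive))
    stop(sprintf("no lineage member is born by %s", format(sampling_year)))
  dev <- abs(ages - target_age)
  dev[!alive] <- Inf
  best <- min(dev)
  # tie toward the older candidate = smaller index (earlier birth year)
  idx <- which(dev <= best + tol)[1L]
  list(index = idx,
       birth_year = lineage$birth_years[idx],
       age = ages[idx],
       exact = best <= tol)
}

#' Read life-history and scenario configuration from YAML or JSON
#'
#' Convenience loader: a config file may contain `growth`, `schedule`,
#' `scenario`, `chemical` and `noise` blocks whose fields are the arguments
#' of [growth_model()], [reproduction_schedule()], [exposure_scenario()],
#' [chemical_params()] and [noise_model()]. Missing blocks fall back to the
#' package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Named list with elements `growth`, `schedule`, `scenario`,
#'   `chemical`, `noise` (the latter three NULL when absent from the file).
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)  # yaml::read_yaml parses JSON too
  out <- list(
    growth = do.call(growth_model, cfg$growth %||% list()),
    schedule = do.call(reproduction_schedule, cfg$schedule %||% list()),
    scenario = if (!is.null(cfg$scenario)) do.call(exposure_scenario, cfg$scenario),
    chemical = if (!is.null(cfg$chemical)) do.call(chemical_params, cfg$chemical),
    noise = if (!is.null(cfg$noise)) do.call(noise_model, cfg$noise)
  )
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
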