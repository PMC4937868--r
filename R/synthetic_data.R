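#' Sampling-noise model for synthetic CSTD
#'
#' Multiplicative lognormal noise emulating the scatter of pooled
#' breast-milk samples: each sampling year draws `n_per_year` lognormal
#' deviates around the model concentration (standard deviation
#' `sigma_log` on the natural-log scale) and reports their geometric
#' mean, mimicking a pooled-sample design. `sigma_log = 0` reproduces the
#' model curve exactly.
#'
#' @param sigma_log Standard deviation of log concentration (>= 0).
#' @param n_per_year Individual samples pooled per year (>= 1).
#' @param seed Optional integer seed for reproducible generation.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(sigma_log = 0.2, n_per_year = 1, seed = NULL) {
  if (sigma_log < 0) stop("sigma_log must be >= 0")
  if (n_per_year < 1) stop("n_per_year must be >= 1")
  structure(list(sigma_log = sigma_log, n_per_year = as.integer(n_per_year),
                 seed = seed),
            class = "noise_model")
}

#' Generate a synthetic CSTD series
#'
#' Evaluates the dynamic or static PPK model on a cross-sectional design
#' and overlays multiplicative lognormal sampling noise. With
#' `noise$sigma_log = 0` the output is identical to [dynamic_cstd()] /
#' [static_cstd()].
#'
#' @param model `"dynamic"` or `"static"`.
#' @param chem A [chemical_params()].
#' @param scenario An [exposure_scenario()].
#' @param target_age Sampled age, years.
#' @param sampling_years Sampling years.
#' @param noise A [noise_model()].
#' @param body A [static_body()] (static model only).
#' @param ... Passed on to [dynamic_cstd()] (schedule, growth, features,
#'   step, n_generations).
#' @return A [cstd_series()] with `n` set to `noise$n_per_year`.
#' @examples
#' sc <- exposure_scenario(1970, 7, 7)
#' generate_cstd("static", chemical_params(3), sc, 30, 1990:1995,
#'               noise_model(0.2, 10, seed = 1))
#' @export
generate_cstd <- function(model = c("dynamic", "static"), chem, scenario,
                          target_age, sampling_years,
                          noise = noise_model(), body = static_body(), ...) {
  model <- match.arg(model)
  base <- switch(model,
    dynamic = dynamic_cstd(chem, scenario, target_age, sampling_years, ...),
    static = static_cstd(body, chem, scenario, target_age, sampling_years))
  if (noise$sigma_log == 0) {
    base$n <- rep(noise$n_per_year, nrow(base))
    return(base)
  }
  if (!is.null(noise$seed)) set.seed(noise$seed)
  conc <- vapply(base$conc, function(mu) {
    draws <- stats::rlnorm(noise$n_per_year, meanlog = log(mu),
                           sdlog = noise$sigma_log)
    exp(mean(log(draws)))
  }, numeric(1))
  cstd_series(base$year, base$age, conc, noise$n_per_year)
}

.FIXTURES <- c("BDE47", "DDT", "PCB153", "HCB")

#' Load packaged reference datasets
#'
#' Ships small CSTD + intake tables for four archetypal POP situations in
#' a monitored population: BDE47 (rapid elimination, recent phaseout),
#' DDT (rapid elimination, old ban), PCB153 (slow elimination - the
#' classic failure case of the static inverse tool) and HCB (intermediate
#' elimination with a slowly declining intake).
#'
#' All shipped tables are *synthetic*: noise-free curves generated by
#' this package's own dynamic PPK model from literature-typical parameter
#' values (recorded alongside the data and returned in `$meta`). They are
#' stand-ins for empirical monitoring tables, intended for examples and
#' for demonstrating the estimators' behaviour; they are not measured
#' data. Requesting `source = "transcribed"` fails with an explanatory
#' error, since no transcription of empirical monitoring tables is
#' distributed with the package.
#'
#' @param name One of `"BDE47"`, `"DDT"`, `"PCB153"`, `"HCB"`.
#' @param source `"synthetic"` (shipped) or `"transcribed"` (unavailable).
#' @return List with elements `cstd` ([cstd_series()]), `intake`
#'   ([intake_series()]) and `meta` (named list of the generating
#'   parameters: ban year, intake doubling/halving times, peak intake,
#'   elimination half-life, sampled age).
#' @export
load_fixture <- function(name, source = c("synthetic", "transcribed")) {
  source <- match.arg(source)
  if (!name %in% .FIXTURES)
    stop(sprintf("unknown fixture '%s'; available fixtures: %s",
                 name, paste(.FIXTURES, collapse = ", ")))
  if (source == "transcribed")
    stop(sprintf(paste(
      "no transcribed empirical monitoring tables are distributed with this",
      "package; only synthetic stand-ins are shipped for '%s'.",
      "Transcribe the published national monitoring CSTD and intake tables",
      "yourself and load them with read_cstd()/read_intake()."), name))
  dir <- system.file("extdata", package = "cstdppk", mustWork = TRUE)
  cstd <- read_cstd(file.path(dir, sprintf("cstd_%s_synthetic.csv",
                                           tolower(name))))
  intake <- read_intake(file.path(dir, sprintf("intake_%s_synthetic.csv",
                                               tolower(name))))
  meta_all <- utils::read.csv(file.path(dir, "fixtures_meta.csv"))
  m <- meta_all[meta_all$chemical == name, , drop = FALSE]
  meta <- as.list(m[1, setdiff(names(m), "chemical")])
  list(cstd = cstd, intake = intake, meta = meta)
}
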