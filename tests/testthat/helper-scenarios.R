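# Shared builders for the reference simulation scenario used across the
# suite: ban in 1970, intake doubling and halving times of 7 years,
# 30-year-old donors; one rapidly (3 y) and one slowly (14 y) eliminated
# chemical under the identical intake trend.

ref_scenario <- function(peak = 1) exposure_scenario(1970, 7, 7, peak_intake = peak)
chem_rapid <- function() chemical_params(3)
chem_slow <- function() chemical_params(14)

# tabulate a parametric scenario as an intake series
scenario_intake_table <- function(scenario, years) {
  intake_series(years, scenario$peak_intake * exposure_multiplier(scenario, years))
}

# halving/doubling time of a fit, sign-free
fitted_time <- function(fit) fit$half_life_or_doubling
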