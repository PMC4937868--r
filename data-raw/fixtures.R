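# Generates the synthetic reference datasets shipped under inst/extdata/.
#
# Each dataset is a noise-free CSTD + intake-table pair produced by the
# package's own dynamic PPK model for an archetypal POP situation in a
# monitored population (30-year-old mothers). Parameter values are
# literature-typical for the named chemicals (ban years, intake trend
# times, elimination half-lives, rough peak intakes); the tables are
# stand-ins for empirical monitoring data, not measurements.
#
# Run from the package root: Rscript data-raw/fixtures.R

devtools::load_all(".", quiet = TRUE)

specs <- list(
  BDE47 = list(ban_year = 1995, t_double_in = 5, t_half_in = 6.8,
               peak_intake = 1, t_half_elim = 2.2, target_age = 30,
               cstd_years = 2004:2012, intake_years = 1965:2015),
  DDT = list(ban_year = 1970, t_double_in = 10, t_half_in = 5,
             peak_intake = 500, t_half_elim = 2, target_age = 30,
             cstd_years = seq(1980, 2006, by = 2),
             intake_years = 1940:2010),
  PCB153 = list(ban_year = 1972, t_double_in = 15, t_half_in = 10,
                peak_intake = 15, t_half_elim = 15, target_age = 30,
                cstd_years = seq(1996, 2012, by = 2),
                intake_years = 1940:2015),
  HCB = list(ban_year = 1975, t_double_in = 15, t_half_in = 12,
             peak_intake = 5, t_half_elim = 6, target_age = 30,
             cstd_years = seq(1996, 2012, by = 2),
             intake_years = 1945:2015)
)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
meta <- NULL
for (nm in names(specs)) {
  p <- specs[[nm]]
  sc <- exposure_scenario(p$ban_year, p$t_double_in, p$t_half_in,
                          peak_intake = p$peak_intake)
  chem <- chemical_params(p$t_half_elim)
  cstd <- dynamic_cstd(chem, sc, p$target_age, p$cstd_years)
  intake <- intake_series(p$intake_years,
                          p$peak_intake * exposure_multiplier(sc, p$intake_years))
  write_cstd(cstd, sprintf("inst/extdata/cstd_%s_synthetic.csv", tolower(nm)))
  write_intake(intake, sprintf("inst/extdata/intake_%s_synthetic.csv", tolower(nm)))
  meta <- rbind(meta, data.frame(
    chemical = nm, ban_year = p$ban_year, t_double_in = p$t_double_in,
    t_half_in = p$t_half_in, peak_intake = p$peak_intake,
    t_half_elim = p$t_half_elim, target_age = p$target_age))
}
write.csv(meta, "inst/extdata/fixtures_meta.csv", row.names = FALSE)
cat("fixtures written\n")
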