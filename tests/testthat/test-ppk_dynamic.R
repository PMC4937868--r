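test_that("zero intake yields identically zero burdens", {
  sc <- exposure_scenario(1970, 7, 7, peak_intake = 0)
  ln <- build_lineage(1950, 2)
  tr <- simulate_lineage(ln, chem_rapid(), sc, c(1950, 2000))
  for (d in tr$individuals)
    expect_true(all(d$burden_ng == 0))
})

test_that("with no elimination and no transfer the burden equals the absorbed intake integral", {
  sc <- ref_scenario()
  ch <- chemical_params(1e9)  # effectively no elimination
  ln <- build_lineage(1950, 1)
  tr <- simulate_lineage(ln, ch, sc, c(1950, 1990),
                         features = dynamic_features(FALSE, FALSE, FALSE))
  d <- tr$individuals[[1]]
  m_end <- d$burden_ng[nrow(d)]
  bw_const <- body_weight(ln$growth, 99)  # adult plateau used when growth off
  oracle <- stats::integrate(function(t) intake_rate(sc, t, t - 1950, bw_const) * 365.25,
                             1950, 1990, rel.tol = 1e-10)$value
  expect_equal(m_end, oracle, tolerance = 1e-3)
})

test_that("with all dynamic features off the simulator reproduces the closed form", {
  sc <- ref_scenario()
  body <- static_body(60, 0.30)  # adult plateau of the default growth model
  for (ch in list(chem_rapid(), chem_slow())) {
    ln <- build_lineage(1940, 1)
    tr <- simulate_lineage(ln, ch, sc, c(1940, 2000),
                           features = dynamic_features(FALSE, FALSE, FALSE))
    d <- tr$individuals[[1]]
    grid <- c(1950, 1965, 1970.5, 1985, 2000)
    dyn <- stats::approx(d$year, d$conc_ng_per_g_lipid, grid)$y
    sta <- concentration_static(body, ch, sc, 1940, grid)
    expect_equal(dyn, sta, tolerance = 1e-3)
  }
})

test_that("longer elimination half-life never lowers the concentration", {
  sc <- ref_scenario()
  halves <- c(2, 5, 10, 20)
  conc <- sapply(halves, function(el)
    dynamic_cstd(chemical_params(el), sc, 30, c(1995, 2020))$conc)
  for (r in 1:2)
    expect_true(all(diff(conc[r, ]) > 0))
})

test_that("breastfeeding moves chemical from mother to child and conserves mass without elimination", {
  sc <- ref_scenario()
  ch0 <- chemical_params(1e9, absorbed_fraction = 1)
  ln <- build_lineage(1950, 2)
  on <- simulate_lineage(ln, ch0, sc, c(1950, 1990),
                         features = dynamic_features(FALSE, TRUE, TRUE))
  off <- simulate_lineage(ln, ch0, sc, c(1950, 1990),
                          features = dynamic_features(FALSE, FALSE, TRUE))
  wean <- 1980 + ln$schedule$breastfeeding_duration
  at <- function(tr, i, t) stats::approx(tr$individuals[[i]]$year,
                                         tr$individuals[[i]]$burden_ng, t)$y
  # mother dips during lactation, child gains
  expect_lt(at(on, 1, wean), at(off, 1, wean))
  expect_gt(at(on, 2, wean), at(off, 2, wean))
  # total burden unchanged by the transfer
  total_on <- at(on, 1, 1990) + at(on, 2, 1990)
  total_off <- at(off, 1, 1990) + at(off, 2, 1990)
  expect_equal(total_on, total_off, tolerance = 1e-4)
})

test_that("in utero transfer equilibrates the newborn with the mother", {
  sc <- ref_scenario()
  ln <- build_lineage(1950, 2)
  tr <- simulate_lineage(ln, chem_slow(), sc, c(1950, 1990))
  mom <- tr$individuals[[1]]
  kid <- tr$individuals[[2]]
  c_mom <- stats::approx(mom$year, mom$conc_ng_per_g_lipid, 1980)$y
  expect_equal(kid$conc_ng_per_g_lipid[1], c_mom, tolerance = 1e-6)
  no_iu <- simulate_lineage(ln, chem_slow(), sc, c(1950, 1990),
                            features = dynamic_features(FALSE, TRUE, TRUE))
  expect_equal(no_iu$individuals[[2]]$burden_ng[1], 0)
})

test_that("CSTD extraction is deterministic and enforces exact-age matching", {
  sc <- ref_scenario()
  s1 <- dynamic_cstd(chem_rapid(), sc, 30, seq(1990, 2004, by = 2))
  s2 <- dynamic_cstd(chem_rapid(), sc, 30, seq(1990, 2004, by = 2))
  expect_identical(s1, s2)
  expect_equal(nrow(s1), 8)
  expect_true(all(s1$age == 30))
  # a lone lineage lacks a 30-year-old in off-cycle years
  ln <- build_lineage(1940, 2)
  tr <- simulate_lineage(ln, chem_rapid(), sc, c(1940, 2000))
  expect_error(extract_cstd(tr, 30, 1985), "nearest")
  near <- extract_cstd(tr, 30, 1985, nearest = TRUE)
  expect_equal(near$age, 45)  # older candidate preferred on ties
  expect_error(extract_cstd(tr, 30, 1920), "covers")
})

test_that("slowly eliminated chemicals decline more slowly than the intake trend, rapid ones track it", {
  sc <- ref_scenario()
  years <- seq(2040, 2080, by = 4)
  hl_rapid <- fitted_time(fit_loglinear(dynamic_cstd(chem_rapid(), sc, 30, years)))
  hl_slow <- fitted_time(fit_loglinear(dynamic_cstd(chem_slow(), sc, 30, years)))
  expect_equal(hl_rapid, 7, tolerance = 0.01)
  expect_gt(hl_slow, hl_rapid)
})
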