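test_that("log-linear fit recovers exact exponential trends", {
  yrs <- 2000:2012
  s <- cstd_series(yrs, 30, 80 * 2^(-(yrs - 2000) / 5))
  fit <- fit_loglinear(s)
  expect_equal(fit$half_life_or_doubling, 5, tolerance = 1e-12)
  expect_equal(fit$direction, "halving")
  expect_equal(fit$r_squared, 1)
  up <- cstd_series(yrs, 30, 3 * 2^((yrs - 2000) / 9))
  expect_equal(fit_loglinear(up)$half_life_or_doubling, 9, tolerance = 1e-12)
  expect_equal(fit_loglinear(up)$direction, "doubling")
})

test_that("a flat series reports an infinite half-life", {
  s <- cstd_series(2000:2010, 30, rep(4, 11))
  fit <- fit_loglinear(s)
  expect_identical(fit$half_life_or_doubling, Inf)
})

test_that("replicate years are pooled by geometric mean before fitting", {
  s_rep <- cstd_series(c(2000, 2000, 2001), 30, c(4, 16, 6))
  s_gm <- cstd_series(c(2000, 2001), 30, c(8, 6))
  expect_equal(coef(fit_loglinear(s_rep)), coef(fit_loglinear(s_gm)))
  # pooling off: each record enters the regression
  expect_equal(fit_loglinear(s_rep, pool_years = FALSE)$n_points, 3)
})

test_that("fit rejects unusable records and tiny windows", {
  s <- cstd_series(2000:2003, 30, c(5, -1, 0, 4))
  expect_warning(fit <- fit_loglinear(s), "rejected")
  expect_equal(fit$n_points, 2)
  expect_error(fit_loglinear(cstd_series(2000, 30, 5)), "at least 2")
  expect_error(suppressWarnings(fit_loglinear(cstd_series(2000:2001, 30, c(-1, -2)))),
               "at least 2")
})

test_that("sample-size weighting shifts the fit toward well-supported years", {
  yrs <- 2000:2006
  conc <- 10 * 2^(-(yrs - 2000) / 6) * exp(c(0.2, -0.1, 0, 0.15, -0.2, 0.1, 0))
  s <- cstd_series(yrs, 30, conc, n = c(100, 1, 1, 1, 1, 1, 100))
  fw <- fit_loglinear(s, weight_by_n = TRUE)
  fu <- fit_loglinear(s)
  expect_false(isTRUE(all.equal(fw$slope, fu$slope)))
})

test_that("period classification follows the ban year and elimination half-life", {
  yrs <- c(1969.9, 1970, 1975, 1980, 1985, 1999, 2010)
  s <- cstd_series(yrs, 30, rep(1, length(yrs)))
  p3 <- classify_periods(s, 1970, 3)
  expect_equal(as.character(p3$label),
               c("pre-ban", "transition", "transition", "post-ban",
                 "post-ban", "post-ban", "post-ban"))
  expect_equal(p3$transition_bounds, c(1970, 1980))
  p14 <- classify_periods(s, 1970, 14)  # transition lasts 2 x 14 = 28 y
  expect_equal(p14$transition_bounds, c(1970, 1998))
  expect_equal(sum(p14$label == "transition"), 4)
  pu <- classify_periods(s, 1970)  # unknown elimination half-life
  expect_true(pu$elim_unknown)
  expect_equal(pu$transition_bounds, c(1970, 1980))
})

test_that("fits overlapping the transition period carry a validity warning", {
  yrs <- 1972:1990
  s <- cstd_series(yrs, 30, 10 * 2^(-(yrs - 1972) / 12))
  p <- classify_periods(s, 1970, 3)
  fit <- fit_loglinear(s, periods = p)
  expect_match(fit$warnings, "transition", all = FALSE)
  post <- fit_loglinear(s, window = c(1981, 1990), periods = p)
  expect_length(post$warnings, 0)
})

test_that("age-concentration diagnostic runs only post-ban and flags real increases", {
  ages <- 20:45
  flat <- cstd_series(rep(2030, length(ages)), ages, rep(2, length(ages)))
  expect_error(age_trend_check(flat, "pre-ban"), "post-ban")
  expect_error(age_trend_check(flat, "transition"), "post-ban")
  expect_false(age_trend_check(flat, "post-ban")$flag)
  set.seed(11)
  rising <- cstd_series(rep(2030, length(ages)), ages,
                        exp(0.05 * ages + rnorm(length(ages), 0, 0.1)))
  chk <- age_trend_check(rising, "post-ban")
  expect_true(chk$flag)
  expect_gt(chk$slope, 0)
  # structural requirements
  two_years <- cstd_series(c(2030, 2031, 2030), 20:22, c(1, 1, 1))
  expect_error(age_trend_check(two_years, "post-ban"), "single sampling year")
  few <- cstd_series(rep(2030, 3), c(20, 20, 30), c(1, 1, 1))
  expect_error(age_trend_check(few, "post-ban"), "3 distinct ages")
})

test_that("trend objects expose standard modelling methods", {
  yrs <- 2000:2010
  s <- cstd_series(yrs, 30, 50 * 2^(-(yrs - 2000) / 4))
  fit <- fit_loglinear(s)
  expect_named(coef(fit), c("intercept", "slope"))
  expect_equal(unname(predict(fit, 2004)), 50 * 2^(-4 / 4), tolerance = 1e-10)
  expect_length(residuals(fit), 11)
  sm <- summary(fit)
  expect_equal(sm$t_half_cstd, 4, tolerance = 1e-12)
  expect_true(is.na(sm$t_double_cstd))
  out <- capture.output(print(sm))
  expect_true(any(grepl("halving", out)))
})
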