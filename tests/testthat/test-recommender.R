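# helper: an exact exponential series over a window, rising or falling,
# with its period labels for a 1970 ban
make_case <- function(years, direction = "falling", t_half_elim = NULL,
                      rate_years = 7) {
  conc <- if (direction == "falling") 10 * 2^(-(years - years[1]) / rate_years)
          else 0.1 * 2^((years - years[1]) / rate_years)
  s <- cstd_series(years, 30, conc)
  list(fit = fit_loglinear(s),
       periods = classify_periods(s, 1970, t_half_elim))
}

test_that("pre-ban rising trends are read as intake doubling times", {
  cs <- make_case(seq(1950, 1968, by = 2), "rising")
  v <- verdicts(recommendations(cs$fit, cs$periods))
  expect_equal(v$verdict[v$id == "R1"], "valid")
})

test_that("fits confined to the first decade after the ban are rejected", {
  cs <- make_case(1971:1979, "falling", t_half_elim = 3)
  v <- verdicts(recommendations(cs$fit, cs$periods, t_half_elim = 3,
                                t_half_in = 7))
  expect_equal(v$verdict[v$id == "R2"], "invalid")
})

test_that("late-transition fits are usable only for rapidly eliminated chemicals", {
  # elimination 7 y < intake halving 10 y; transition spans 1970-1984
  cs <- make_case(seq(1980, 1983, by = 1), "falling", t_half_elim = 7)
  v <- verdicts(recommendations(cs$fit, cs$periods, t_half_elim = 7,
                                t_half_in = 10))
  expect_equal(v$verdict[v$id == "R3"], "valid")
  expect_equal(v$verdict[v$id == "R4"], "valid")
  # slow eliminator: whole transition off-limits
  slow <- make_case(seq(1985, 1995, by = 2), "falling", t_half_elim = 14)
  vs <- verdicts(recommendations(slow$fit, slow$periods, t_half_elim = 14,
                                 t_half_in = 7))
  expect_equal(vs$verdict[vs$id == "R2"], "invalid")
  # unknown ordering: caution
  vu <- verdicts(recommendations(slow$fit, slow$periods, t_half_elim = 14))
  expect_equal(vu$verdict[vu$id == "R2"], "caution")
})

test_that("post-ban verdicts depend on the half-life ordering and the age flag", {
  rapid <- make_case(seq(1990, 2010, by = 2), "falling", t_half_elim = 3)
  v <- verdicts(recommendations(rapid$fit, rapid$periods, t_half_elim = 3,
                                t_half_in = 7))
  expect_setequal(v$id, c("R3", "R4"))
  expect_true(all(v$verdict == "valid"))
  # slower elimination than intake decline -> tool forbidden
  slow <- make_case(seq(2000, 2020, by = 2), "falling", t_half_elim = 14)
  vs <- verdicts(recommendations(slow$fit, slow$periods, t_half_elim = 14,
                                 t_half_in = 7))
  expect_equal(vs$verdict[vs$id == "R5"], "invalid")
  # a raised age flag forbids the tool even when elimination looks rapid
  vf <- verdicts(recommendations(rapid$fit, rapid$periods, t_half_elim = 3,
                                 t_half_in = 7, age_flag = TRUE))
  expect_equal(vf$verdict[vf$id == "R5"], "invalid")
  # long elimination half-life alone (>= 10 y) forbids the tool
  vlong <- verdicts(recommendations(slow$fit, slow$periods, t_half_elim = 12,
                                    t_half_in = 20))
  expect_equal(vlong$verdict[vlong$id == "R5"], "invalid")
  # nothing known: upper-limit reading only
  vu <- verdicts(recommendations(slow$fit, slow$periods))
  expect_equal(vu$verdict[vu$id == "R5"], "caution")
})

test_that("an unknown intake halving time is proxied by its upper limit, downgrading verdicts", {
  rapid <- make_case(seq(1990, 2010, by = 2), "falling", t_half_elim = 3)
  v <- verdicts(recommendations(rapid$fit, rapid$periods, t_half_elim = 3))
  expect_true(all(v$verdict[v$id %in% c("R3", "R4")] == "caution"))
})

test_that("windows mixing periods are flagged for splitting", {
  cs <- make_case(seq(1960, 2000, by = 5), "falling", t_half_elim = 3)
  rec <- recommendations(cs$fit, cs$periods, t_half_elim = 3, t_half_in = 7)
  v <- verdicts(rec)
  expect_true("caution" %in% v$verdict)
  expect_match(rec$recommendations[[1]]$rationale, "split")
})

test_that("every period x ordering x age-flag combination yields a defined verdict", {
  windows <- list(pre = seq(1950, 1965, by = 5),
                  transition_early = 1971:1979,
                  transition_late = 1985:1995,
                  post = seq(2000, 2020, by = 5))
  elims <- list(3, 14, NULL)
  tins <- list(7, NULL)
  flags <- list(TRUE, FALSE, NULL)
  for (wn in names(windows)) {
    dirn <- if (wn == "pre") "rising" else "falling"
    for (el in elims) for (tin in tins) for (fl in flags) {
      cs <- make_case(windows[[wn]], dirn, t_half_elim = el)
      rec <- recommendations(cs$fit, cs$periods, t_half_elim = el,
                             t_half_in = tin, age_flag = fl)
      v <- verdicts(rec)
      expect_gte(nrow(v), 1)
      expect_true(all(v$verdict %in% c("valid", "invalid", "caution")))
      expect_true(all(v$id %in% paste0("R", 1:5)))
    }
  }
})

test_that("reports never present the CSTD half-life as an elimination half-life", {
  cs <- make_case(seq(2000, 2020, by = 2), "falling", t_half_elim = 14)
  rec <- recommendations(cs$fit, cs$periods, t_half_elim = 14, t_half_in = 7)
  expect_match(rec$note, "never equals")
  out <- capture.output(print(cs$fit))
  # the fitted quantity is labelled an apparent CSTD time, never elimination
  expect_false(any(grepl("elimination", out, ignore.case = TRUE)))
  expect_true(any(grepl("apparent CSTD", out)))
})
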