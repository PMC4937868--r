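#' Cross-sectional trend data (CSTD) series
#'
#' The container every fitting routine consumes: one record per pooled
#' sample, with the sampling year, the donors' age, the lipid-normalized
#' concentration (ng/g lipid) and an optional sample size.
#'
#' @param year Sampling year(s), decimal calendar years.
#' @param age Donor age(s) in years.
#' @param conc Lipid-normalized concentration(s), ng/g lipid.
#' @param n Optional sample size(s) per record.
#' @return A data frame of class `cstd_series` with columns `year`, `age`,
#'   `conc`, `n`.
#' @export
cstd_series <- function(year, age, conc, n = NA_real_) {
  stopifnot(length(year) == length(conc))
  df <- data.frame(year = as.numeric(year),
                   age = rep_len(as.numeric(age), length(year)),
                   conc = as.numeric(conc),
                   n = rep_len(as.numeric(n), length(year)))
  class(df) <- c("cstd_series", "data.frame")
  df
}

#' @export
print.cstd_series <- function(x, ...) {
  cat(sprintf("CSTD series: %d records, years %.4g-%.4g, conc %.3g-%.3g ng/g lipid\n",
              nrow(x), min(x$year), max(x$year), min(x$conc), max(x$conc)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Intake time series
#'
#' Tabulated population intake estimates (e.g. from total diet studies):
#' ng/kg body weight/day by year. Interpolation between records is
#' log-linear, i.e. piecewise exponential, matching the exponential-trend
#' convention used throughout; extrapolation beyond either end reuses the
#' terminal log-slope.
#'
#' @param year Ascending years.
#' @param intake Intakes, ng/kg bw/day, strictly positive.
#' @return Data frame of class `intake_series` with columns `year`, `intake`.
#' @export
intake_series <- function(year, intake) {
  stopifnot(length(year) == length(intake))
  if (is.unsorted(year, strictly = TRUE)) stop("years must be strictly ascending")
  if (any(intake <= 0)) stop("intakes must be strictly positive")
  df <- data.frame(year = as.numeric(year), intake = as.numeric(intake))
  class(df) <- c("intake_series", "data.frame")
  df
}

#' @export
print.intake_series <- function(x, ...) {
  cat(sprintf("Intake series: %d records, years %.4g-%.4g, %.3g-%.3g ng/kg bw/day\n",
              nrow(x), min(x$year), max(x$year), min(x$intake), max(x$intake)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Evaluate an intake series at arbitrary years (log-linear interpolation)
#'
#' @param intake An [intake_series()].
#' @param year Years at which to evaluate (vectorized).
#' @param warn_extrapolation Warn when `year` falls outside the tabulated
#'   range (the terminal log-slope is then extended).
#' @return Intake(s) in ng/kg bw/day.
#' @export
intake_at <- function(intake, year, warn_extrapolation = TRUE) {
  stopifnot(inherits(intake, "intake_series"))
  yr <- intake$year
  li <- log(intake$intake)
  outside <- year < yr[1] | year > yr[length(yr)]
  if (warn_extrapolation && any(outside))
    warning(sprintf(
      "intake series extrapolated log-linearly outside [%s, %s] for %d year(s)",
      format(yr[1]), format(yr[length(yr)]), sum(outside)))
  if (length(yr) == 1) return(rep(intake$intake, length(year)))
  n <- length(yr)
  # linear interpolation of log-intake; linear extrapolation with end slopes
  val <- stats::approx(yr, li, xout = pmin(pmax(year, yr[1]), yr[n]))$y
  s1 <- (li[2] - li[1]) / (yr[2] - yr[1])
  s2 <- (li[n] - li[n - 1]) / (yr[n] - yr[n - 1])
  lo <- year < yr[1]
  hi <- year > yr[n]
  val[lo] <- li[1] + s1 * (year[lo] - yr[1])
  val[hi] <- li[n] + s2 * (year[hi] - yr[n])
  exp(val)
}

#' Write / read CSTD and intake tables as CSV
#'
#' The on-disk schema is `year, age, conc_ng_per_g_lipid, n` for CSTD and
#' `year, intake_ng_per_kg_bw_per_day` for intake series.
#'
#' @param x A `cstd_series` or `intake_series`.
#' @param path File path.
#' @return `write_*` return `path` invisibly; `read_*` return the parsed
#'   object.
#' @export
write_cstd <- function(x, path) {
  stopifnot(inherits(x, "cstd_series"))
  out <- data.frame(year = x$year, age = x$age,
                    conc_ng_per_g_lipid = x$conc, n = x$n)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cstd
#' @export
read_cstd <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "age", "conc_ng_per_g_lipid")
  if (!all(need %in% names(df)))
    stop("CSTD CSV must have columns year, age, conc_ng_per_g_lipid[, n]")
  cstd_series(df$year, df$age, df$conc_ng_per_g_lipid,
              if ("n" %in% names(df)) df$n else NA_real_)
}

#' @rdname write_cstd
#' @export
write_intake <- function(x, path) {
  stopifnot(inherits(x, "intake_series"))
  out <- data.frame(year = x$year, intake_ng_per_kg_bw_per_day = x$intake)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cstd
#' @export
read_intake <- function(path) {
  df <- utils::read.csv(path)
  need <- c("year", "intake_ng_per_kg_bw_per_day")
  if (!all(need %in% names(df)))
    stop("intake CSV must have columns year, intake_ng_per_kg_bw_per_day")
  intake_series(df$year, df$intake_ng_per_kg_bw_per_day)
}
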