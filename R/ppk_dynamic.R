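#' Feature switches of the dynamic PPK model
#'
#' The dynamic model differs from the static one by four processes:
#' in-utero transfer, breastfeeding transfer, and age-dependent body and
#' lipid weight. Each can be switched off; with all three flags off (body
#' and lipid growth share one flag) the simulator reduces to the static
#' model, which is used as an analytic oracle in the test-suite.
#'
#' @param in_utero Newborns start at the mother's lipid-normalized
#'   concentration (TRUE) or at zero (FALSE).
#' @param breastfeeding Transfer of chemical in milk lipid from mother to
#'   child during lactation.
#' @param growth Use the lineage's age-dependent growth curves (TRUE) or a
#'   constant adult body (the growth model's final anchors) for the whole
#'   life (FALSE).
#' @return A named list of class `dynamic_features`.
#' @export
dynamic_features <- function(in_utero = TRUE, breastfeeding = TRUE,
                             growth = TRUE) {
  structure(list(in_utero = isTRUE(in_utero),
                 breastfeeding = isTRUE(breastfeeding),
                 growth = isTRUE(growth)),
            class = "dynamic_features")
}

# Grid from t0 to t1 with step h plus event knots (ban year, lactation
# boundaries) inserted so every RK4 step sees smooth forcing.
.time_grid <- function(t0, t1, h, events = numeric(0)) {
  g <- seq(t0, t1, by = h)
  if (g[length(g)] < t1) g <- c(g, t1)
  ev <- events[events > t0 & events < t1]
  sort(unique(c(g, ev)))
}

# One individual's integration. a(t) = absorbed input rate (ng/year),
# b(t) = loss rate constant (1/year, elimination + lactation output).
# Supplied per step (left node, midpoint, right node) so that on/off
# forcing such as lactation, whose boundaries are grid knots, is constant
# within each step.
.rk4_linear <- function(grid, m0, aL, bL, aM, bM, aR, bR) {
  n <- length(grid)
  m <- numeric(n)
  m[1] <- m0
  floored <- 0L
  for (i in seq_len(n - 1)) {
    h <- grid[i + 1] - grid[i]
    a0 <- aL[i];  b0 <- bL[i]
    am <- aM[i];  bm <- bM[i]
    a1 <- aR[i];  b1 <- bR[i]
    y <- m[i]
    k1 <- a0 - b0 * y
    k2 <- am - bm * (y + 0.5 * h * k1)
    k3 <- am - bm * (y + 0.5 * h * k2)
    k4 <- a1 - b1 * (y + h * k3)
    y1 <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(y1))
      stop(sprintf("integration diverged at year %.3f (burden %g)",
                   grid[i + 1], y1))
    if (y1 < 0) {
      if (y1 < -1e-6 * max(abs(m[seq_len(i)]), 1))
        stop(sprintf("burden went negative beyond tolerance at year %.3f",
                     grid[i + 1]))
      y1 <- 0
      floored <- floored + 1L
    }
    m[i + 1] <- y1
  }
  list(m = m, floored = floored)
}

#' Simulate body-burden trajectories for a whole lineage
#'
#' Integrates, generation by generation, the one-compartment mass balance
#' of each lineage member:
#' \deqn{dm/dt = f_{abs} I(t, a) - k_{elim} m - 1_{lactating} \frac{m}{L(a)} r_{milk},}
#' where `m` is the body burden (ng), `I` the gross dietary intake
#' (ng/day, converted to ng/year), `L(a)` the body lipid mass (g) at age
#' `a`, and `r_milk` the milk lipid output (g/day). While a child is
#' breastfed it receives the mother's lactation output times the absorbed
#' fraction (milk lipid is assumed in equilibrium with the mother's body
#' lipid, so the mother's gross output equals the child's gross milk-borne
#' intake at every instant). With in-utero transfer on, a newborn starts
#' at the mother's lipid-normalized concentration at delivery.
#'
#' Integration is a fixed-step 4th-order Runge-Kutta scheme (default step
#' 1/52 year, resolving the 6-month lactation window) on a grid with knots
#' inserted at the ban year and lactation boundaries so each step sees
#' smooth forcing. Burdens are floored at zero; floor events are counted
#' in the result.
#'
#' @param lineage A [build_lineage()] result.
#' @param chem A [chemical_params()].
#' @param scenario An [exposure_scenario()].
#' @param window Length-2 numeric: simulate each member from birth to
#'   `window[2]` (members born after `window[2]` are skipped).
#' @param features A [dynamic_features()] list.
#' @param step Integration step, years.
#' @return Object of class `ppk_trajectories`: per-individual data frames
#'   with columns `year`, `age`, `burden_ng`, `conc_ng_per_g_lipid`.
#' @examples
#' ln <- build_lineage(1940, 2)
#' sc <- exposure_scenario(1970, 7, 7)
#' tr <- simulate_lineage(ln, chemical_params(3), sc, window = c(1940, 2005))
#' tr
#' @export
simulate_lineage <- function(lineage, chem, scenario, window,
                             features = dynamic_features(), step = 1 / 52) {
  stopifnot(inherits(lineage, "lineage"), inherits(chem, "chemical_params"),
            inherits(scenario, "exposure_scenario"))
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be an increasing pair of years")
  sched <- lineage$schedule
  growth <- lineage$growth
  if (!features$growth) {
    nlast <- length(growth$anchor_ages)
    growth <- constant_growth(growth$body_weight[nlast],
                              growth$lipid_fraction[nlast])
  }
  births <- lineage$birth_years
  t_end <- window[2]
  n_ind <- length(births)
  milk_rate <- sched$milk_lipid_output * .DAYS_PER_YEAR  # g lipid / year
  f_abs <- chem$absorbed_fraction

  individuals <- vector("list", n_ind)
  conc_fun <- vector("list", n_ind)   # linear interpolators of C(t)
  floored_total <- 0L

  for (i in seq_len(n_ind)) {
    t0 <- births[i]
    if (t0 >= t_end) break
    cb <- if (i < n_ind) births[i + 1] else NA_real_
    events <- c(scenario$ban_year,
                if (i < n_ind) c(cb, cb + sched$breastfeeding_duration),
                t0 + sched$breastfeeding_duration)
    grid <- .time_grid(t0, t_end, step, events)
    mids <- (grid[-1] + grid[-length(grid)]) / 2

    # tt: evaluation times; ind: times deciding on/off forcing (the step
    # midpoint for all three stage times, so each step sees constant
    # lactation status; boundaries are grid knots)
    eval_ab <- function(tt, ind) {
      age <- tt - t0
      bw <- body_weight(growth, age)
      lm <- lipid_mass(growth, age)
      a <- f_abs * intake_rate(scenario, tt, age, bw) * .DAYS_PER_YEAR
      b <- rep(chem$k_elim, length(tt))
      if (features$breastfeeding && sched$breastfeeding_duration > 0) {
        # lactation output (mother role)
        if (i < n_ind && !is.na(cb)) {
          lact <- ind >= cb & ind < cb + sched$breastfeeding_duration
          b[lact] <- b[lact] + milk_rate / lm[lact]
        }
        # milk input (child role)
        if (i > 1 && !is.null(conc_fun[[i - 1]])) {
          fed <- ind >= t0 & ind < t0 + sched$breastfeeding_duration
          if (any(fed))
            a[fed] <- a[fed] + f_abs * conc_fun[[i - 1]](tt[fed]) * milk_rate
        }
      }
      list(a = a, b = b)
    }

    left <- eval_ab(grid[-length(grid)], mids)
    midv <- eval_ab(mids, mids)
    right <- eval_ab(grid[-1], mids)

    m0 <- 0
    if (features$in_utero && i > 1 && !is.null(conc_fun[[i - 1]]))
      m0 <- conc_fun[[i - 1]](t0) * lipid_mass(growth, 0)

    sol <- .rk4_linear(grid, m0, left$a, left$b, midv$a, midv$b,
                       right$a, right$b)
    floored_total <- floored_total + sol$floored
    age <- grid - t0
    lm <- lipid_mass(growth, age)
    conc <- sol$m / lm
    individuals[[i]] <- data.frame(
      year = grid, age = age, burden_ng = sol$m,
      conc_ng_per_g_lipid = conc)
    conc_fun[[i]] <- stats::approxfun(grid, conc, rule = 2)
  }

  structure(
    list(lineage = lineage, chem = chem, scenario = scenario,
         features = features, step = step, window = window,
         individuals = individuals, floor_events = floored_total),
    class = "ppk_trajectories"
  )
}

#' @export
print.ppk_trajectories <- function(x, ...) {
  done <- sum(!vapply(x$individuals, is.null, logical(1)))
  cat(sprintf(
    "Dynamic PPK trajectories: %d individual(s), window %.4g-%.4g, step %.4g y\n",
    done, x$window[1], x$window[2], x$step))
  cat(sprintf("  features: in_utero=%s, breastfeeding=%s, growth=%s; %d floor event(s)\n",
              x$features$in_utero, x$features$breastfeeding, x$features$growth,
              x$floor_events))
  invisible(x)
}

#' Plot lineage trajectories
#'
#' Lipid-normalized concentration against calendar year, one line per
#' lineage member.
#'
#' @param x A `ppk_trajectories` object.
#' @param log Plot concentrations on a log axis (default TRUE).
#' @param ... Passed to [graphics::matplot()]-style plotting.
#' @export
plot.ppk_trajectories <- function(x, log = TRUE, ...) {
  ind <- Filter(Negate(is.null), x$individuals)
  if (!length(ind)) stop("nothing to plot")
  rng_y <- range(unlist(lapply(ind, function(d) d$year)))
  pos <- unlist(lapply(ind, function(d) d$conc_ng_per_g_lipid))
  pos <- pos[pos > 0]
  graphics::plot(NA, xlim = rng_y, ylim = range(pos),
                 log = if (log) "y" else "",
                 xlab = "year", ylab = "concentration (ng/g lipid)", ...)
  for (k in seq_along(ind))
    graphics::lines(ind[[k]]$year, ind[[k]]$conc_ng_per_g_lipid, col = k)
  invisible(x)
}

#' Extract cross-sectional trend data from simulated trajectories
#'
#' For each requested sampling year, reads the lipid-normalized
#' concentration of the lineage member whose age equals `target_age` at
#' that instant (milk lipid is assumed in equilibrium with body lipid, so
#' this is also the milk concentration for a lactating mother). Without
#' an exact-age member the call fails unless `nearest = TRUE`, in which
#' case the closest-aged (ties toward older) member is used and the actual
#' age is recorded.
#'
#' @param trajectories A [simulate_lineage()] result, or a list of them.
#' @param target_age Age at sampling, years.
#' @param sampling_years Sampling years.
#' @param nearest Allow nearest-age fallback (default FALSE).
#' @param tol Age tolerance for an exact match, years.
#' @return A [cstd_series()].
#' @export
extract_cstd <- function(trajectories, target_age, sampling_years,
                         nearest = FALSE, tol = 1e-6) {
  trs <- if (inherits(trajectories, "ppk_trajectories")) list(trajectories)
         else trajectories
  stopifnot(all(vapply(trs, inherits, logical(1), "ppk_trajectories")))
  year <- conc <- age_out <- numeric(length(sampling_years))
  for (j in seq_along(sampling_years)) {
    ys <- sampling_years[j]
    best <- NULL
    for (tr in trs) {
      births <- tr$lineage$birth_years
      for (i in seq_along(tr$individuals)) {
        d <- tr$individuals[[i]]
        if (is.null(d)) next
        if (ys < d$year[1] || ys > d$year[nrow(d)]) next
        a <- ys - births[i]
        dev <- abs(a - target_age)
        if (is.null(best) || dev < best$dev - tol ||
            (dev < best$dev + tol && a > best$age))
          best <- list(dev = dev, age = a, data = d)
      }
    }
    if (is.null(best))
      stop(sprintf("no simulated individual covers sampling year %s",
                   format(ys)))
    if (best$dev > tol && !nearest)
      stop(sprintf(
        "no individual of age %.4g in year %s (closest age %.4g); set nearest = TRUE to allow",
        target_age, format(ys), best$age))
    year[j] <- ys
    age_out[j] <- best$age
    conc[j] <- stats::approx(best$data$year, best$data$conc_ng_per_g_lipid,
                             xout = ys)$y
  }
  cstd_series(year, age_out, conc)
}

# Group sampling years so that years whose sampled-individual birth years
# differ by a multiple of the childbirth age share one lineage (the chain
# then contains an exact-age member for each of them).
.lineage_plan <- function(targets, target_age, n_generations, g) {
  birth_needed <- targets - target_age
  key <- round((birth_needed %% g) / 1e-9) * 1e-9
  split(seq_along(targets), format(key, digits = 15))
}

#' Dynamic-model CSTD for a cross-sectional sampling design
#'
#' Convenience wrapper around [build_lineage()], [simulate_lineage()] and
#' [extract_cstd()]: for every sampling year it guarantees a lineage
#' member of exactly `target_age`, each with at least
#' `n_generations - 1` simulated ancestors so that the transgenerationally
#' inherited burden has converged (the mother-to-child concentration
#' carry-over per generation is a few percent, so four generations are
#' ample).
#'
#' @inheritParams simulate_lineage
#' @param target_age Age of the sampled individuals, years.
#' @param sampling_years Sampling years.
#' @param n_generations Minimum number of simulated ancestor generations
#'   (including the sampled one).
#' @param schedule A [reproduction_schedule()].
#' @param growth A [growth_model()].
#' @return A [cstd_series()].
#' @examples
#' sc <- exposure_scenario(1970, 7, 7)
#' dynamic_cstd(chemical_params(3), sc, 30, c(1990, 2000, 2010))
#' @export
dynamic_cstd <- function(chem, scenario, target_age, sampling_years,
                         n_generations = 4,
                         schedule = reproduction_schedule(),
                         growth = growth_model(),
                         features = dynamic_features(), step = 1 / 52) {
  g <- schedule$age_at_childbirth
  plan <- .lineage_plan(sampling_years, target_age, n_generations, g)
  out <- vector("list", length(plan))
  for (k in seq_along(plan)) {
    idx <- plan[[k]]
    births <- sampling_years[idx] - target_age
    founder <- min(births) - (n_generations - 1) * g
    n_gen <- round((max(births) - founder) / g) + 1
    ln <- build_lineage(founder, n_gen, schedule, growth)
    tr <- simulate_lineage(ln, chem, scenario,
                           window = c(founder, max(sampling_years[idx])),
                           features = features, step = step)
    out[[k]] <- cbind(idx = idx,
                      extract_cstd(tr, target_age, sampling_years[idx]))
  }
  all <- do.call(rbind, out)
  all <- all[order(all$idx), ]
  cstd_series(all$year, all$age, all$conc)
}

#' Dynamic-model age cross-section in one sampling year
#'
#' Simulates individuals of several ages all sampled in the same calendar
#' year — the input of the age-concentration diagnostic for slow
#' eliminators ([age_trend_check()]).
#'
#' @inheritParams dynamic_cstd
#' @param ages Ages sampled, years.
#' @param sampling_year Single calendar year.
#' @return A [cstd_series()] with one record per age.
#' @export
dynamic_cross_section <- function(chem, scenario, ages, sampling_year,
                                  n_generations = 4,
                                  schedule = reproduction_schedule(),
                                  growth = growth_model(),
                                  features = dynamic_features(),
                                  step = 1 / 52) {
  recs <- lapply(ages, function(a) {
    s <- dynamic_cstd(chem, scenario, a, sampling_year,
                      n_generations = n_generations, schedule = schedule,
                      growth = growth, features = features, step = step)
    s
  })
  all <- do.call(rbind, recs)
  cstd_series(all$year, all$age, all$conc)
}
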