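#' Parameter bundles for the synthetic-rate generator
#'
#' `schedule_params()` describes one period's vital rates by interpretable
#' summary parameters: the total fertility rate (births per woman), the mean
#' age at childbearing and the spread of the fertility schedule (years), the
#' target life expectancy at birth (years) and the shape of the
#' Gompertz-Makeham hazard (age slope per year, background level per year).
#' `trend_params()` describes one synthetic location: start and end
#' schedules, a logistic transition between them, and the random-walk
#' innovation scale used to fan out stochastic future trajectories around
#' the median path (emulating the structure of probabilistic demographic
#' projection ensembles).
#'
#' @param tfr Births per woman (both sexes), `>= 0`.
#' @param mean_age_childbearing Mean age of the fertility schedule, years.
#' @param fertility_width Standard deviation of the schedule, years.
#' @param life_expectancy_target Female life expectancy at birth, years.
#' @param gompertz_slope Exponential age slope of the senescent hazard.
#' @param makeham_level Age-independent background hazard.
#' @param male_e0_gap Female-minus-male gap in life expectancy, years.
#' @return A `schedule_params` list.
#' @export
schedule_params <- function(tfr = 2, mean_age_childbearing = 28,
                            fertility_width = 6.5,
                            life_expectancy_target = 75,
                            gompertz_slope = 0.11, makeham_level = 0.0015,
                            male_e0_gap = 4) {
  stopifnot(tfr >= 0,
            mean_age_childbearing > 10, mean_age_childbearing < 55,
            life_expectancy_target > 20, life_expectancy_target < 110,
            fertility_width > 0, gompertz_slope > 0, makeham_level >= 0)
  structure(as.list(environment()), class = "schedule_params")
}

#' @rdname schedule_params
#' @param start,end `schedule_params` at the beginning and end of the
#'   transition.
#' @param midpoint_year Calendar year at which the logistic transition is
#'   halfway.
#' @param transition_speed Logistic time scale in years (larger = slower).
#' @param trajectory_noise Innovation SD per 5-y step of the random walks on
#'   log-TFR and the log mortality gap.
#' @param n_trajectories Number of sampled future trajectories.
#' @param present_year Trajectories coincide with the median path up to and
#'   including this year and branch after it.
#' @param pop_scale Female population size used when scaling the stable
#'   structure into population counts.
#' @export
trend_params <- function(start, end = start, midpoint_year = 2000,
                         transition_speed = 20, trajectory_noise = 0.05,
                         n_trajectories = 1000, present_year = 2020,
                         pop_scale = 1e5) {
  stopifnot(inherits(start, "schedule_params"),
            inherits(end, "schedule_params"),
            n_trajectories >= 1, trajectory_noise >= 0,
            transition_speed > 0, pop_scale > 0)
  structure(list(start = start, end = end, midpoint_year = midpoint_year,
                 transition_speed = transition_speed,
                 trajectory_noise = trajectory_noise,
                 n_trajectories = as.integer(n_trajectories),
                 present_year = present_year, pop_scale = pop_scale),
            class = "trend_params")
}

#' Generate a unimodal fertility schedule
#'
#' Builds a smooth age-specific fertility schedule with the requested total
#' fertility rate and mean age at childbearing: a scaled beta density over
#' the reproductive span (ages 10-55), discretised to the grid, with class
#' rates normalised so the per-step rates sum exactly to `tfr`.
#'
#' @param p A [schedule_params()].
#' @param grid An [age_grid()].
#' @return A [fertility_schedule()] (per-step rates).
#' @export
make_fertility <- function(p, grid = age_grid(), frac_female = 100 / 205) {
  stopifnot(inherits(p, "schedule_params"))
  omega <- grid$n_classes
  if (p$tfr == 0) {
    return(fertility_schedule(numeric(omega), frac_female))
  }
  lo <- 10
  hi <- 55
  m <- (p$mean_age_childbearing - lo) / (hi - lo)
  v <- (p$fertility_width / (hi - lo))^2
  v <- min(v, 0.95 * m * (1 - m))  # beta feasibility
  k <- m * (1 - m) / v - 1
  a <- m * k
  b <- (1 - m) * k
  bounds <- c(grid$lower_bounds, grid$lower_bounds[omega] + grid$step_years)
  z <- pmin(pmax((bounds - lo) / (hi - lo), 0), 1)
  mass <- diff(stats::pbeta(z, a, b))
  f <- p$tfr * mass / sum(mass)
  fertility_schedule(f, frac_female)
}

#' @rdname make_fertility
#' @param frac_female Proportion of births that are female.
NULL

# internal: survivor curve of a Gompertz-Makeham hazard on a fine age grid
gm_survivor <- function(age, M, C, beta) {
  exp(-M * age - (C / beta) * (exp(beta * age) - 1))
}

# internal: life expectancy at birth for given hazard parameters
gm_e0 <- function(M, C, beta, max_age = 130, da = 0.25) {
  a <- seq(0, max_age, by = da)
  l <- gm_survivor(a, M, C, beta)
  sum((l[-1] + l[-length(l)]) / 2) * da
}

#' Generate a mortality schedule from a Gompertz-Makeham law
#'
#' The hazard is `h(a) = makeham_level + C * exp(gompertz_slope * a)`, with
#' `C` calibrated by root-finding so that life expectancy at birth on the
#' grid matches the target within 0.25 years. Per-step survival
#' probabilities come from the life-table person-years of the fitted curve,
#' `p[x] = L[x+1] / L[x]`, with `p = 0` out of the open-ended class. Male
#' schedules target `life_expectancy_target - male_e0_gap`.
#'
#' @param p A [schedule_params()].
#' @param grid An [age_grid()].
#' @param sex `"female"` or `"male"`.
#' @return A [mortality_schedule()] carrying its Lx column.
#' @export
make_mortality <- function(p, grid = age_grid(), sex = c("female", "male")) {
  stopifnot(inherits(p, "schedule_params"))
  sex <- match.arg(sex)
  target <- p$life_expectancy_target - if (sex == "male") p$male_e0_gap else 0
  M <- p$makeham_level
  beta <- p$gompertz_slope
  gap <- function(logC) gm_e0(M, 10^logC, beta) - target
  lo <- -14
  hi <- 2
  if (gap(lo) < 0 || gap(hi) > 0) {
    stop("mortality calibration error: life expectancy target ", target,
         " y unattainable with this hazard shape", call. = FALSE)
  }
  root <- stats::uniroot(gap, c(lo, hi), tol = 1e-6)
  C <- 10^root$root
  step <- grid$step_years
  omega <- grid$n_classes
  da <- 0.25
  Lx <- numeric(omega)
  for (x in seq_len(omega)) {
    lo_a <- grid$lower_bounds[x]
    hi_a <- if (x < omega) lo_a + step else 130
    a <- seq(lo_a, hi_a, by = da)
    l <- gm_survivor(a, M, C, beta)
    Lx[x] <- sum((l[-1] + l[-length(l)]) / 2) * da
  }
  conv <- annual_to_step_rates(numeric(omega), Lx, grid, sex)
  conv$mortality
}

# internal: schedule_params interpolated along the logistic transition
interp_params <- function(tp, year) {
  s <- 1 / (1 + exp(-(year - tp$midpoint_year) / tp$transition_speed))
  mix <- function(field) tp$start[[field]] + s * (tp$end[[field]] - tp$start[[field]])
  schedule_params(
    tfr = mix("tfr"),
    mean_age_childbearing = mix("mean_age_childbearing"),
    fertility_width = mix("fertility_width"),
    life_expectancy_target = mix("life_expectancy_target"),
    gompertz_slope = mix("gompertz_slope"),
    makeham_level = mix("makeham_level"),
    male_e0_gap = mix("male_e0_gap")
  )
}

# internal: all schedule columns for one year's params
schedule_cols <- function(pj, grid, frac_female, pop_scale) {
  fs <- make_fertility(pj, grid, frac_female)
  mf <- make_mortality(pj, grid, "female")
  mm <- make_mortality(pj, grid, "male")
  st <- stable_structures(fs$f, mf$p, mm$p, frac_female)
  list(fert = fs$f, surv_f = mf$p, surv_m = mm$p,
       Lx_f = mf$Lx, Lx_m = mm$Lx,
       pop_f = st$w_f / sum(st$w_f) * pop_scale,
       pop_m = st$w_m / sum(st$w_f) * pop_scale *
         (1 - frac_female) / frac_female)
}

# internal: one full rate_series from a per-year list of schedule_params;
# `template` + `recompute` allow rebuilding only the perturbed columns
series_from_params <- function(params_by_year, grid, years, location,
                               pop_scale, frac_female = 100 / 205,
                               template = NULL, recompute = NULL) {
  omega <- grid$n_classes
  nt <- length(years)
  fields <- c("fert", "surv_f", "surv_m", "pop_f", "pop_m", "Lx_f", "Lx_m")
  if (is.null(template)) {
    mats <- stats::setNames(replicate(length(fields),
                                      matrix(0, omega, nt),
                                      simplify = FALSE), fields)
    recompute <- seq_len(nt)
  } else {
    mats <- lapply(stats::setNames(fields, fields),
                   function(fl) template[[fl]])
  }
  for (j in recompute) {
    cols <- schedule_cols(params_by_year[[j]], grid, frac_female, pop_scale)
    for (fl in fields) mats[[fl]][, j] <- cols[[fl]]
  }
  new_rate_series(location, grid, years, frac_female, mats$fert,
                  mats$surv_f, mats$surv_m, mats$pop_f, mats$pop_m,
                  mats$Lx_f, mats$Lx_m)
}

#' Generate the median rate path of a synthetic location
#'
#' Interpolates the start and end [schedule_params()] of a [trend_params()]
#' along a logistic transition and builds a full `rate_series`: fertility
#' and mortality schedules per period, with population structure set to the
#' period-stable structure implied by each year's rates.
#'
#' @param tp A [trend_params()].
#' @param grid An [age_grid()].
#' @param years Calendar years at `grid$step_years` spacing.
#' @param location Location label attached to the series.
#' @return A `rate_series`.
#' @export
make_rate_series <- function(tp, grid = age_grid(),
                             years = seq(1950, 2100, by = grid$step_years),
                             location = "synthetic") {
  stopifnot(inherits(tp, "trend_params"))
  params <- lapply(years, function(y) interp_params(tp, y))
  series_from_params(params, grid, years, location, tp$pop_scale)
}

#' Sample an ensemble of stochastic future rate trajectories
#'
#' Emulates probabilistic demographic projections: every trajectory shares
#' the median path up to `tp$present_year` and then perturbs it by seeded
#' random walks on log-TFR and on the log mortality gap
#' `log(110 - e0)` (so trajectories fan out with horizon while life
#' expectancy stays below 110 y). Schedules are rebuilt from the perturbed
#' parameters, so every trajectory is a fully valid `rate_series`.
#'
#' @inheritParams make_rate_series
#' @param seed Integer seed; the ensemble is a pure function of
#'   (parameters, seed).
#' @return A `trajectory_ensemble`: list with the `median` series, the list
#'   `trajectories`, and the generating parameters.
#' @export
sample_trajectories <- function(tp, grid = age_grid(),
                                years = seq(1950, 2100, by = grid$step_years),
                                seed = 1, location = "synthetic") {
  stopifnot(inherits(tp, "trend_params"))
  median_params <- lapply(years, function(y) interp_params(tp, y))
  median_series <- series_from_params(median_params, grid, years, location,
                                      tp$pop_scale)
  future <- which(years > tp$present_year)
  set.seed(seed)
  trajectories <- vector("list", tp$n_trajectories)
  for (k in seq_len(tp$n_trajectories)) {
    pk <- median_params
    if (length(future) && tp$trajectory_noise > 0) {
      z_tfr <- cumsum(stats::rnorm(length(future), 0, tp$trajectory_noise))
      z_mort <- cumsum(stats::rnorm(length(future), 0, tp$trajectory_noise))
      for (i in seq_along(future)) {
        j <- future[i]
        pj <- pk[[j]]
        pj$tfr <- pj$tfr * exp(z_tfr[i])
        gap <- (110 - pj$life_expectancy_target) * exp(z_mort[i])
        pj$life_expectancy_target <- min(max(110 - gap, 25), 105)
        pk[[j]] <- pj
      }
    }
    # past columns are shared with the median path and need no rebuild
    trajectories[[k]] <- series_from_params(
      pk, grid, years, location, tp$pop_scale,
      template = median_series,
      recompute = if (tp$trajectory_noise > 0) future else integer(0))
  }
  structure(list(median = median_series, trajectories = trajectories,
                 params = tp, seed = seed, years = years),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat(sprintf("<trajectory_ensemble> %s: %d trajectories, %s-%s (branching after %s)\n",
              x$median$location, length(x$trajectories),
              min(x$years), max(x$years), x$params$present_year))
  invisible(x)
}
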