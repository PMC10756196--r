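test_that("generated fertility schedules hit TFR and mean age", {
  g <- age_grid()
  fs <- make_fertility(schedule_params(tfr = 2), g)
  expect_equal(sum(fs$f), 2, tolerance = 1e-9)
  expect_equal(sum(make_fertility(schedule_params(tfr = 0), g)$f), 0)
  mean_age <- function(f) sum(age_midpoints(g) * f) / sum(f)
  m25 <- make_fertility(schedule_params(tfr = 2, mean_age_childbearing = 25), g)
  m35 <- make_fertility(schedule_params(tfr = 2, mean_age_childbearing = 35), g)
  expect_lt(abs(mean_age(m25$f) - 25), 2.5)
  expect_lt(abs(mean_age(m35$f) - 35), 2.5)
  expect_lt(abs((mean_age(m35$f) - mean_age(m25$f)) - 10), 2.5)
})

test_that("generated mortality calibrates to the life-expectancy target", {
  g <- age_grid()
  for (target in c(45, 60, 80)) {
    m <- make_mortality(schedule_params(life_expectancy_target = target), g)
    e0 <- sum(m$Lx)
    expect_lt(abs(e0 - target), 0.25)
    expect_true(all(m$p >= 0 & m$p <= 1))
    expect_equal(m$p[g$n_classes], 0)
  }
  # male schedules target the gap-adjusted life expectancy
  sp <- schedule_params(life_expectancy_target = 70, male_e0_gap = 5)
  expect_lt(abs(sum(make_mortality(sp, g, "male")$Lx) - 65), 0.25)
  # a heavy background hazard caps survival at every age: with
  # makeham_level M, five-year survival cannot exceed exp(-5M)
  heavy <- schedule_params(life_expectancy_target = 21,
                           makeham_level = 0.045)
  p_heavy <- make_mortality(heavy, g)$p
  expect_lt(max(p_heavy), exp(-5 * 0.045) + 1e-9)
  light <- schedule_params(life_expectancy_target = 21,
                           makeham_level = 1e-4)
  expect_lt(max(p_heavy), max(make_mortality(light, g)$p))
  # a target beyond what the background hazard allows is a calibration error
  expect_error(
    make_mortality(schedule_params(life_expectancy_target = 105,
                                   makeham_level = 0.05), g),
    "calibration")
})

test_that("steeper senescence at fixed e0 lowers old-age survival", {
  g <- age_grid()
  shallow <- make_mortality(schedule_params(gompertz_slope = 0.09), g)
  steep <- make_mortality(schedule_params(gompertz_slope = 0.14), g)
  old <- 17:20  # classes 80+
  expect_true(all(steep$p[old] <= shallow$p[old]))
})

test_that("median rate paths interpolate the trend logistically", {
  g <- age_grid()
  sp <- schedule_params(tfr = 3)
  flat <- make_rate_series(trend_params(sp), g, years = seq(1950, 1970, 5))
  for (j in 2:5) expect_equal(flat$fert[, j], flat$fert[, 1])
  tp <- trend_params(schedule_params(tfr = 6),
                     schedule_params(tfr = 1.5),
                     midpoint_year = 2000, transition_speed = 15)
  s <- make_rate_series(tp, g, years = seq(1950, 2100, 5))
  tfr <- colSums(s$fert)
  expect_true(all(diff(tfr) < 0))
  # shifting the midpoint year shifts the half-way crossing accordingly
  crossing <- function(mid) {
    tp2 <- trend_params(schedule_params(tfr = 6), schedule_params(tfr = 1.5),
                        midpoint_year = mid, transition_speed = 15)
    s2 <- make_rate_series(tp2, g, years = seq(1950, 2100, 5))
    s2$times[which(colSums(s2$fert) < 3.75)[1]]
  }
  expect_equal(crossing(2020) - crossing(1990), 30, tolerance = 5)
})

test_that("trajectory ensembles are seeded, branch after the present, and fan out", {
  g <- age_grid()
  yrs <- seq(1990, 2060, 5)
  tp <- trend_params(schedule_params(tfr = 3), schedule_params(tfr = 2),
                     trajectory_noise = 0.08, n_trajectories = 30,
                     present_year = 2020)
  e1 <- sample_trajectories(tp, g, yrs, seed = 4)
  e2 <- sample_trajectories(tp, g, yrs, seed = 4)
  expect_identical(e1$trajectories, e2$trajectories)
  past <- which(yrs <= 2020)
  for (k in c(1, 17)) {
    expect_identical(e1$trajectories[[k]]$fert[, past],
                     e1$median$fert[, past])
  }
  # zero noise collapses the ensemble onto the median path
  tp0 <- trend_params(schedule_params(tfr = 3), schedule_params(tfr = 2),
                      trajectory_noise = 0, n_trajectories = 5)
  e0 <- sample_trajectories(tp0, g, yrs, seed = 9)
  for (tr in e0$trajectories) expect_equal(tr$fert, e0$median$fert)
  # the TFR fan widens with horizon: the log-scale spread around the median
  # path is a random walk, so its variance grows with the number of steps
  tfr_mat <- sapply(e1$trajectories, function(s) colSums(s$fert))
  med <- colSums(e1$median$fert)
  vlog <- apply(log(tfr_mat / med), 1, stats::var)
  future <- which(yrs > 2020)
  expect_true(all(vlog[past] == 0))
  expect_gt(vlog[future[length(future)]], vlog[future[1]])
  expect_gt(stats::cor(seq_along(future), vlog[future],
                       method = "spearman"), 0.8)
})

test_that("ensemble medians track the median path at the horizon", {
  g <- age_grid()
  yrs <- seq(2010, 2050, 5)
  tp <- trend_params(schedule_params(tfr = 3), schedule_params(tfr = 2),
                     trajectory_noise = 0.05, n_trajectories = 200,
                     present_year = 2020)
  ens <- sample_trajectories(tp, g, yrs, seed = 12)
  horizon_tfr <- sapply(ens$trajectories,
                        function(s) sum(s$fert[, length(yrs)]))
  med_path <- sum(ens$median$fert[, length(yrs)])
  se <- stats::sd(horizon_tfr) / sqrt(length(horizon_tfr))
  # random-walk on log scale: the ensemble median is the median path
  expect_lt(abs(stats::median(horizon_tfr) - med_path), 2 * se * sqrt(pi / 2))
})

test_that("generated series pass rate validation through the real I/O path", {
  s <- const_series(tfr = 3.2, e0 = 68)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rate_series(s, path)
  back <- read_rate_series(path)  # validates internally
  s2 <- as_rate_series(back)
  expect_equal(s2$fert, s$fert, tolerance = 1e-12)
  expect_equal(s2$surv_f, s$surv_f, tolerance = 1e-12)
})
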