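#' Trend parameters of the built-in two-country synthetic world
#'
#' Two stylised locations spanning the range of observed demographic
#' transitions: "Alta", a high-fertility, high-mortality population whose
#' fertility declines steeply (TFR 6.5 to 1.8, e0 45 to 78), and "Bassa", an
#' already low-fertility, long-lived population aging further (TFR 2.3 to
#' 1.5, e0 65 to 86).
#'
#' @param n_trajectories,trajectory_noise Passed to [trend_params()].
#' @return Named list of two [trend_params()].
#' @export
demo_world_params <- function(n_trajectories = 1000, trajectory_noise = 0.05) {
  list(
    Alta = trend_params(
      start = schedule_params(tfr = 6.5, mean_age_childbearing = 29,
                              fertility_width = 7,
                              life_expectancy_target = 45),
      end = schedule_params(tfr = 1.8, mean_age_childbearing = 31,
                            fertility_width = 6,
                            life_expectancy_target = 78),
      midpoint_year = 2010, transition_speed = 22,
      trajectory_noise = trajectory_noise,
      n_trajectories = n_trajectories, pop_scale = 3e5),
    Bassa = trend_params(
      start = schedule_params(tfr = 2.3, mean_age_childbearing = 27,
                              fertility_width = 6,
                              life_expectancy_target = 65),
      end = schedule_params(tfr = 1.5, mean_age_childbearing = 32,
                            fertility_width = 5.5,
                            life_expectancy_target = 86),
      midpoint_year = 1990, transition_speed = 25,
      trajectory_noise = trajectory_noise,
      n_trajectories = n_trajectories, pop_scale = 1e5)
  )
}

#' Hand-checkable toy rate table
#'
#' A three-class, two-period constant rate table used in examples and
#' tests: one fertile age class (annual ASFR 0.08, so 0.4 births per 5-y
#' step), female survival 0.9 then 2/3 (from Lx 5, 4.5, 3).
#'
#' @return The canonical long-format tibble.
#' @export
toy_rate_table <- function() {
  ages <- c(0, 5, 10)
  blocks <- dplyr::bind_rows(
    tibble::tibble(sex = "female", variable = "asfr",
                   age_lower = ages, value = c(0, 0.08, 0)),
    tibble::tibble(sex = "female", variable = "Lx",
                   age_lower = ages, value = c(5, 4.5, 3)),
    tibble::tibble(sex = "male", variable = "Lx",
                   age_lower = ages, value = c(5, 4, 2)),
    tibble::tibble(sex = "female", variable = "population",
                   age_lower = ages, value = c(100, 80, 60)),
    tibble::tibble(sex = "male", variable = "population",
                   age_lower = ages, value = c(105, 80, 50))
  )
  tidyr::expand_grid(location = "toy", year = c(1950, 1955), blocks) |>
    dplyr::select("location", "year", "age_lower", "sex", "variable", "value")
}

#' Hand-built three-generation pedigree
#'
#' A genealogy small enough to count by hand: a grandmother, her two
#' daughters, and one granddaughter of each. For the younger granddaughter
#' (id 4) at the default tally time, the network is exactly one mother, one
#' grandmother, one (younger) aunt and one cousin through her.
#'
#' @param grid The [age_grid()] attached to the genealogy.
#' @return A `genealogy` tibble (see [simulate_genealogy()]).
#' @export
toy_pedigree <- function(grid = age_grid()) {
  g <- tibble::tibble(
    id = 1:5,
    sex = "female",
    birth = c(0L, 4L, 5L, 9L, 8L),
    death = NA_integer_,
    mother_id = c(NA, 1L, 1L, 2L, 3L),
    father_id = NA_integer_
  )
  structure(g, class = c("genealogy", class(g)),
            n_steps = 10L, grid = grid, variant = "one_sex", extinct = FALSE)
}

#' Write the bundled fixtures to disk
#'
#' Regenerates, deterministically under a seed, (i) the hand-checkable toy
#' rate file, (ii) the two-country synthetic world (median rate paths of
#' [demo_world_params()], written through the canonical rate writer so they
#' exercise the real I/O path), and (iii) the three-generation pedigree.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed (the fixtures are a pure function of it).
#' @return Named character vector of the files written, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  files <- c(
    toy_rates = file.path(out_dir, "toy_rates.csv"),
    demo_world = file.path(out_dir, "demo_world.csv"),
    pedigree = file.path(out_dir, "pedigree.csv")
  )
  write_rate_series(toy_rate_table(), files[["toy_rates"]])
  wp <- demo_world_params()
  world <- dplyr::bind_rows(lapply(names(wp), function(loc) {
    rate_series_to_table(make_rate_series(wp[[loc]], location = loc))
  }))
  readr::write_csv(world, files[["demo_world"]], progress = FALSE)
  readr::write_csv(tibble::as_tibble(toy_pedigree()), files[["pedigree"]],
                   progress = FALSE)
  invisible(files)
}
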