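# constant-rate regime built through the synthetic generator
const_series <- function(tfr = 4, e0 = 60, years = 1950, frac_female = NULL,
                         ...) {
  sp <- schedule_params(tfr = tfr, life_expectancy_target = e0, ...)
  tp <- trend_params(sp, n_trajectories = 1, trajectory_noise = 0)
  s <- make_rate_series(tp, years = years)
  if (!is.null(frac_female)) s$frac_female <- frac_female
  s
}

# canonical long table for hand-specified toy schedules
rates_table <- function(location = "X", years = 1950, ages = c(0, 5, 10),
                        asfr = c(0, 0.08, 0), Lx_f = c(5, 4.5, 3),
                        Lx_m = Lx_f, pop_f = rep(10, length(ages)),
                        pop_m = pop_f) {
  one_year <- function(y) {
    dplyr::bind_rows(
      tibble::tibble(sex = "female", variable = "asfr", value = asfr),
      tibble::tibble(sex = "female", variable = "Lx", value = Lx_f),
      tibble::tibble(sex = "male", variable = "Lx", value = Lx_m),
      tibble::tibble(sex = "female", variable = "population", value = pop_f),
      tibble::tibble(sex = "male", variable = "population", value = pop_m)
    ) |>
      dplyr::mutate(location = location, year = y,
                    age_lower = rep(ages, 5), .before = 1)
  }
  dplyr::bind_rows(lapply(years, one_year))
}

# per-focal-age totals of one kin type
type_totals <- function(net, type, year = NULL) {
  colSums(kinproj:::kin_slab(net, type, year))
}
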