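#' Run the full kinship projection analysis
#'
#' Orchestrates the pipeline for one or more locations: per location and
#' trajectory, the time-invariant boundary network at the first year feeds a
#' time-varying projection; kin-category counts, mean kin ages and total
#' family size are extracted at the requested Focal ages and years; the
#' trajectory ensemble is summarised by median and 80% projection interval,
#' and (optionally) aggregated to regions weighted by the female population
#' in Focal's age class.
#'
#' @param inputs One of: a canonical long-format rate tibble (possibly
#'   several locations; deterministic, single trajectory), a `rate_series`,
#'   a named list of [trend_params()] (synthetic mode: trajectories are
#'   sampled per location), or a `trajectory_ensemble` / named list of them.
#' @param years Calendar years to report (default: every year of the
#'   input); the projection always runs over the full input horizon.
#' @param focal_ages Focal ages in years to report (class lower bounds).
#' @param variant `"two_sex"` (androgynous) or `"one_sex"`.
#' @param n_trajectories Trajectories sampled per location in synthetic
#'   mode (ignored when `inputs` already fixes the trajectories).
#' @param seed Integer seed; all randomness derives from it.
#' @param grid [age_grid()] used in synthetic mode.
#' @param region_map Optional tibble `location`, `region` for regional
#'   aggregation.
#' @return A `kin_projection` object: list with tibbles `details`
#'   (per-trajectory kin-category counts and mean ages), `family`
#'   (per-trajectory total family size with aggregation weights),
#'   `summary` (ensemble medians and 80% intervals) and `regional`
#'   (`NULL` without a `region_map`), plus the echoed configuration.
#' @export
run_kinship_analysis <- function(inputs, years = NULL,
                                 focal_ages = c(0, 35, 65),
                                 variant = c("two_sex", "one_sex"),
                                 n_trajectories = 1, seed = 1,
                                 grid = age_grid(), region_map = NULL) {
  variant <- match.arg(variant)
  traj_sets <- normalize_inputs(inputs, n_trajectories, seed, grid, years)
  errors <- character()
  per_loc <- purrr::imap(traj_sets, function(trajs, loc) {
    tryCatch(
      purrr::imap_dfr(trajs, function(series, k) {
        project_one(series, as.integer(k), focal_ages, years, variant)
      }),
      error = function(e) {
        errors <<- c(errors, paste0(loc, ": ", conditionMessage(e)))
        NULL
      }
    )
  })
  failed <- names(per_loc)[vapply(per_loc, is.null, logical(1))]
  for (msg in errors) message("location failed: ", msg)
  details <- dplyr::bind_rows(per_loc[!names(per_loc) %in% failed])
  if (!nrow(details)) stop("every location failed", call. = FALSE)
  family <- details |>
    dplyr::group_by(.data$location, .data$trajectory, .data$year,
                    .data$focal_age) |>
    dplyr::summarise(total_family_size = sum(.data$expected_count),
                     weight = .data$weight[1], .groups = "drop")
  summary <- list(
    family = summarize_ensemble(
      family, value = "total_family_size",
      by = c("location", "year", "focal_age")),
    kin = summarize_ensemble(
      dplyr::select(details, -"mean_kin_age", -"weight"),
      value = "expected_count",
      by = c("location", "year", "focal_age", "kin_category"))
  )
  regional <- if (!is.null(region_map)) {
    aggregate_regions(family, region_map, value = "total_family_size",
                      by = c("year", "focal_age"))
  }
  structure(
    list(details = details, family = family, summary = summary,
         regional = regional,
         config = list(focal_ages = focal_ages, years = years,
                       variant = variant, seed = seed,
                       n_trajectories = n_trajectories,
                       locations = names(traj_sets), failed = failed)),
    class = "kin_projection")
}

# internal: coerce the accepted input forms into a named list (per location)
# of named lists of rate_series (per trajectory)
normalize_inputs <- function(inputs, n_trajectories, seed, grid, years) {
  as_traj_list <- function(x) stats::setNames(x, seq_along(x))
  if (inherits(inputs, "rate_series")) {
    out <- list(as_traj_list(list(inputs)))
    names(out) <- inputs$location
    return(out)
  }
  if (inherits(inputs, "trajectory_ensemble")) {
    out <- list(as_traj_list(inputs$trajectories))
    names(out) <- inputs$median$location
    return(out)
  }
  if (is.data.frame(inputs)) {
    series <- as_rate_series(inputs)
    if (inherits(series, "rate_series")) series <- list(series) |>
        stats::setNames(series$location)
    return(lapply(series, function(s) as_traj_list(list(s))))
  }
  if (inherits(inputs, "trend_params")) inputs <- list(synthetic = inputs)
  if (is.list(inputs) && length(inputs) &&
      all(vapply(inputs, inherits, logical(1), "trajectory_ensemble"))) {
    return(lapply(inputs, function(e) as_traj_list(e$trajectories)))
  }
  if (is.list(inputs) && length(inputs) &&
      all(vapply(inputs, inherits, logical(1), "trend_params"))) {
    if (is.null(names(inputs))) {
      names(inputs) <- paste0("location_", seq_along(inputs))
    }
    yrs <- if (is.null(years)) seq(1950, 2100, by = grid$step_years) else
      seq(min(years), max(years), by = grid$step_years)
    out <- purrr::imap(inputs, function(tp, loc) {
      i <- match(loc, names(inputs))
      tp$n_trajectories <- as.integer(n_trajectories)
      ens <- sample_trajectories(tp, grid, yrs, seed = (seed + 7919L * i) %% 2147483647L,
                                 location = loc)
      as_traj_list(ens$trajectories)
    })
    return(out)
  }
  stop("unsupported `inputs`: see ?run_kinship_analysis", call. = FALSE)
}

# internal: one location x trajectory -> per-category detail rows
project_one <- function(series, trajectory, focal_ages, years, variant) {
  net <- time_variant_kinship(series, variant = variant)
  keep_years <- if (is.null(years)) series$times else
    intersect(years, series$times)
  if (!length(keep_years)) {
    stop("requested years not covered by the input series", call. = FALSE)
  }
  td <- tidy(net, focal_ages = focal_ages, years = keep_years)
  step <- series$grid$step_years
  weights <- tibble::tibble(
    year = rep(series$times, each = series$grid$n_classes),
    focal_age = rep(series$grid$lower_bounds, length(series$times)),
    weight = as.vector(series$pop_f)
  )
  td |>
    dplyr::group_by(.data$year, .data$focal_age, .data$kin_category) |>
    dplyr::summarise(
      expected_count = sum(.data$count),
      mean_kin_age = if (sum(.data$count) > 0)
        sum((.data$kin_age + step / 2) * .data$count) / sum(.data$count)
      else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::left_join(weights, by = c("year", "focal_age")) |>
    dplyr::mutate(location = series$location, trajectory = trajectory,
                  .before = 1)
}

#' Write projection results as tidy CSV tables
#'
#' Writes the per-trajectory detail and family-size tables, the ensemble
#' summaries, the regional summary (when present), and a YAML-style
#' `config.yml` sidecar echoing the run configuration. Data tables never
#' mix with metadata.
#'
#' @param x A `kin_projection` from [run_kinship_analysis()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of files written, invisibly.
#' @export
write_projection <- function(x, dir) {
  stopifnot(inherits(x, "kin_projection"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(
    details = file.path(dir, "kin_details.csv"),
    family = file.path(dir, "family_size.csv"),
    summary_family = file.path(dir, "summary_family.csv"),
    summary_kin = file.path(dir, "summary_kin.csv"),
    config = file.path(dir, "config.yml")
  )
  readr::write_csv(x$details, files[["details"]], progress = FALSE)
  readr::write_csv(x$family, files[["family"]], progress = FALSE)
  readr::write_csv(x$summary$family, files[["summary_family"]], progress = FALSE)
  readr::write_csv(x$summary$kin, files[["summary_kin"]], progress = FALSE)
  if (!is.null(x$regional)) {
    files[["regional"]] <- file.path(dir, "summary_regional.csv")
    readr::write_csv(x$regional, files[["regional"]], progress = FALSE)
  }
  cfg <- x$config
  writeLines(c(
    paste0("variant: ", cfg$variant),
    paste0("seed: ", cfg$seed),
    paste0("n_trajectories: ", cfg$n_trajectories),
    paste0("focal_ages: [", paste(cfg$focal_ages, collapse = ", "), "]"),
    paste0("locations: [", paste(cfg$locations, collapse = ", "), "]"),
    paste0("quantile_rule: type 7 (linear interpolation)")
  ), files[["config"]])
  invisible(files)
}

#' @export
print.kin_projection <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<kin_projection> %s variant: %d location(s), %d trajectory(ies)\n",
    cfg$variant, length(cfg$locations), max(x$details$trajectory)))
  cat("  locations:", paste(cfg$locations, collapse = ", "), "\n")
  if (length(cfg$failed)) cat("  failed:", paste(cfg$failed, collapse = ", "), "\n")
  invisible(x)
}

#' @rdname run_kinship_analysis
#' @param x A `kin_projection`.
#' @param ... Unused.
#' @export
tidy.kin_projection <- function(x, ...) x$details

#' @rdname run_kinship_analysis
#' @export
glance.kin_projection <- function(x, ...) {
  tibble::tibble(
    variant = x$config$variant,
    n_locations = length(x$config$locations),
    n_trajectories = max(x$details$trajectory),
    first_year = min(x$details$year),
    last_year = max(x$details$year),
    seed = x$config$seed
  )
}
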