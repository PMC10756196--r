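#' Read, validate and assemble time-indexed rate series
#'
#' Rate inputs travel as a long-format table with columns `location`, `year`,
#' `age_lower`, `sex`, `variable`, `value`, where `variable` is one of
#' `asfr` (annual age-specific fertility, female rows), `Lx` (life-table
#' person-years, female and male rows) and `population` (counts, female and
#' male rows), on matching 5-year (or other constant-width) age and period
#' grids. [read_rate_series()] reads and validates such a file;
#' [as_rate_series()] turns the table into the internal per-location
#' `rate_series` object consumed by the kinship kernel. Missing blocks are an
#' error, never silently interpolated.
#'
#' @param path Path to a delimited text file (CSV).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(location = "Location", year = "Time", age_lower = "AgeGrp")`,
#'   to adapt WPP-style exports.
#' @return [read_rate_series()]: the validated canonical tibble.
#' @export
read_rate_series <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("rate file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(df)) {
        names(df)[names(df) == col_map[[canon]]] <- canon
      }
    }
  }
  validate_rate_series(df)
  df
}

#' Write a canonical rate table
#'
#' @param df A canonical long-format rate tibble (or a `rate_series` object,
#'   which is converted back to the canonical table first).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rate_series <- function(df, path) {
  if (inherits(df, "rate_series")) df <- rate_series_to_table(df)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Validate a long-format rate table
#'
#' Checks the schema, value ranges, duplicate records, constant age/period
#' spacing, and block completeness (every location-year needs female asfr,
#' female and male Lx, and female and male population over the full age
#' range).
#'
#' @param df A data frame in the canonical long format.
#' @param stop_on_error If `TRUE` (default) abort with a message naming the
#'   violations; if `FALSE` return them.
#' @return Invisibly `TRUE` when valid; when `stop_on_error = FALSE`, a
#'   tibble of violations (zero rows when valid).
#' @export
validate_rate_series <- function(df, stop_on_error = TRUE) {
  problems <- character()
  need <- c("location", "year", "age_lower", "sex", "variable", "value")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    problems <- c(problems,
                  paste("missing column(s):", paste(missing_cols, collapse = ", ")))
  } else {
    df <- dplyr::as_tibble(df)
    if (any(!df$variable %in% c("asfr", "Lx", "population"))) {
      problems <- c(problems, paste(
        "unknown variable(s):",
        paste(unique(setdiff(df$variable, c("asfr", "Lx", "population"))),
              collapse = ", ")))
    }
    if (anyNA(df$value)) problems <- c(problems, "missing values in `value`")
    if (any(df$value < 0, na.rm = TRUE)) {
      problems <- c(problems, "negative values in `value`")
    }
    dup <- df |>
      dplyr::count(.data$location, .data$year, .data$age_lower, .data$sex,
                   .data$variable) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup)) {
      problems <- c(problems, paste0(
        "overlapping duplicate records, e.g. ", dup$location[1], " ",
        dup$year[1], " age ", dup$age_lower[1], " ", dup$sex[1], " ",
        dup$variable[1]))
    }
    ages <- sort(unique(df$age_lower))
    if (length(ages) < 3 || length(unique(diff(ages))) != 1) {
      problems <- c(problems, "age_lower values do not form a constant-spacing grid")
    } else {
      step <- diff(ages)[1]
      yrs <- sort(unique(df$year))
      if (length(yrs) > 1 && any(diff(yrs) != step)) {
        problems <- c(problems,
                      paste0("year spacing must equal the age-class width (",
                             step, " y)"))
      }
      blocks <- dplyr::tribble(
        ~variable, ~sex,
        "asfr", "female",
        "Lx", "female", "Lx", "male",
        "population", "female", "population", "male"
      )
      have <- df |>
        dplyr::distinct(.data$location, .data$year, .data$sex,
                        .data$variable, .data$age_lower) |>
        dplyr::count(.data$location, .data$year, .data$sex, .data$variable)
      want <- tidyr::expand_grid(
        location = unique(df$location), year = unique(df$year), blocks)
      chk <- dplyr::left_join(
        want, have, by = c("location", "year", "sex", "variable"))
      bad <- chk[is.na(chk$n) | chk$n != length(ages), ]
      if (nrow(bad)) {
        problems <- c(problems, sprintf(
          "incomplete block: %s %s %s %d (need %d age classes)",
          bad$variable, bad$sex, bad$location, bad$year, length(ages)))
      }
    }
  }
  if (length(problems) && stop_on_error) {
    stop("invalid rate series:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  if (stop_on_error) return(invisible(TRUE))
  tibble::tibble(problem = problems)
}

#' Assemble the internal per-location rate series
#'
#' Converts a validated canonical rate table into `rate_series` object(s):
#' per-step fertility and survival schedules plus population structure on a
#' common [age_grid()], one object per location. Annualized ASFR and Lx are
#' converted through [annual_to_step_rates()]. Rates are treated as constant
#' within each step (piecewise-constant, no interpolation).
#'
#' @param df Canonical long-format tibble (see [read_rate_series()]).
#' @param location Optional single location to extract; when `NULL` and the
#'   table holds several locations, a named list of `rate_series` is
#'   returned.
#' @param frac_female Proportion of births that are female (sex ratio at
#'   birth allocation); the canonical table does not carry an SRB column.
#' @return A `rate_series` object, or a named list of them.
#' @export
as_rate_series <- function(df, location = NULL, frac_female = 100 / 205) {
  validate_rate_series(df)
  df <- dplyr::as_tibble(df)
  locs <- unique(df$location)
  if (is.null(location)) {
    if (length(locs) > 1) {
      out <- lapply(locs, function(l) as_rate_series(df, l, frac_female))
      names(out) <- locs
      return(out)
    }
    location <- locs
  }
  if (!location %in% locs) {
    stop("location not present in table: ", location, call. = FALSE)
  }
  d <- df[df$location == location, ]
  ages <- sort(unique(d$age_lower))
  step <- diff(ages)[1]
  grid <- age_grid(length(ages), step, start = ages[1])
  times <- sort(unique(d$year))
  omega <- grid$n_classes

  pull_block <- function(dd, var, sx) {
    b <- dd[dd$variable == var & dd$sex == sx, ]
    b$value[order(b$age_lower)]
  }
  fert <- surv_f <- surv_m <- pop_f <- pop_m <- Lx_f <- Lx_m <-
    matrix(0, omega, length(times))
  for (j in seq_along(times)) {
    dt <- d[d$year == times[j], ]
    asfr <- pull_block(dt, "asfr", "female")
    Lf <- pull_block(dt, "Lx", "female")
    Lm <- pull_block(dt, "Lx", "male")
    conv_f <- annual_to_step_rates(asfr, Lf, grid, "female", frac_female)
    conv_m <- annual_to_step_rates(numeric(omega), Lm, grid, "male", frac_female)
    fert[, j] <- conv_f$fertility$f
    surv_f[, j] <- conv_f$mortality$p
    surv_m[, j] <- conv_m$mortality$p
    Lx_f[, j] <- Lf
    Lx_m[, j] <- Lm
    pop_f[, j] <- pull_block(dt, "population", "female")
    pop_m[, j] <- pull_block(dt, "population", "male")
  }
  new_rate_series(location, grid, times, frac_female,
                  fert, surv_f, surv_m, pop_f, pop_m, Lx_f, Lx_m)
}

# internal constructor shared with the synthetic generator
new_rate_series <- function(location, grid, times, frac_female, fert,
                            surv_f, surv_m, pop_f, pop_m,
                            Lx_f = NULL, Lx_m = NULL, androgynous = TRUE) {
  stopifnot(length(times) >= 1, nrow(fert) == grid$n_classes)
  if (length(times) > 1 && any(diff(times) != grid$step_years)) {
    stop("time spacing must equal the grid step (", grid$step_years, " y)",
         call. = FALSE)
  }
  structure(
    list(location = location, grid = grid, times = as.numeric(times),
         frac_female = frac_female, fert = fert,
         surv_f = surv_f, surv_m = surv_m,
         pop_f = pop_f, pop_m = pop_m, Lx_f = Lx_f, Lx_m = Lx_m,
         androgynous = androgynous),
    class = "rate_series"
  )
}

#' @export
print.rate_series <- function(x, ...) {
  cat(sprintf(
    "<rate_series> %s: %d times (%s-%s), %d age classes of %d y\n",
    x$location, length(x$times), min(x$times), max(x$times),
    x$grid$n_classes, x$grid$step_years))
  tfr <- colSums(x$fert)
  cat(sprintf("  TFR %0.2f -> %0.2f; androgynous fertility: %s\n",
              tfr[1], tfr[length(tfr)], x$androgynous))
  invisible(x)
}

# internal: one time slice of a series (index into times)
rate_slice <- function(series, j) {
  list(location = series$location, grid = series$grid,
       year = series$times[j], frac_female = series$frac_female,
       f = series$fert[, j], p_f = series$surv_f[, j],
       p_m = series$surv_m[, j],
       w_f = series$pop_f[, j], w_m = series$pop_m[, j],
       androgynous = series$androgynous)
}

# internal: canonical long table from a rate_series (asfr back-converted to
# annual rates; Lx reconstructed from survival when not stored)
rate_series_to_table <- function(s) {
  grid <- s$grid
  omega <- grid$n_classes
  Lx_f <- s$Lx_f
  Lx_m <- s$Lx_m
  if (is.null(Lx_f)) Lx_f <- apply(s$surv_f, 2, function(p) cumprod(c(1, p[-omega])))
  if (is.null(Lx_m)) Lx_m <- apply(s$surv_m, 2, function(p) cumprod(c(1, p[-omega])))
  blocks <- list(
    list(var = "asfr", sex = "female", m = s$fert / grid$step_years),
    list(var = "Lx", sex = "female", m = Lx_f),
    list(var = "Lx", sex = "male", m = Lx_m),
    list(var = "population", sex = "female", m = s$pop_f),
    list(var = "population", sex = "male", m = s$pop_m)
  )
  purrr::map_dfr(blocks, function(b) {
    tibble::tibble(
      location = s$location,
      year = rep(s$times, each = omega),
      age_lower = rep(grid$lower_bounds, length(s$times)),
      sex = b$sex,
      variable = b$var,
      value = as.vector(b$m)
    )
  })
}

#' Mark a rate series as using the androgynous approximation
#'
#' Male fertility schedules are rarely available; under the androgynous
#' approximation male kin reproduce at the female age-specific rates (female
#' and male survival stay sex-specific). Series are androgynous by default
#' because the canonical input format carries only female fertility; this
#' function makes the choice explicit and is the hook where a sex-specific
#' male schedule would be attached instead.
#'
#' @param series A `rate_series`.
#' @return The series with the androgynous flag set.
#' @export
make_androgynous <- function(series) {
  stopifnot(inherits(series, "rate_series"))
  series$androgynous <- TRUE
  series
}
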