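#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a kinship network into a long tibble
#'
#' @param x A `kin_network` or `kin_network_series`.
#' @param focal_ages Optional Focal ages (years, class lower bounds) to keep.
#' @param years Optional calendar years to keep (network series only).
#' @param ... Unused.
#' @return A tibble with columns `year`, `focal_age`, `kin_type`,
#'   `kin_category` (the reported 10-category label), `sex`, `kin_age` and
#'   `count`.
#' @export
tidy.kin_network <- function(x, focal_ages = NULL, years = NULL, ...) {
  grid <- x$grid
  omega <- grid$n_classes
  cats <- kin_categories()
  reported <- stats::setNames(cats$reported, cats$code)
  is_series <- inherits(x, "kin_network_series")
  yrs <- if (is_series) x$times else x$year
  if (!is.null(years)) {
    if (!all(years %in% yrs)) stop("year(s) not in network", call. = FALSE)
    yrs <- years
  }
  fages <- grid$lower_bounds
  if (!is.null(focal_ages)) {
    age_to_class(focal_ages, grid)  # validates
    fages <- focal_ages
  }
  xi <- age_to_class(fages, grid)
  sexes <- if (x$variant == "one_sex") "female" else c("female", "male")
  nstate <- omega * length(sexes)

  purrr::map_dfr(names(x$arrays), function(type) {
    purrr::map_dfr(yrs, function(yr) {
      slab <- kin_slab(x, type, if (is_series) yr else NULL)[, xi, drop = FALSE]
      tibble::tibble(
        year = yr,
        focal_age = rep(fages, each = nstate),
        kin_type = type,
        kin_category = unname(reported[type]),
        sex = rep(rep(sexes, each = omega), length(fages)),
        kin_age = rep(grid$lower_bounds, length(sexes) * length(fages)),
        count = as.vector(slab)
      )
    })
  })
}

#' One-row summary of a kinship network
#'
#' @param x A `kin_network` or `kin_network_series`.
#' @param ... Unused.
#' @return A tibble with the variant, grid dimensions, time coverage and the
#'   expected total family size for a newborn Focal at the first time.
#' @export
glance.kin_network <- function(x, ...) {
  first_year <- if (inherits(x, "kin_network_series")) x$times[1] else x$year
  tibble::tibble(
    variant = x$variant,
    n_age_classes = x$grid$n_classes,
    step_years = x$grid$step_years,
    first_year = first_year,
    n_times = if (inherits(x, "kin_network_series")) length(x$times) else 1L,
    family_size_at_birth = total_family_size(x, focal_age = x$grid$lower_bounds[1],
                                             time = first_year)
  )
}
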