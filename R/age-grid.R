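#' Define a discrete age grid
#'
#' All schedules and projection matrices in kinproj live on a common grid of
#' equal-width age classes, the last of which is open-ended (no survival out
#' of it). The default reproduces the 21 five-year classes (0-4, 5-9, ...,
#' 100+) of standard abridged demographic output.
#'
#' @param n_classes Number of age classes (at least 3).
#' @param step_years Width of each class in years; also the projection time
#'   step, so rates are per `step_years`-year period.
#' @param start Lower bound of the first class in years.
#'
#' @return An object of class `age_grid`: a list with `n_classes`,
#'   `step_years` and `lower_bounds`.
#' @export
#' @examples
#' age_grid()          # 21 x 5-year classes, 0 to 100+
#' age_grid(4, 1)      # toy single-year grid
age_grid <- function(n_classes = 21, step_years = 5, start = 0) {
  stopifnot(is.numeric(n_classes), length(n_classes) == 1, n_classes >= 3,
            n_classes == as.integer(n_classes),
            is.numeric(step_years), length(step_years) == 1, step_years > 0)
  structure(
    list(
      n_classes = as.integer(n_classes),
      step_years = as.integer(step_years),
      lower_bounds = start + step_years * (seq_len(n_classes) - 1L)
    ),
    class = "age_grid"
  )
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf("<age_grid> %d classes of %d y: %d, %d, ..., %d+\n",
              x$n_classes, x$step_years, x$lower_bounds[1],
              x$lower_bounds[2], x$lower_bounds[x$n_classes]))
  invisible(x)
}

#' Midpoints of the age classes
#'
#' @param grid An [age_grid()].
#' @return Numeric vector of class midpoints in years (lower bound + step/2),
#'   used to compute mean kin ages.
#' @export
age_midpoints <- function(grid) {
  stopifnot(inherits(grid, "age_grid"))
  grid$lower_bounds + grid$step_years / 2
}

# internal: map ages in years to 1-based class indices; error when outside
age_to_class <- function(age_years, grid) {
  idx <- match(age_years, grid$lower_bounds)
  if (anyNA(idx)) {
    stop("age(s) ", paste(age_years[is.na(idx)], collapse = ", "),
         " are not lower bounds of the age grid", call. = FALSE)
  }
  idx
}
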