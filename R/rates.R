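#' Age-specific schedule constructors
#'
#' A `mortality_schedule` holds per-step survival probabilities `p` (the
#' probability of surviving from class x to class x+1 over one projection
#' step); the last, open-ended class has `p = 0`, i.e. kin do not persist
#' beyond the grid. A `fertility_schedule` holds expected births of both
#' sexes per woman per step by age class of the mother, together with the
#' proportion of births that are female (`frac_female`, the sex-ratio-at-birth
#' allocation needed by the two-sex model; the default 100/205 corresponds to
#' the conventional SRB of 1.05).
#'
#' @param p Numeric vector of per-step survival probabilities in `[0, 1]`,
#'   one per age class. The last entry is forced to 0.
#' @param sex `"female"` or `"male"`.
#' @param Lx Optional life-table person-years column the probabilities were
#'   derived from (kept for round-tripping through the file format).
#' @param f Numeric vector of per-step both-sex fertility rates, one per age
#'   class; non-negative, zero outside the reproductive span.
#' @param frac_female Proportion of births that are female, in (0, 1).
#' @return A `mortality_schedule` / `fertility_schedule` list object.
#' @name schedules
NULL

#' @rdname schedules
#' @export
mortality_schedule <- function(p, sex = c("female", "male"), Lx = NULL) {
  sex <- match.arg(sex)
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("survival probabilities must lie in [0, 1] and be non-missing",
         call. = FALSE)
  }
  p[length(p)] <- 0
  structure(list(sex = sex, p = p, Lx = Lx), class = "mortality_schedule")
}

#' @rdname schedules
#' @export
fertility_schedule <- function(f, frac_female = 100 / 205) {
  f <- as.numeric(f)
  if (anyNA(f) || any(f < 0)) {
    stop("fertility rates must be non-negative and non-missing", call. = FALSE)
  }
  if (!(frac_female > 0 && frac_female < 1)) {
    stop("frac_female must lie strictly between 0 and 1", call. = FALSE)
  }
  pos <- which(f > 0)
  if (length(pos) > 1 && any(diff(pos) != 1)) {
    stop("fertility must be zero outside one contiguous reproductive span",
         call. = FALSE)
  }
  structure(list(f = f, frac_female = frac_female),
            class = "fertility_schedule")
}

# internal: pull the raw vector out of a schedule or accept a bare vector
surv_vec <- function(m) if (inherits(m, "mortality_schedule")) m$p else as.numeric(m)
fert_vec <- function(fs) if (inherits(fs, "fertility_schedule")) fs$f else as.numeric(fs)

#' Build the survival (age-transition) projection matrix
#'
#' Returns the Leslie-type transition matrix U with the age-specific survival
#' probabilities on the subdiagonal and zeros elsewhere: `U[x+1, x] = p[x]`.
#' Applied to an age-distribution vector it survives and ages the population
#' by one step; nobody survives out of the open-ended last class.
#'
#' @param m A [mortality_schedule()] or a bare numeric vector of per-step
#'   survival probabilities.
#' @param grid An [age_grid()]; the schedule must have `grid$n_classes`
#'   entries.
#' @return An `omega x omega` numeric matrix.
#' @export
#' @examples
#' build_survival_matrix(c(0.9, 0.8, 0), age_grid(3))
build_survival_matrix <- function(m, grid = age_grid(length(surv_vec(m)))) {
  p <- surv_vec(m)
  omega <- grid$n_classes
  if (length(p) != omega) {
    stop("survival schedule has ", length(p), " classes but the grid has ",
         omega, call. = FALSE)
  }
  U <- matrix(0, omega, omega)
  U[cbind(2:omega, 1:(omega - 1))] <- p[1:(omega - 1)]
  U
}

#' Build the fertility projection matrix
#'
#' Returns the matrix F with age-specific fertility rates in the first row,
#' so that newborns enter age class 0. Rates are allocated by offspring sex:
#' `f * frac_female` for daughters, `f * (1 - frac_female)` for sons, or the
#' full both-sex rate.
#'
#' @param fs A [fertility_schedule()] or a bare numeric vector of per-step
#'   both-sex rates (then `frac_female` defaults to 100/205).
#' @param grid An [age_grid()].
#' @param sex_of_offspring `"female"`, `"male"` or `"both"`.
#' @return An `omega x omega` numeric matrix with one nonzero row.
#' @export
#' @examples
#' build_fertility_matrix(fertility_schedule(c(0, 1, 0), 0.5), age_grid(3),
#'                        "female")
build_fertility_matrix <- function(fs, grid = age_grid(length(fert_vec(fs))),
                                   sex_of_offspring = c("female", "male", "both")) {
  sex_of_offspring <- match.arg(sex_of_offspring)
  f <- fert_vec(fs)
  alpha <- if (inherits(fs, "fertility_schedule")) fs$frac_female else 100 / 205
  omega <- grid$n_classes
  if (length(f) != omega) {
    stop("fertility schedule has ", length(f), " classes but the grid has ",
         omega, call. = FALSE)
  }
  fac <- switch(sex_of_offspring, female = alpha, male = 1 - alpha, both = 1)
  Fm <- matrix(0, omega, omega)
  Fm[1, ] <- f * fac
  Fm
}

#' Convert annualized rates to per-step schedules
#'
#' UNWPP-style sources publish annualized age-specific fertility rates (ASFR)
#' and life-table person-years (`Lx`); the projection model needs per-step
#' rates. Fertility is scaled by the step width, `f[x] = asfr[x] *
#' step_years`; survival uses the period life-table approximation `p[x] =
#' L[x+1] / L[x]` (clipped to `[0, 1]`), with `p = 0` out of the open-ended
#' class.
#'
#' @param asfr_annual Numeric vector of annual fertility rates by age class.
#' @param survivorship_L Numeric vector of person-years lived in each class
#'   (life-table Lx column, any radix).
#' @param grid An [age_grid()].
#' @param sex Sex label attached to the mortality schedule.
#' @param frac_female Passed to [fertility_schedule()].
#' @return A list with elements `fertility` ([fertility_schedule()]) and
#'   `mortality` ([mortality_schedule()]).
#' @export
annual_to_step_rates <- function(asfr_annual, survivorship_L, grid,
                                 sex = "female", frac_female = 100 / 205) {
  omega <- grid$n_classes
  stopifnot(length(asfr_annual) == omega, length(survivorship_L) == omega)
  L <- as.numeric(survivorship_L)
  if (any(L < 0)) stop("Lx must be non-negative", call. = FALSE)
  bad <- which(L[-omega] == 0 & L[-1] > 0)
  if (length(bad)) {
    stop("invalid life table: Lx is zero at class ", bad[1],
         " but positive at class ", bad[1] + 1, call. = FALSE)
  }
  p <- numeric(omega)
  nz <- L[-omega] > 0
  p[-omega][nz] <- pmin(pmax(L[-1][nz] / L[-omega][nz], 0), 1)
  list(
    fertility = fertility_schedule(asfr_annual * grid$step_years, frac_female),
    mortality = mortality_schedule(p, sex, Lx = L)
  )
}
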