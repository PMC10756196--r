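#' Kin types and reported categories
#'
#' The kinship recursions track 14 kin types, distinguished by the line
#' through which kin are acquired; they aggregate into the 10 reported
#' categories (older + younger siblings = "siblings", and similarly for
#' niblings, aunts/uncles and cousins).
#'
#' @return A tibble with columns `code`, `category` and `depends_on` (the
#'   recruitment-source type, `NA` for types acquired only at Focal's birth).
#' @export
kin_categories <- function() {
  tibble::tibble(
    code = c("a", "b", "c", "d", "g", "h", "m", "n",
             "p", "q", "r", "s", "t", "v"),
    category = c("children", "grandchildren", "great-grandchildren",
                 "parents", "grandparents", "great-grandparents",
                 "older siblings", "younger siblings",
                 "niblings (older line)", "niblings (younger line)",
                 "aunts/uncles (older)", "aunts/uncles (younger)",
                 "cousins (older line)", "cousins (younger line)"),
    reported = c("children", "grandchildren", "great-grandchildren",
                 "parents", "grandparents", "great-grandparents",
                 "siblings", "siblings", "niblings", "niblings",
                 "aunts/uncles", "aunts/uncles", "cousins", "cousins"),
    depends_on = c("focal", "a", "b", NA, NA, NA, NA, "d",
                   "m", "n", NA, "g", "r", "s")
  )
}

# evaluation order: every type after its initial-condition and recruitment
# dependencies (the recruitment graph is acyclic, so one pass suffices)
kin_eval_order <- c("a", "d", "b", "g", "m", "n",
                    "c", "h", "p", "q", "r", "s", "t", "v")

# boundary (focal age 0) construction per type:
#   zero           -- no kin of this type at Focal's birth
#   pi             -- the parents' age(-sex) distribution itself
#   list(of, mix)  -- sum_x pi_mix[x] * K_of(x): kin of the parent(s), mixed
#                     over the parent's age at Focal's birth. mix = "anc"
#                     runs through both parents (in the one-sex variant the
#                     father term is absent, so it reduces to the mother);
#                     kin are acquired along both the matrilineal and the
#                     patrilineal line in the two-sex model
kin_boundary_rules <- list(
  a = "zero", b = "zero", c = "zero", n = "zero", q = "zero",
  d = "pi",
  g = list(of = "d", mix = "anc"),
  h = list(of = "g", mix = "anc"),
  m = list(of = "a", mix = "anc"),
  p = list(of = "b", mix = "anc"),
  r = list(of = "m", mix = "anc"),
  s = list(of = "n", mix = "anc"),
  t = list(of = "p", mix = "anc"),
  v = list(of = "q", mix = "anc")
)

#' Age distribution of mothers of current newborns
#'
#' The probability that the mother of a randomly chosen newborn belongs to
#' each age class: fertility weighted by the female population structure,
#' `pi[x] = f[x] w[x] / sum(f w)`. This distribution anchors every ancestor
#' and lateral kin boundary condition.
#'
#' @param fs A [fertility_schedule()] or per-step fertility vector.
#' @param w Female population counts by age class (same grid).
#' @return A probability vector summing to 1.
#' @export
#' @examples
#' mother_age_distribution(c(0, 1, 0), c(5, 3, 2))  # single fertile class
mother_age_distribution <- function(fs, w) {
  f <- fert_vec(fs)
  w <- as.numeric(w)
  stopifnot(length(f) == length(w))
  if (any(w < 0)) stop("population counts must be non-negative", call. = FALSE)
  tot <- sum(f * w)
  if (!is.finite(tot) || tot <= 0) {
    stop("zero total births: mothers' age distribution is undefined",
         call. = FALSE)
  }
  f * w / tot
}

#' One step of a kin-population projection
#'
#' Projects one kin array forward a single step: survivors of the existing
#' kin plus kin newly recruited by the source population,
#' `counts' = U %*% counts + F %*% source` (the recruitment term is omitted
#' for kin types acquired only at Focal's birth).
#'
#' @param kin Numeric vector of expected kin counts by age class (stacked
#'   female-then-male in the two-sex model).
#' @param source Recruitment-source kin vector of the same length, or `NULL`.
#' @param U Survival/age-transition matrix ([build_survival_matrix()] or its
#'   two-sex block-diagonal analogue).
#' @param F_ Fertility matrix ([build_fertility_matrix()] or the two-sex
#'   operator).
#' @return The projected kin vector.
#' @export
project_kin_step <- function(kin, source = NULL, U, F_) {
  kin <- as.numeric(kin)
  if (nrow(U) != length(kin)) stop("dimension mismatch", call. = FALSE)
  out <- drop(U %*% kin)
  if (!is.null(source)) {
    source <- as.numeric(source)
    if (ncol(F_) != length(source)) stop("dimension mismatch", call. = FALSE)
    out <- out + drop(F_ %*% source)
  }
  out
}

# ---- internal regime machinery ---------------------------------------------

# survivorship column l[x] = prob of surviving from birth to class x
survivorship_from_p <- function(p) cumprod(c(1, p[-length(p)]))

# stable-equivalent population structures implied by fixed rates: female
# structure from the dominant eigenvalue of the female Leslie matrix,
# male structure from male survivorship discounted at the same growth rate
stable_structures <- function(f, p_f, p_m, alpha) {
  omega <- length(f)
  A <- build_survival_matrix(p_f, age_grid(omega))
  A[1, ] <- A[1, ] + alpha * f
  ev <- eigen(A, only.values = TRUE)$values
  lambda <- max(Re(ev[abs(Im(ev)) < 1e-8 * (1 + abs(Re(ev)))]))
  if (!is.finite(lambda) || lambda <= 0) lambda <- 1
  disc <- lambda^(-(seq_len(omega) - 1))
  list(w_f = survivorship_from_p(p_f) * disc,
       w_m = survivorship_from_p(p_m) * disc,
       lambda = lambda)
}

# build the projection operators + boundary weights for one rate slice.
# pi_source = "stable" (time-invariant boundary) or "observed" (in-projection)
kin_regime <- function(slice, variant = c("two_sex", "one_sex"),
                       pi_source = c("stable", "observed")) {
  variant <- match.arg(variant)
  pi_source <- match.arg(pi_source)
  omega <- slice$grid$n_classes
  alpha <- slice$frac_female
  f <- slice$f
  U_f <- build_survival_matrix(slice$p_f, slice$grid)
  if (pi_source == "stable") {
    st <- stable_structures(f, slice$p_f, slice$p_m, alpha)
    w_f <- st$w_f
    w_m <- st$w_m
  } else {
    w_f <- slice$w_f
    w_m <- slice$w_m
  }
  pi_f <- mother_age_distribution(f, w_f)

  if (variant == "one_sex") {
    # strict female matrilineal model: female kin, daughter recruitment
    F_ <- matrix(0, omega, omega)
    F_[1, ] <- alpha * f
    list(variant = variant, omega = omega, nstate = omega, grid = slice$grid,
         U = U_f, F_ = F_,
         pi = pi_f, pi_mother = pi_f, pi_anc = pi_f,
         d0 = pi_f,
         focal = diag(omega))
  } else {
    # androgynous two-sex model: stacked female/male blocks; kin of both
    # sexes reproduce at the female (androgynous) rates, births split by
    # the sex ratio at birth
    U_m <- build_survival_matrix(slice$p_m, slice$grid)
    U2 <- matrix(0, 2 * omega, 2 * omega)
    U2[1:omega, 1:omega] <- U_f
    U2[(omega + 1):(2 * omega), (omega + 1):(2 * omega)] <- U_m
    F2 <- matrix(0, 2 * omega, 2 * omega)
    F2[1, ] <- alpha * c(f, f)
    F2[omega + 1, ] <- (1 - alpha) * c(f, f)
    # fathers' age distribution: male population weighted by the
    # androgynous fertility schedule
    pi_m <- mother_age_distribution(f, w_m)
    focal <- rbind(diag(omega), matrix(0, omega, omega))
    list(variant = variant, omega = omega, nstate = 2 * omega,
         grid = slice$grid, U = U2, F_ = F2,
         pi = pi_f, pi_father = pi_m,
         pi_mother = pi_f, pi_anc = pi_f + pi_m,
         d0 = c(pi_f, pi_m),
         focal = focal)
  }
}

# boundary vector for one type given the regime and the full-age arrays of
# already-computed types at the same time
kin_boundary <- function(type, regime, arrays) {
  rule <- kin_boundary_rules[[type]]
  if (identical(rule, "zero")) return(numeric(regime$nstate))
  if (identical(rule, "pi")) return(regime$d0)
  wts <- if (rule$mix == "anc") regime$pi_anc else regime$pi_mother
  drop(arrays[[rule$of]] %*% wts)
}

# full network over focal ages under one fixed regime
kin_network_fixed <- function(regime) {
  omega <- regime$omega
  src_of <- stats::setNames(kin_categories()$depends_on, kin_categories()$code)
  arrays <- list()
  for (type in kin_eval_order) {
    K <- matrix(0, regime$nstate, omega)
    K[, 1] <- kin_boundary(type, regime, arrays)
    src_name <- src_of[[type]]
    src <- if (is.na(src_name)) NULL
           else if (src_name == "focal") regime$focal
           else arrays[[src_name]]
    for (x in seq_len(omega - 1)) {
      K[, x + 1] <- drop(regime$U %*% K[, x])
      if (!is.null(src)) K[, x + 1] <- K[, x + 1] + drop(regime$F_ %*% src[, x])
    }
    arrays[[type]] <- K
  }
  arrays
}

new_kin_network <- function(arrays, grid, variant, year, times = NULL) {
  structure(list(arrays = arrays, grid = grid, variant = variant,
                 year = year, times = times),
            class = if (is.null(times)) "kin_network"
                    else c("kin_network_series", "kin_network"))
}

#' Kinship network under time-invariant rates
#'
#' Computes the expected age-sex distribution of every kin type of a female
#' Focal at every Focal age, assuming one fixed set of fertility and survival
#' schedules has been operating indefinitely (the "stable" boundary model
#' used as the initial condition of a time-varying projection). The mothers'
#' age distribution uses the stable-equivalent population implied by the
#' fixed rates.
#'
#' @param series A `rate_series` (see [as_rate_series()]).
#' @param year Calendar year of the slice to use; defaults to the first.
#' @param variant `"two_sex"` (androgynous, the default) or `"one_sex"`
#'   (strict female matrilineal model: female kin only, daughter
#'   recruitment).
#' @return A `kin_network`: expected kin counts by type, kin age class (and
#'   sex in the two-sex variant) for every Focal age. Use [generics::tidy()]
#'   for a tibble view, [total_family_size()] and [mean_kin_age()] for
#'   summaries.
#' @export
time_invariant_kinship <- function(series, year = NULL,
                                   variant = c("two_sex", "one_sex")) {
  variant <- match.arg(variant)
  stopifnot(inherits(series, "rate_series"))
  j <- if (is.null(year)) 1L else match(year, series$times)
  if (is.na(j)) stop("year ", year, " not in the series", call. = FALSE)
  regime <- kin_regime(rate_slice(series, j), variant, pi_source = "stable")
  new_kin_network(kin_network_fixed(regime), series$grid, variant,
                  series$times[j])
}

#' Kinship network under time-varying rates
#'
#' Marches the kinship network forward through a sequence of rate schedules:
#' each kin array at Focal age x+1 and time t+1 is the survivors of the
#' time-t array plus recruitment from its source kin under the time-t
#' operators, while the Focal-age-0 boundary at each new time is rebuilt from
#' the contemporaneous arrays of prospective parents, with the mothers' age
#' distribution taken from the observed population structure.
#'
#' @param series A `rate_series` covering the projection horizon.
#' @param variant `"two_sex"` or `"one_sex"`, as in
#'   [time_invariant_kinship()].
#' @param initial A full-age `kin_network` at the first time of `series`;
#'   defaults to [time_invariant_kinship()] on the first slice.
#' @return A `kin_network_series` holding arrays of dimension
#'   (kin state x Focal age x time).
#' @export
time_variant_kinship <- function(series, variant = c("two_sex", "one_sex"),
                                 initial = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(series, "rate_series"))
  omega <- series$grid$n_classes
  nt <- length(series$times)
  if (is.null(initial)) {
    initial <- time_invariant_kinship(series, variant = variant)
  }
  if (!inherits(initial, "kin_network") ||
      initial$variant != variant ||
      initial$grid$n_classes != omega ||
      !isTRUE(all.equal(initial$year, series$times[1]))) {
    stop("`initial` must be a kin_network on the same grid and variant at ",
         "the first time of the series", call. = FALSE)
  }
  nstate <- if (variant == "one_sex") omega else 2L * omega
  src_of <- stats::setNames(kin_categories()$depends_on, kin_categories()$code)
  out <- lapply(kin_eval_order, function(t) array(0, c(nstate, omega, nt)))
  names(out) <- kin_eval_order
  for (type in kin_eval_order) out[[type]][, , 1] <- initial$arrays[[type]]

  for (j in seq_len(nt - 1)) {
    regime_t <- kin_regime(rate_slice(series, j), variant, "observed")
    regime_next <- kin_regime(rate_slice(series, j + 1), variant, "observed")
    cur <- lapply(out, function(a) a[, , j, drop = FALSE][, , 1])
    nxt <- list()
    for (type in kin_eval_order) {
      K <- matrix(0, nstate, omega)
      src_name <- src_of[[type]]
      src <- if (is.na(src_name)) NULL
             else if (src_name == "focal") regime_t$focal
             else cur[[src_name]]
      K[, 2:omega] <- regime_t$U %*% cur[[type]][, 1:(omega - 1)]
      if (!is.null(src)) {
        K[, 2:omega] <- K[, 2:omega] + regime_t$F_ %*% src[, 1:(omega - 1)]
      }
      K[, 1] <- kin_boundary(type, regime_next, nxt)
      nxt[[type]] <- K
      out[[type]][, , j + 1] <- K
    }
  }
  new_kin_network(out, series$grid, variant, series$times[1],
                  times = series$times)
}

#' @export
print.kin_network <- function(x, ...) {
  kind <- if (inherits(x, "kin_network_series")) {
    sprintf("%d times (%s-%s)", length(x$times), min(x$times), max(x$times))
  } else sprintf("year %s", x$year)
  cat(sprintf("<kin_network> %s variant, %d age classes, %s\n",
              x$variant, x$grid$n_classes, kind))
  invisible(x)
}

# ---- accessors -------------------------------------------------------------

# internal: matrix (nstate x omega) for one type at one time
kin_slab <- function(net, type, year = NULL) {
  a <- net$arrays[[type]]
  if (is.null(a)) stop("kin type not in network: ", type, call. = FALSE)
  if (inherits(net, "kin_network_series")) {
    j <- if (is.null(year)) length(net$times) else match(year, net$times)
    if (is.na(j)) stop("year ", year, " not in network", call. = FALSE)
    a[, , j, drop = FALSE][, , 1]
  } else a
}

#' Expected kin counts as an age-sex vector
#'
#' @param net A `kin_network` or `kin_network_series`.
#' @param type One of the 14 kin-type codes (see [kin_categories()]).
#' @param focal_age Focal's age in years (a lower bound of the grid).
#' @param year Calendar year (for network series).
#' @return A tibble with columns `sex`, `kin_age` (class lower bound, years)
#'   and `count`.
#' @export
kin_counts <- function(net, type, focal_age, year = NULL) {
  x <- age_to_class(focal_age, net$grid)
  v <- kin_slab(net, type, year)[, x]
  omega <- net$grid$n_classes
  if (net$variant == "one_sex") {
    tibble::tibble(sex = "female", kin_age = net$grid$lower_bounds, count = v)
  } else {
    tibble::tibble(sex = rep(c("female", "male"), each = omega),
                   kin_age = rep(net$grid$lower_bounds, 2), count = v)
  }
}
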