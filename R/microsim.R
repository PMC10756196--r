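#' Simulate an explicit genealogy under given rates
#'
#' A brute-force individual-based counterpart of the kinship kernel: starts
#' from founders drawn from the stable age distribution, then at every step
#' each living woman in age class x bears a Poisson number of offspring
#' (expectation = the per-step fertility rate; in the one-sex variant the
#' daughter rate `frac_female * f`, all offspring female) and every
#' individual survives to the next class with the sex-specific probability
#' `p[x]`. Newborns enter age class 0 at the next step; a mother's births in
#' a step do not depend on her surviving it, matching the projection-matrix
#' event order. In the two-sex variant fathers are sampled from living men
#' with weights proportional to the androgynous fertility at their age.
#'
#' @param rates A `rate_series`; a single-time series gives a constant-rate
#'   regime, a longer one is walked slice by slice (the last slice repeats
#'   if the simulation outruns it).
#' @param n_founders Number of founders (at least 100 recommended for
#'   stable tallies).
#' @param burn_in_steps Steps simulated before the tally window; with six
#'   generations or more of burn-in, great-grandparents of sampled Focals
#'   are themselves in-simulation individuals.
#' @param horizon_steps Further steps after burn-in.
#' @param seed Integer seed.
#' @param variant `"one_sex"` (female matrilineal) or `"two_sex"`.
#' @param deterministic If `TRUE`, Poisson draws are replaced by their
#'   (rounded) expectations — intended for integer-valued test schedules.
#' @return A `genealogy`: a tibble with columns `id`, `sex`, `birth`,
#'   `death` (step indices; `NA` death = alive at the end), `mother_id`,
#'   `father_id`, with attributes `n_steps`, `grid`, `variant` and
#'   `extinct`.
#' @export
simulate_genealogy <- function(rates, n_founders = 500, burn_in_steps = 30,
                               horizon_steps = 5, seed = 1,
                               variant = c("one_sex", "two_sex"),
                               deterministic = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(rates, "rate_series"), n_founders >= 1)
  set.seed(seed)
  grid <- rates$grid
  omega <- grid$n_classes
  alpha <- rates$frac_female
  n_steps <- burn_in_steps + horizon_steps
  nt <- length(rates$times)

  sl1 <- rate_slice(rates, 1)
  st <- stable_structures(sl1$f, sl1$p_f, sl1$p_m, alpha)
  founder_class <- sample.int(omega, n_founders, replace = TRUE,
                              prob = st$w_f / sum(st$w_f))
  # columns grown in chunks; founders get negative births so that
  # age-in-steps at time t is t - birth
  cap <- max(4L * n_founders, 1024L)
  birth <- integer(cap); death <- integer(cap)
  mother <- integer(cap); father <- integer(cap); female <- logical(cap)
  n <- n_founders
  birth[1:n] <- -(founder_class - 1L)
  death[1:n] <- NA_integer_
  mother[1:n] <- NA_integer_
  father[1:n] <- NA_integer_
  female[1:n] <- if (variant == "one_sex") TRUE else
    stats::runif(n_founders) < alpha
  alive <- seq_len(n)
  extinct <- FALSE

  grow <- function(need) {
    while (need > cap) {
      newcap <- 2L * cap
      length(birth) <<- newcap; length(death) <<- newcap
      length(mother) <<- newcap; length(father) <<- newcap
      length(female) <<- newcap
      cap <<- newcap
    }
  }

  for (t in 0:(n_steps - 1)) {
    if (!length(alive)) { extinct <- TRUE; break }
    sl <- rate_slice(rates, min(t + 1L, nt))
    cls <- t - birth[alive] + 1L            # 1-based age class at time t
    # births from living women at time t; newborns appear at t + 1
    fem <- alive[female[alive]]
    fem_cls <- t - birth[fem] + 1L
    lam <- if (variant == "one_sex") alpha * sl$f[fem_cls] else sl$f[fem_cls]
    n_off <- if (deterministic) round(lam) else stats::rpois(length(fem), lam)
    moms <- rep(fem, n_off)
    n_new <- length(moms)
    dads <- rep(NA_integer_, n_new)
    if (variant == "two_sex" && n_new) {
      men <- alive[!female[alive]]
      if (length(men)) {
        men_cls <- t - birth[men] + 1L
        wts <- sl$f[men_cls]
        if (sum(wts) > 0) {
          dads <- men[sample.int(length(men), n_new, replace = TRUE,
                                 prob = wts)]
        }
      }
    }
    # survival of everyone alive at t
    p_ind <- ifelse(female[alive], sl$p_f[cls], sl$p_m[cls])
    lives <- stats::runif(length(alive)) < p_ind
    death[alive[!lives]] <- t + 1L
    alive <- alive[lives]
    if (n_new) {
      grow(n + n_new)
      ids <- n + seq_len(n_new)
      birth[ids] <- t + 1L
      death[ids] <- NA_integer_
      mother[ids] <- moms
      father[ids] <- dads
      female[ids] <- if (variant == "one_sex") TRUE else
        stats::runif(n_new) < alpha
      n <- n + n_new
      alive <- c(alive, ids)
    }
  }
  if (extinct) {
    warning("population went extinct before the horizon; partial genealogy",
            call. = FALSE)
  }
  g <- tibble::tibble(
    id = seq_len(n),
    sex = ifelse(female[1:n], "female", "male"),
    birth = birth[1:n],
    death = death[1:n],
    mother_id = mother[1:n],
    father_id = father[1:n]
  )
  structure(g, class = c("genealogy", class(g)),
            n_steps = n_steps, grid = grid, variant = variant,
            extinct = extinct)
}

#' Export a genealogy as a delimited edge list
#'
#' @param g A `genealogy`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_genealogy <- function(g, path) {
  readr::write_csv(tibble::as_tibble(g), path, progress = FALSE)
  invisible(path)
}

# Number of generational ascents in the pedigree path to each kin type.
# The kernel's boundary conditions take the parent's kin arrays at the birth
# instant (the mothers' age distribution mixes states of women counted at
# the start of the birth interval), whereas the simulation's integer clock
# ticks once between that count and the newborn cohort's appearance; each
# ascent therefore contributes one extra survival/aging step on the
# simulation clock. Tallying a kin type at (time - ascents) evaluates every
# pedigree path on exactly the kernel's clock.
kin_ascents <- c(a = 0L, b = 0L, c = 0L, d = 1L, g = 2L, h = 3L,
                 m = 1L, n = 1L, p = 1L, q = 1L,
                 r = 2L, s = 2L, t = 2L, v = 2L)

# internal: children-of lookup built from mother (and father) links
children_lookup <- function(g, two_sex = FALSE) {
  n <- nrow(g)
  out <- vector("list", n)
  add <- function(parent) {
    has <- !is.na(parent)
    sp <- split(which(has), parent[has])
    idx <- as.integer(names(sp))
    for (i in seq_along(idx)) out[[idx[i]]] <<- c(out[[idx[i]]], sp[[i]])
  }
  add(g$mother_id)
  if (two_sex) add(g$father_id)
  out
}

#' Tally kin empirically from a simulated genealogy
#'
#' Walks the pedigree for every eligible Focal (female, alive, in the
#' requested age class at the tally time), classifies her living kin into
#' the 14 kin types by exact pedigree links — children are own offspring,
#' siblings the mother's other offspring split older/younger by birth step,
#' aunts/uncles the parents' siblings, cousins their children, and so on —
#' and reports Monte Carlo means with standard errors across Focals.
#' Kin born in the same step as the reference person of a split (Focal for
#' siblings, the parent for aunts/uncles) belong to the younger array,
#' mirroring the discrete-time model convention (the recursions recruit
#' them through the parent's fertility in the birth step itself).
#'
#' Vital status and age of each kin type are evaluated on the kernel's
#' clock: the projection model's boundary conditions snapshot the parents'
#' kin arrays at the birth instant, so a kin individual reached by `l`
#' generational ascents is tallied at simulation time `time - l` (children
#' at `time`, parents at `time - 1`, grandparents at `time - 2`, ...). This
#' makes the empirical means estimate exactly the expectations the
#' recursions propagate.
#'
#' @param g A `genealogy`.
#' @param focal_age Focal's age in years (class lower bound).
#' @param time Tally time in step indices (defaults to the final step).
#' @param by `"type"` (14 kin types), `"category"` (10 reported categories)
#'   or `"age"` (kin type x kin age class).
#' @param max_focals Cap on the number of Focals used (sampled without
#'   replacement when exceeded).
#' @return A tibble of empirical means with columns `mean`, `se`, `n_focal`
#'   and the relevant keys.
#' @export
tally_kin <- function(g, focal_age, time = NULL,
                      by = c("type", "category", "age"),
                      max_focals = Inf) {
  by <- match.arg(by)
  grid <- attr(g, "grid")
  variant <- attr(g, "variant")
  if (is.null(time)) time <- attr(g, "n_steps")
  x <- age_to_class(focal_age, grid)
  omega <- grid$n_classes

  alive_at <- function(ids, at) {
    ids[!is.na(ids) & g$birth[ids] <= at &
          (is.na(g$death[ids]) | g$death[ids] > at)]
  }
  focals <- which(g$sex == "female" &
                    (time - g$birth) == (x - 1L) &
                    (is.na(g$death) | g$death > time))
  if (length(focals) < 1) {
    stop("no eligible Focal at age ", focal_age, " and time ", time,
         call. = FALSE)
  }
  if (length(focals) > max_focals) {
    focals <- sample(focals, max_focals)
  }
  kids_of <- children_lookup(g, two_sex = (variant == "two_sex"))
  kids <- function(ids) {
    ids <- ids[!is.na(ids)]
    if (!length(ids)) integer(0) else unlist(kids_of[ids], use.names = FALSE)
  }
  parents_of <- function(ids) {
    ids <- ids[!is.na(ids)]
    if (variant == "two_sex") c(g$mother_id[ids], g$father_id[ids])
    else g$mother_id[ids]
  }
  split_by_birth <- function(ids, ref_id) {
    ref <- g$birth[ref_id]
    # same-cohort kin count as younger: the recursions recruit them through
    # the parent's post-birth fertility term (first entry of the younger
    # array), never through the older array's initial condition
    list(older = ids[g$birth[ids] < ref], younger = ids[g$birth[ids] >= ref])
  }

  codes <- kin_categories()$code
  nf <- length(focals)
  counts <- array(0, c(nf, length(codes), omega),
                  dimnames = list(NULL, codes, NULL))
  for (i in seq_len(nf)) {
    fo <- focals[i]
    k <- list()
    k$a <- kids(fo)
    k$b <- kids(k$a)
    k$c <- kids(k$b)
    k$d <- parents_of(fo)
    k$g <- parents_of(k$d)
    k$h <- parents_of(k$g)
    # siblings through either parent (patrilineal half-siblings included in
    # the two-sex model, where parents_of returns mother and father)
    sibs <- setdiff(unique(kids(k$d)), fo)
    sp <- split_by_birth(sibs, fo)
    k$m <- sp$older
    k$n <- sp$younger
    k$p <- kids(k$m)
    k$q <- kids(k$n)
    pa_sibs <- function(par) {
      gp <- parents_of(par)
      gp <- gp[!is.na(gp)]
      if (!length(gp)) return(list(older = integer(0), younger = integer(0)))
      split_by_birth(setdiff(unique(kids(gp)), par), par)
    }
    parents <- unique(k$d[!is.na(k$d)])
    au <- lapply(parents, pa_sibs)
    k$r <- unlist(lapply(au, `[[`, "older"), use.names = FALSE)
    k$s <- unlist(lapply(au, `[[`, "younger"), use.names = FALSE)
    k$t <- kids(k$r)
    k$v <- kids(k$s)
    for (code in codes) {
      at <- time - kin_ascents[[code]]
      ids <- alive_at(unique(k[[code]]), at)
      if (length(ids)) {
        ages <- at - g$birth[ids] + 1L
        counts[i, code, ] <- tabulate(ages, nbins = omega)
      }
    }
  }

  cats <- kin_categories()
  if (by == "age") {
    res <- purrr::map_dfr(seq_along(codes), function(ci) {
      m <- matrix(counts[, ci, ], nrow = nf)
      tibble::tibble(
        kin_type = codes[ci],
        kin_age = grid$lower_bounds,
        mean = colMeans(m),
        se = apply(m, 2, stats::sd) / sqrt(nf),
        n_focal = nf
      )
    })
    return(res)
  }
  totals <- matrix(apply(counts, c(1, 2), sum), nrow = nf,
                   dimnames = list(NULL, codes))
  if (by == "category") {
    rep_cat <- stats::setNames(cats$reported, cats$code)
    cats10 <- unique(cats$reported)
    agg <- matrix(0, nf, length(cats10), dimnames = list(NULL, cats10))
    for (rc in cats10) {
      agg[, rc] <- rowSums(totals[, codes[rep_cat[codes] == rc],
                                  drop = FALSE])
    }
    tibble::tibble(
      kin_category = cats10,
      mean = colMeans(agg),
      se = apply(agg, 2, stats::sd) / sqrt(nf),
      n_focal = nf
    )
  } else {
    tibble::tibble(
      kin_type = codes,
      kin_category = cats$reported,
      mean = colMeans(totals),
      se = apply(totals, 2, stats::sd) / sqrt(nf),
      n_focal = nf
    )
  }
}

#' Compare the kinship kernel against the microsimulation oracle
#'
#' Runs [time_invariant_kinship()] and [simulate_genealogy()] +
#' [tally_kin()] under the same constant-rate regime and reports, for every
#' reported kin category at the requested Focal ages, the kernel
#' expectation, the Monte Carlo mean, and the discrepancy in Monte Carlo
#' standard errors. The SE used is the larger of the empirical SE across
#' Focals and the Poisson model SE `sqrt(mu / n)`, which is the relevant
#' scale for rare kin whose empirical spread degenerates to zero.
#'
#' @param series A constant-rate `rate_series` (first slice used).
#' @param focal_ages Focal ages in years to compare at.
#' @param n_founders,burn_in_steps,horizon_steps,seed Passed to
#'   [simulate_genealogy()].
#' @param variant Kernel/simulation variant.
#' @param max_focals Cap per Focal age in [tally_kin()].
#' @return A tibble with columns `focal_age`, `kin_category`, `kernel`,
#'   `simulated`, `se`, `z`.
#' @export
oracle_check <- function(series, focal_ages = c(0, 35, 65),
                         n_founders = 2000, burn_in_steps = 30,
                         horizon_steps = 6, seed = 1,
                         variant = "one_sex", max_focals = 1500) {
  net <- time_invariant_kinship(series, variant = variant)
  g <- simulate_genealogy(series, n_founders = n_founders,
                          burn_in_steps = burn_in_steps,
                          horizon_steps = horizon_steps, seed = seed,
                          variant = variant)
  cats <- kin_categories()
  purrr::map_dfr(focal_ages, function(fa) {
    sim <- tally_kin(g, fa, by = "category", max_focals = max_focals)
    kern <- tidy(net, focal_ages = fa) |>
      dplyr::group_by(.data$kin_category) |>
      dplyr::summarise(kernel = sum(.data$count), .groups = "drop")
    out <- dplyr::inner_join(kern, sim, by = "kin_category")
    se_used <- pmax(out$se, sqrt(pmax(out$kernel, 0) / out$n_focal))
    tibble::tibble(
      focal_age = fa,
      kin_category = out$kin_category,
      kernel = out$kernel,
      simulated = out$mean,
      se = se_used,
      z = ifelse(se_used > 0, (out$mean - out$kernel) / se_used, 0)
    )
  })
}
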