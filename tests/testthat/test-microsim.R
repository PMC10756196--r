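test_that("without fertility the population only ages and dies", {
  tab <- rates_table(asfr = c(0, 0, 0))
  s <- as_rate_series(tab)
  # founders cannot be drawn from a stable distribution without growth;
  # the survivorship-weighted fallback applies
  expect_warning(
    g <- simulate_genealogy(s, n_founders = 50, burn_in_steps = 4,
                            horizon_steps = 0, seed = 1),
    "extinct")
  expect_equal(nrow(g), 50)
  expect_true(all(is.na(g$mother_id)))
  expect_true(all(g$death <= 3, na.rm = TRUE))
})

test_that("deterministic births with certain survival double each generation", {
  # two guaranteed daughters per woman at her second age class
  tab <- rates_table(asfr = c(0, 4 / 5, 0), Lx_f = c(1, 1, 1),
                     Lx_m = c(1, 1, 1))
  s <- as_rate_series(tab, frac_female = 0.5)
  g <- simulate_genealogy(s, n_founders = 64, burn_in_steps = 10,
                          horizon_steps = 0, seed = 2, deterministic = TRUE)
  births <- table(factor(g$birth[g$birth > 0], levels = 1:10))
  # every cohort bears exactly twice its size two steps later
  for (t in 1:8) {
    expect_equal(unname(births[[t + 2]]), 2 * unname(births[[t]]))
  }
})

test_that("lifetime offspring match the survival-adjusted fertility sum", {
  s <- const_series(tfr = 3, e0 = 55)
  g <- simulate_genealogy(s, n_founders = 800, burn_in_steps = 16,
                          horizon_steps = 0, seed = 5)
  omega <- s$grid$n_classes
  alpha <- s$frac_female
  p <- s$surv_f[, 1]
  # closed form: expected daughters per newborn woman over her whole life
  expected <- sum(alpha * s$fert[, 1] *
                    c(1, cumprod(p[-omega]))[seq_len(omega)])
  # women born early enough to complete the reproductive span
  done <- which(!is.na(g$mother_id) & g$birth >= 1 & g$birth <= 4)
  kids <- tabulate(g$mother_id[!is.na(g$mother_id)], nbins = nrow(g))
  got <- kids[done]
  se <- stats::sd(got) / sqrt(length(got))
  expect_gt(length(done), 100)
  expect_lt(abs(mean(got) - expected), 3 * se)
})

test_that("the hand-built pedigree tallies exactly", {
  g <- toy_pedigree()
  out <- tally_kin(g, focal_age = 5, time = 10, by = "type")
  got <- stats::setNames(out$mean, out$kin_type)
  expect_equal(got[["d"]], 1)  # mother
  expect_equal(got[["g"]], 1)  # grandmother
  expect_equal(got[["s"]], 1)  # aunt, younger than the mother
  expect_equal(got[["v"]], 1)  # cousin through that aunt
  others <- setdiff(names(got), c("d", "g", "s", "v"))
  expect_equal(unname(got[others]), rep(0, length(others)))
  # the reported categories aggregate the split codes
  cat_out <- tally_kin(g, focal_age = 5, time = 10, by = "category")
  expect_equal(unname(cat_out$mean[cat_out$kin_category == "aunts/uncles"]), 1)
  expect_equal(unname(cat_out$mean[cat_out$kin_category == "cousins"]), 1)
})

test_that("founder Focals have censored (zero) ancestor counts", {
  g <- tibble::tibble(
    id = 1:2, sex = "female", birth = c(0L, 3L),
    death = NA_integer_, mother_id = c(NA, 1L), father_id = NA_integer_)
  g <- structure(g, class = c("genealogy", class(g)),
                 n_steps = 4L, grid = age_grid(), variant = "one_sex",
                 extinct = FALSE)
  out <- tally_kin(g, focal_age = 20, time = 4, by = "type")
  got <- stats::setNames(out$mean, out$kin_type)
  expect_equal(unname(got[c("d", "g", "h", "m", "n")]), rep(0, 5))
  expect_equal(got[["a"]], 1)
})

test_that("kin relations are symmetric on complete pedigrees", {
  s <- const_series(tfr = 4, e0 = 60)
  g <- simulate_genealogy(s, n_founders = 120, burn_in_steps = 14,
                          horizon_steps = 0, seed = 8)
  kids_of <- kinproj:::children_lookup(g)
  kin_sets <- function(id) {
    kids <- function(ids) {
      ids <- ids[!is.na(ids)]
      if (!length(ids)) integer(0) else
        unlist(kids_of[ids], use.names = FALSE)
    }
    mo <- g$mother_id[id]
    gm <- if (!is.na(mo)) g$mother_id[mo] else NA
    sibs <- if (!is.na(mo)) setdiff(kids(mo), id) else integer(0)
    aunts <- if (!is.na(gm)) setdiff(kids(gm), mo) else integer(0)
    list(siblings = sibs, cousins = kids(aunts))
  }
  # restrict to individuals whose grandmother is in-simulation
  ids <- which(!is.na(g$mother_id) & !is.na(g$mother_id[g$mother_id]) &
                 g$birth >= 6)
  ids <- ids[seq_len(min(length(ids), 150))]
  sets <- lapply(ids, kin_sets)
  names(sets) <- ids
  for (i in seq_along(ids)) {
    for (cz in sets[[i]]$cousins) {
      if (as.character(cz) %in% names(sets)) {
        expect_true(ids[i] %in% sets[[as.character(cz)]]$cousins)
      }
    }
    for (sb in sets[[i]]$siblings) {
      if (as.character(sb) %in% names(sets)) {
        expect_true(ids[i] %in% sets[[as.character(sb)]]$siblings)
      }
    }
  }
})

test_that("the two-sex kernel agrees with a two-sex microsimulation", {
  # sex-symmetric regime (equal survival, even sex ratio at birth): here the
  # androgynous model is exactly consistent with an individual-based
  # population, because the fertility-weighted male and female pools
  # coincide and each man fathers births at the female age-specific rates
  s <- const_series(tfr = 3.6, e0 = 62, male_e0_gap = 0, frac_female = 0.5)
  oc <- oracle_check(s, focal_ages = c(0, 35), n_founders = 1500,
                     burn_in_steps = 24, horizon_steps = 4, seed = 31,
                     variant = "two_sex", max_focals = 3000)
  expect_true(all(abs(oc$z) <= 3))
  # and the headline conditioning: two living parents at birth
  parents <- oc[oc$focal_age == 0 & oc$kin_category == "parents", ]
  expect_equal(parents$kernel, 2, tolerance = 1e-10)
})

test_that("with a male surplus the androgynous model overstates paternal-line kin", {
  # 105 males per 100 female births dilute each man's realized fathering
  # below the female rates; the kernel, which lets male kin reproduce at
  # the full androgynous schedule, therefore sits slightly above the
  # simulated counts for kin acquired through fathers
  s <- const_series(tfr = 3.6, e0 = 62)
  net <- time_invariant_kinship(s, variant = "two_sex")
  g <- simulate_genealogy(s, n_founders = 2500, burn_in_steps = 24,
                          horizon_steps = 4, seed = 31, variant = "two_sex")
  sim <- tally_kin(g, 35, by = "type")
  q_kernel <- sum(kin_counts(net, "q", 35)$count)
  q_sim <- sim$mean[sim$kin_type == "q"]
  expect_gt(q_kernel, q_sim)
})

test_that("genealogies export and re-import as plain tables", {
  s <- const_series()
  g <- simulate_genealogy(s, n_founders = 60, burn_in_steps = 6,
                          horizon_steps = 0, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_genealogy(g, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(g))
  expect_true(all(is.na(back$mother_id) |
                    back$mother_id < back$id))
})
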