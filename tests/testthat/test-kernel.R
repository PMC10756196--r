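test_that("mothers' age distribution is fertility-weighted population", {
  expect_equal(mother_age_distribution(c(0, 1, 0), c(5, 3, 2)), c(0, 1, 0))
  expect_equal(mother_age_distribution(c(0, 1, 1), c(1, 1, 1)),
               c(0, 0.5, 0.5))
  expect_equal(mother_age_distribution(c(0, 0.2, 0.1), c(10, 5, 10)),
               c(0, 0.5, 0.5))
  expect_error(mother_age_distribution(c(0, 0, 0), c(1, 1, 1)),
               "zero total births")
  set.seed(3)
  for (i in 1:10) {
    pi_ <- mother_age_distribution(runif(6), runif(6, 1, 10))
    expect_equal(sum(pi_), 1, tolerance = 1e-12)
    expect_true(all(pi_ >= 0))
  }
})

test_that("a single projection step survives kin and recruits newborns", {
  U <- rbind(c(0, 0), c(0.5, 0))
  F_ <- rbind(c(0, 1), c(0, 0))
  expect_equal(project_kin_step(c(0, 0), c(0, 1), U, F_), c(1, 0))
  expect_equal(project_kin_step(c(0, 0), c(0, 0), U, F_), c(0, 0))
  # pure aging with certain survival conserves totals
  U3 <- build_survival_matrix(c(1, 1, 0), age_grid(3))
  expect_equal(project_kin_step(c(2, 0, 0), NULL, U3, matrix(0, 3, 3)),
               c(0, 2, 0))
  expect_error(project_kin_step(c(1, 1, 1), NULL, U, F_), "dimension")
})

test_that("zero fertility leaves the mothers' distribution undefined", {
  tab <- rates_table(asfr = c(0, 0, 0))
  s <- as_rate_series(tab)
  expect_error(time_invariant_kinship(s), "zero total births")
})

test_that("an immortal single-age-class regime gives phi children and phi^2 grandchildren", {
  # recruitment alpha * f = phi concentrated in the second age class;
  # survival 1 everywhere inside the grid
  phi <- 0.8
  tab <- rates_table(ages = seq(0, 25, 5), years = 1950,
                     asfr = c(0, 2 * phi / 5, 0, 0, 0, 0),
                     Lx_f = rep(1, 6), Lx_m = rep(1, 6),
                     pop_f = rep(1, 6))
  s <- as_rate_series(tab, frac_female = 0.5)
  net <- time_invariant_kinship(s, variant = "one_sex")
  a_tot <- type_totals(net, "a")
  expect_equal(unname(a_tot[1:2]), c(0, 0))
  expect_equal(unname(a_tot[3:6]), rep(phi, 4), tolerance = 1e-12)
  b_tot <- type_totals(net, "b")
  expect_equal(unname(b_tot[1:4]), rep(0, 4))
  expect_equal(unname(b_tot[5:6]), rep(phi^2, 2), tolerance = 1e-12)
})

test_that("a newborn has one living mother in the one-sex model and two parents in the two-sex model", {
  s <- const_series()
  one <- time_invariant_kinship(s, variant = "one_sex")
  two <- time_invariant_kinship(s, variant = "two_sex")
  expect_equal(unname(type_totals(one, "d")[1]), 1, tolerance = 1e-12)
  expect_equal(unname(type_totals(two, "d")[1]), 2, tolerance = 1e-12)
  # and no younger siblings can exist at Focal's birth
  expect_equal(unname(type_totals(one, "n")[1]), 0)
  expect_equal(unname(type_totals(two, "n")[1]), 0)
})

test_that("children counts match the analytic survival-weighted sum of past births", {
  s <- const_series(tfr = 4.4, e0 = 63)
  net <- time_invariant_kinship(s, variant = "one_sex")
  omega <- s$grid$n_classes
  f_rec <- s$frac_female * s$fert[, 1]
  p <- s$surv_f[, 1]
  closed_form <- vapply(0:(omega - 1), function(x) {
    if (x == 0) return(0)
    sum(vapply(0:(x - 1), function(y) {
      f_rec[y + 1] * prod(p[seq_len(x - y - 1)])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(type_totals(net, "a")), closed_form,
               tolerance = 1e-10)
})

test_that("kin arrays are nonnegative and finite across random regimes", {
  set.seed(11)
  for (i in 1:8) {
    s <- const_series(tfr = runif(1, 0.8, 6.5), e0 = runif(1, 35, 88),
                      mean_age_childbearing = runif(1, 22, 36))
    net <- time_invariant_kinship(s, variant = sample(c("one_sex", "two_sex"), 1))
    for (arr in net$arrays) {
      expect_true(all(is.finite(arr)))
      expect_true(all(arr >= 0))
    }
  }
})

test_that("symmetric sexes double descendants and quadruple grandparents", {
  s <- const_series(tfr = 3.5, e0 = 65, male_e0_gap = 0)
  one <- time_invariant_kinship(s, variant = "one_sex")
  two <- time_invariant_kinship(s, variant = "two_sex")
  alpha <- s$frac_female
  # children of both sexes vs daughters only: factor 1/alpha
  expect_equal(type_totals(two, "a"), type_totals(one, "a") / alpha,
               tolerance = 1e-10)
  expect_equal(unname(type_totals(two, "d")[1]), 2, tolerance = 1e-12)
  expect_equal(type_totals(two, "g")[1], 4 * type_totals(one, "g")[1],
               tolerance = 1e-10)
  expect_equal(type_totals(two, "h")[1], 8 * type_totals(one, "h")[1],
               tolerance = 1e-10)
})

test_that("fathers vanish when male survival is zero", {
  tab <- rates_table(Lx_m = c(5, 1e-9, 0))
  s <- as_rate_series(tab)
  net <- time_invariant_kinship(s, variant = "two_sex")
  omega <- s$grid$n_classes
  male_d <- kinproj:::kin_slab(net, "d")[(omega + 1):(2 * omega), ]
  expect_lt(max(colSums(male_d)[-1]), 1e-9)
  # the mother side is untouched
  female_d <- kinproj:::kin_slab(net, "d")[1:omega, ]
  expect_equal(sum(female_d[, 1]), 1, tolerance = 1e-12)
})

test_that("time-varying projection reduces to the fixed-rate network under constant rates", {
  s <- const_series(tfr = 3.8, e0 = 62, years = seq(1950, 1975, 5))
  for (variant in c("one_sex", "two_sex")) {
    fixed <- time_invariant_kinship(s, variant = variant)
    varying <- time_variant_kinship(s, variant = variant)
    for (type in names(fixed$arrays)) {
      for (j in seq_along(s$times)) {
        expect_lt(max(abs(varying$arrays[[type]][, , j] -
                            fixed$arrays[[type]])), 1e-10)
      }
    }
  }
})

test_that("a two-period toy projection matches hand matrix arithmetic", {
  tab <- dplyr::bind_rows(
    rates_table(years = 1950, asfr = c(0, 0.08, 0.04), Lx_f = c(5, 4, 2),
                Lx_m = c(5, 4, 2), pop_f = c(10, 5, 5)),
    rates_table(years = 1955, asfr = c(0, 0.06, 0.02), Lx_f = c(5, 4.5, 3),
                Lx_m = c(5, 4.5, 3), pop_f = c(8, 6, 4))
  )
  s <- as_rate_series(tab, frac_female = 0.5)
  net <- time_variant_kinship(s, variant = "one_sex")
  # children: recruited from Focal at 1950 rates, f_step = (0, .4, .2);
  # a Focal in class 3 at 1955 bore daughters while in class 2 at 1950
  a_1955 <- net$arrays$a[, , 2]
  expect_equal(a_1955[, 2], c(0, 0, 0))          # fertility zero in class 1
  expect_equal(a_1955[, 3], c(0.5 * 0.4, 0, 0))
  # the age-0 parent boundary at 1955 is the observed-population pi
  pi_1955 <- c(0, 0.3 * 6, 0.1 * 4) / (0.3 * 6 + 0.1 * 4)
  expect_equal(net$arrays$d[, 1, 2], pi_1955, tolerance = 1e-12)
  # interior parents advance by 1950 survival: d(1, 1955) = U_1950 d(0, 1950)
  U0 <- build_survival_matrix(c(4 / 5, 2 / 4, 0), s$grid)
  expect_equal(net$arrays$d[, 2, 2],
               drop(U0 %*% net$arrays$d[, 1, 1]), tolerance = 1e-12)
})

test_that("lower survival in the final period depresses surviving kin", {
  s <- const_series(tfr = 4, e0 = 60, years = seq(1950, 1960, 5))
  s2 <- s
  s2$surv_f[, 2] <- s$surv_f[, 2] / 2
  s2$surv_m[, 2] <- s$surv_m[, 2] / 2
  base <- time_variant_kinship(s, variant = "two_sex")
  hit <- time_variant_kinship(s2, variant = "two_sex")
  last <- length(s$times)
  omega <- s$grid$n_classes
  for (type in names(base$arrays)) {
    b <- colSums(base$arrays[[type]][, , last])
    h <- colSums(hit$arrays[[type]][, , last])
    # strict decrease wherever a survived component exists; recruitment in
    # the final interval and the rebuilt age-0 boundary are untouched by
    # survival, so only those entries can tie
    survived <- colSums(base$arrays[[type]][, , last - 1])[-omega] > 1e-12
    keep <- c(FALSE, survived)
    expect_true(all(h[keep] < b[keep]))
    expect_true(all(h <= b + 1e-12))
  }
})

test_that("the androgynous flag is explicit on rate series", {
  s <- const_series()
  expect_true(make_androgynous(s)$androgynous)
})

test_that("tidy and glance views of a network are consistent with accessors", {
  s <- const_series(years = c(1950, 1955))
  net <- time_variant_kinship(s)
  td <- tidy(net, focal_ages = c(0, 35), years = 1955)
  expect_setequal(unique(td$kin_type), kin_categories()$code)
  expect_equal(
    td |> dplyr::filter(kin_type == "d", focal_age == 35) |>
      dplyr::pull(count) |> sum(),
    sum(kin_counts(net, "d", 35, 1955)$count))
  gl <- glance(net)
  expect_equal(gl$family_size_at_birth, total_family_size(net, 0, 1950))
  expect_equal(gl$n_times, 2L)
})
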