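test_that("table validation names eyes with missing replicates", {
  tab <- simulate_repeated_table(n_subjects = 5, n_two_eyed = 2, seed = 1)
  expect_silent(validate_repeated_table(tab))
  bad <- tab[-1, ]
  expect_error(validate_repeated_table(bad), "S001")
  tab2 <- tab; tab2$replicate[1] <- 3L
  expect_error(validate_repeated_table(tab2), "replicate")
})

test_that("duplicated replicates give exactly zero imprecision", {
  tab <- simulate_repeated_table(n_subjects = 6, n_two_eyed = 2, seed = 2)
  tab$value[tab$replicate == 2] <- tab$value[tab$replicate == 1]
  est <- fit_measurement_error_model(tab, "pore_diameter_mean")
  expect_identical(est$imprecision_sd, 0)
  expect_identical(est$relative_imprecision, 0)
})

test_that("REML residual equals the balanced-case closed form", {
  # one eye per subject, two replicates: residual variance is the within-eye
  # mean square, i.e. RMS(paired differences about zero) / sqrt(2)
  tab <- simulate_repeated_table(n_subjects = 20, n_two_eyed = 0,
                                 subject_sd = 2, eye_sd = 0,
                                 residual_sd = 0.5, seed = 4)
  est <- fit_measurement_error_model(tab, "pore_diameter_mean")
  w <- lcmicro:::eye_pairs(tab)
  closed_form <- sqrt(sum(w$diff^2) / (2 * nrow(w)))
  expect_equal(est$imprecision_sd, closed_form, tolerance = 1e-8)
})

test_that("imprecision estimate is scale-equivariant and shift-invariant", {
  tab <- simulate_repeated_table(n_subjects = 15, n_two_eyed = 5, seed = 6)
  est <- fit_measurement_error_model(tab, "pore_diameter_mean")
  tab_sc <- tab; tab_sc$value <- tab$value * 3
  est_sc <- fit_measurement_error_model(tab_sc, "pore_diameter_mean")
  expect_equal(est_sc$imprecision_sd, 3 * est$imprecision_sd, tolerance = 1e-6)
  expect_equal(est_sc$relative_imprecision, est$relative_imprecision,
               tolerance = 1e-6)
  tab_sh <- tab; tab_sh$value <- tab$value + 100
  est_sh <- fit_measurement_error_model(tab_sh, "pore_diameter_mean")
  expect_equal(est_sh$imprecision_sd, est$imprecision_sd, tolerance = 1e-6)
})

test_that("modelling the eye level keeps anatomy out of the error term", {
  tab <- simulate_repeated_table(n_subjects = 30, n_two_eyed = 30,
                                 subject_sd = 2, eye_sd = 1.5,
                                 residual_sd = 0.3, seed = 9)
  est <- fit_measurement_error_model(tab, "pore_diameter_mean")
  expect_lte(est$imprecision_sd, sd(tab$value))
  expect_equal(est$imprecision_sd, 0.3, tolerance = 0.15)
})

test_that("relative imprecision formula and guards", {
  expect_equal(relative_imprecision(0, 10), 0)
  expect_error(relative_imprecision(1, 0), "nonzero")
})

test_that("per-group fits are independent and symmetric", {
  a <- simulate_repeated_table(n_subjects = 10, n_two_eyed = 3, group = "A", seed = 3)
  b <- a; b$group <- "B"
  both <- rbind(a, b)
  ests <- imprecision_by_group(both, "pore_diameter_mean")
  expect_named(ests, c("A", "B"))
  expect_equal(ests$A$imprecision_sd, ests$B$imprecision_sd)
  single <- fit_measurement_error_model(a, "pore_diameter_mean")
  expect_equal(ests$A$imprecision_sd, single$imprecision_sd)
  # tiny groups are flagged, not fatal
  tiny <- simulate_repeated_table(n_subjects = 3, n_two_eyed = 0, group = "C", seed = 8)
  ests2 <- imprecision_by_group(rbind(a, tiny), "pore_diameter_mean")
  expect_true(ests2$C$flag_small)
})

test_that("bootstrap variance ratio behaves for identical and degenerate groups", {
  a <- simulate_repeated_table(n_subjects = 12, n_two_eyed = 0, group = "A", seed = 3)
  ea <- fit_measurement_error_model(a, "pore_diameter_mean")
  cmp <- compare_group_imprecision(ea, ea, draws = 300, seed = 1)
  expect_equal(cmp$ratio, 1)
  expect_lte(cmp$conf_int[1], 1)
  expect_gte(cmp$conf_int[2], 1)
  z <- a; z$value[z$replicate == 2] <- z$value[z$replicate == 1]
  ez <- fit_measurement_error_model(z, "pore_diameter_mean")
  expect_error(compare_group_imprecision(ea, ez), "zero residual")
})

test_that("the bootstrap CI separates groups with a 4x residual-variance gap", {
  hits <- vapply(1:40, function(r) {
    ta <- simulate_repeated_table(n_subjects = 20, n_two_eyed = 0,
                                  residual_sd = 0.6, group = "A", seed = 1000 + r)
    tb <- simulate_repeated_table(n_subjects = 20, n_two_eyed = 0,
                                  residual_sd = 0.3, group = "B", seed = 2000 + r)
    ea <- fit_measurement_error_model(ta, "pore_diameter_mean")
    eb <- fit_measurement_error_model(tb, "pore_diameter_mean")
    ci <- compare_group_imprecision(ea, eb, draws = 400, seed = r)$conf_int
    ci[1] > 1 || ci[2] < 1
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("group residual-SD ratios are recovered in simulation", {
  ratios <- vapply(1:25, function(r) {
    ta <- simulate_repeated_table(n_subjects = 20, n_two_eyed = 0,
                                  residual_sd = 0.6, group = "A", seed = 5000 + r)
    tb <- simulate_repeated_table(n_subjects = 20, n_two_eyed = 0,
                                  residual_sd = 0.3, group = "B", seed = 6000 + r)
    ea <- fit_measurement_error_model(ta, "pore_diameter_mean")
    eb <- fit_measurement_error_model(tb, "pore_diameter_mean")
    ea$imprecision_sd / eb$imprecision_sd
  }, numeric(1))
  expect_gte(mean(ratios), 1.6)
  expect_lte(mean(ratios), 2.4)
})
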