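test_that("speckle is multiplicative, unit-mean, with the requested contrast", {
  g <- voxel_grid(c(40L, 40L, 40L), c(1, 1, 1))
  v <- lc_volume(array(100, g$shape), g)
  out <- apply_speckle(v, 0.2, seed = 5)
  expect_equal(mean(out$data), 100, tolerance = 0.01)
  expect_equal(sd(out$data) / mean(out$data), 0.2, tolerance = 0.1)
  expect_true(all(out$data >= 0))
  # contrast zero is the identity
  expect_identical(apply_speckle(v, 0, seed = 5)$data, v$data)
  # different seeds: different fields, same distribution
  out2 <- apply_speckle(v, 0.2, seed = 6)
  expect_false(identical(out$data, out2$data))
  expect_equal(mean(out2$data), mean(out$data), tolerance = 0.01)
  expect_error(apply_speckle(v, -0.1, 1), "contrast")
})

test_that("vessel shadows cover the requested en-face fraction and darken columns", {
  g <- voxel_grid(c(128L, 128L, 32L), c(8.75, 8.75, 4.0625))
  v <- lc_volume(array(100, g$shape), g)
  res <- add_vessel_shadows(v, fraction = 0.2, seed = 9)
  cov <- mean(res$shadow_mask)
  expect_gte(cov, 0.15)
  expect_lte(cov, 0.25)
  sh <- array(rep(res$shadow_mask, g$shape[3]), g$shape)
  expect_lt(mean(res$volume$data[sh]), mean(res$volume$data[!sh]))
  # zero fraction: untouched volume, empty mask
  res0 <- add_vessel_shadows(v, fraction = 0, seed = 9)
  expect_identical(res0$volume$data, v$data)
  expect_false(any(res0$shadow_mask))
})

test_that("noise-free phantom has exactly two intensities inside the slab", {
  ph <- generate_phantom(small_phantom_spec(seed = 3), compute_truth_params = FALSE)
  slab <- ph$truth_labels$labels != 0L
  vals <- sort(unique(ph$volume$data[slab]))
  expect_identical(vals, c(ph$spec$pore_intensity, ph$spec$beam_intensity))
})

test_that("phantom generation is deterministic and validates its spec", {
  a <- generate_phantom(small_phantom_spec(seed = 8), compute_truth_params = FALSE)
  b <- generate_phantom(small_phantom_spec(seed = 8), compute_truth_params = FALSE)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth_labels$labels, b$truth_labels$labels)
  # unresolvable targets error out
  expect_error(
    phantom_spec(grid = voxel_grid(c(32L, 32L, 32L), c(20, 20, 20)),
                 true_pore_diameter_mean = 24, lc_depth = 300),
    "unresolvable")
  expect_error(phantom_spec(beam_intensity = 50, pore_intensity = 60),
               "beam_intensity")
})

test_that("truth-label morphometry recovers the generator targets", {
  ph <- generate_phantom(phantom_spec(seed = 7))
  tp <- ph$truth_params
  expect_gte(tp$pore_diameter_mean, 0.85 * ph$spec$true_pore_diameter_mean)
  expect_lte(tp$pore_diameter_mean, 1.15 * ph$spec$true_pore_diameter_mean)
  expect_gte(tp$beam_thickness_mean, 0.85 * ph$spec$true_beam_thickness_mean)
  expect_lte(tp$beam_thickness_mean, 1.15 * ph$spec$true_beam_thickness_mean)
  # ratio invariant is exact by construction
  expect_identical(tp$beam_pore_ratio,
                   tp$beam_thickness_mean / tp$pore_diameter_mean)
})

test_that("identity repeat scan reproduces the scan bit-exactly", {
  ph <- generate_phantom(small_phantom_spec(seed = 4, speckle = 0.3),
                         compute_truth_params = FALSE)
  rs <- repeat_scan_spec(0, c(0, 0, 0), 1, ph$speckle_seed)
  ph2 <- simulate_repeat_scan(ph, rs, compute_truth_params = FALSE)
  expect_identical(ph2$volume$data, ph$volume$data)
  expect_identical(ph2$truth_labels$labels, ph$truth_labels$labels)
})

test_that("repeat-scan contrast scaling is linear in mean intensity", {
  ph <- generate_phantom(small_phantom_spec(seed = 4, speckle = 0.2),
                         compute_truth_params = FALSE)
  rs <- repeat_scan_spec(0, c(0, 0, 0), 1.2, 99)
  ph2 <- simulate_repeat_scan(ph, rs, compute_truth_params = FALSE)
  slab <- ph$truth_labels$labels != 0L
  expect_equal(mean(ph2$volume$data[slab]) / mean(ph$volume$data[slab]),
               1.2, tolerance = 0.02)
})

test_that("opposite rotations approximately restore the truth labels", {
  ph <- generate_phantom(phantom_spec(seed = 11, shadow_fraction = 0),
                         compute_truth_params = FALSE)
  a <- simulate_repeat_scan(ph, repeat_scan_spec(10, c(0, 0, 0), 1, 5),
                            compute_truth_params = FALSE)
  b <- simulate_repeat_scan(a, repeat_scan_spec(-10, c(0, 0, 0), 1, 6),
                            compute_truth_params = FALSE)
  slab <- ph$truth_labels$labels != 0L
  agree <- mean((b$truth_labels$labels == ph$truth_labels$labels)[slab])
  expect_gte(agree, 0.90)
  expect_error(repeat_scan_spec(20), "15")
})

test_that("the rigid transform moves volume and labels consistently", {
  # a delta marker transformed as intensity (trilinear) and as label (NN)
  # must land at the same voxel neighbourhood
  g <- voxel_grid(c(33L, 33L, 33L), c(1, 1, 1))
  vol <- array(0, g$shape); vol[10, 17, 17] <- 1
  lab <- array(0L, g$shape); lab[10, 17, 17] <- 2L
  out_v <- lcmicro:::cpp_rigid_resample(vol, g$shape, g$spacing, 10, c(0, 0, 0), 1L, 0)
  out_l <- lcmicro:::cpp_rigid_resample(as.numeric(lab), g$shape, g$spacing, 10, c(0, 0, 0), 0L, 0)
  pv <- arrayInd(which.max(out_v), g$shape)
  pl <- arrayInd(which.max(out_l), g$shape)
  expect_lte(sqrt(sum((pv - pl)^2)), sqrt(3) + 1e-9)
  # mass lands where the forward rotation predicts (about the slow axis)
  th <- 10 * pi / 180
  ctr <- (g$shape - 1) / 2 + 1
  p0 <- c(10, 17, 17) - ctr
  pred <- c(cos(th) * p0[1] - sin(th) * p0[3], p0[2],
            sin(th) * p0[1] + cos(th) * p0[3]) + ctr
  expect_lte(sqrt(sum((pv - pred)^2)), sqrt(3) + 1e-9)
})
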