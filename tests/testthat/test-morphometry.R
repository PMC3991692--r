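test_that("local thickness matches the brute-force sphere-fitting oracle", {
  set.seed(101)
  for (trial in 1:8) {
    d <- sample(4:10, 3, replace = TRUE)
    phase <- array(runif(prod(d)) < 0.6, d)
    got <- array(lcmicro:::cpp_local_thickness(phase, d, c(1, 1, 1)), d)
    expect_equal(got, bf_local_thickness(phase, c(1, 1, 1)), tolerance = 1e-12)
  }
  # anisotropic spacing: spheres are physical, not voxel-count, spheres
  for (trial in 1:4) {
    d <- sample(4:9, 3, replace = TRUE)
    phase <- array(runif(prod(d)) < 0.6, d)
    sp <- c(2, 1.5, 0.75)
    got <- array(lcmicro:::cpp_local_thickness(phase, d, sp), d)
    expect_lt(max(abs(got - bf_local_thickness(phase, sp))), 1e-9)
  }
})

test_that("a digital ball measures its own diameter", {
  n <- 25L; ctr <- (n + 1) / 2
  co <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  ball <- array(sqrt(rowSums(sweep(co, 2, ctr, `-`)^2)) <= 10, c(n, n, n))
  th <- array(lcmicro:::cpp_local_thickness(ball, c(n, n, n), c(1, 1, 1)),
              c(n, n, n))
  expect_lte(max(abs(th[ball] - 20)), sqrt(3))
  # anisotropic grid, same physical ball
  sp <- c(2, 2, 1)
  co_um <- sweep(co - ctr, 2, sp, `*`)
  ball2 <- array(sqrt(rowSums(co_um^2)) <= 10, c(n, n, n))
  th2 <- array(lcmicro:::cpp_local_thickness(ball2, c(n, n, n), sp), c(n, n, n))
  expect_lte(max(abs(th2[ball2] - 20)), sqrt(sum(sp^2)))
})

test_that("a slab measures its own thickness away from the lateral borders", {
  d <- c(24L, 24L, 20L); dz <- 4.0625
  phase <- array(FALSE, d); phase[, , 5:16] <- TRUE  # 12 slices = 48.75 um
  th <- array(lcmicro:::cpp_local_thickness(phase, d, c(8.75, 8.75, dz)), d)
  core <- th[5:20, 5:20, 5:16]
  expect_lte(max(abs(core - 12 * dz)), sqrt(2 * 8.75^2 + dz^2))
})

test_that("thickness never decreases when the phase is dilated", {
  set.seed(77)
  for (trial in 1:3) {
    d <- c(12L, 12L, 12L)
    phase <- array(runif(prod(d)) < 0.4, d)
    fat <- lcmicro:::box_dilate(phase, d, c(1L, 1L, 1L))
    t1 <- lcmicro:::cpp_local_thickness(phase, d, c(1, 1, 1))
    t2 <- lcmicro:::cpp_local_thickness(fat, d, c(1, 1, 1))
    expect_true(all(t2[phase] >= t1[phase] - 1e-12))
  }
})

test_that("thickness is bounded by the phase bounding box", {
  set.seed(5)
  d <- c(14L, 14L, 14L)
  phase <- array(FALSE, d); phase[3:9, 2:13, 4:8] <- runif(7 * 12 * 5) < 0.8
  sp <- c(2, 1, 3)
  th <- lcmicro:::cpp_local_thickness(phase, d, sp)
  ext <- c(7 + 1, 12 + 1, 5 + 1) * sp  # bbox voxel counts + virtual margin
  expect_lte(max(th), min(ext) + 1e-9)
})

test_that("thickness maps and stats respect the phase and empty cases", {
  lab <- array(LABEL_OUTSIDE, c(6, 6, 6))
  lab[2:5, 2:5, 2:5] <- LABEL_BEAM
  seg <- seg_from_labels(lab)
  expect_warning(tm <- local_thickness(seg, "pore"), "empty")
  expect_true(all(tm$values == 0))
  expect_error(thickness_stats(tm), "no positive")
  tb <- local_thickness(seg, "beam")
  expect_true(all(tb$values[lab == LABEL_BEAM] > 0))
  expect_true(all(tb$values[lab != LABEL_BEAM] == 0))
})

test_that("thickness stats are voxel-weighted mean and population SD", {
  tmap <- structure(list(values = array(c(rep(0, 4), rep(20, 6), rep(30, 6)),
                                        c(4, 2, 2)),
                         grid = voxel_grid(c(4L, 2L, 2L), c(1, 1, 1)),
                         phase = "pore"), class = "lc_thickness_map")
  s <- thickness_stats(tmap)
  expect_equal(unname(s["mean"]), 25)
  expect_equal(unname(s["sd"]), 5)
  tmap$values[] <- 0; tmap$values[1] <- 24.2
  expect_equal(unname(thickness_stats(tmap)), c(24.2, 0))
})

test_that("slice pore moments recover disk, ellipse and rectangle geometry", {
  mk_seg <- function(inside, n = 64L, spacing = c(1, 1)) {
    lab <- array(LABEL_BEAM, c(n, n, 1))
    lab[, , 1][inside] <- LABEL_PORE
    seg_from_labels(lab, c(spacing, 1))
  }
  n <- 64L
  xy <- as.matrix(expand.grid(1:n, 1:n)) - 32.5
  # disk of radius 10 px: aspect ratio ~1
  disk <- matrix(sqrt(rowSums(xy^2)) <= 10, n, n)
  pd <- slice_pores(mk_seg(disk))
  expect_equal(nrow(pd), 1L)
  expect_gte(pd$aspect_ratio, 1)
  expect_lte(pd$aspect_ratio, 1.05)
  # axis-aligned ellipse semi-axes 20 and 10 px: ratio 2 +- 5%
  ell <- matrix((xy[, 1] / 20)^2 + (xy[, 2] / 10)^2 <= 1, n, n)
  pe <- slice_pores(mk_seg(ell))
  expect_equal(pe$major_axis / pe$minor_axis, 2, tolerance = 0.05)
  # 10 x 20 px rectangle at 8.75 um/px: area = 200 * 8.75^2
  rect <- matrix(FALSE, n, n); rect[21:30, 21:40] <- TRUE
  pr <- slice_pores(mk_seg(rect, spacing = c(8.75, 8.75)))
  expect_equal(pr$area, 200 * 8.75^2)
})

test_that("pores touching the mask boundary or smaller than 4 px are dropped", {
  n <- 32L
  lab <- array(LABEL_OUTSIDE, c(n, n, 1))
  lab[4:29, 4:29, 1] <- LABEL_BEAM
  lab[10:13, 10:13, 1] <- LABEL_PORE      # interior pore: kept
  lab[4:6, 20:23, 1] <- LABEL_PORE        # touches OUTSIDE: dropped
  lab[25, 25, 1] <- LABEL_PORE            # 1 px: dropped
  pores <- slice_pores(seg_from_labels(lab))
  expect_equal(nrow(pores), 1L)
  expect_equal(pores$n_pixels, 16L)
})

test_that("full parameter set obeys its structural invariants", {
  ph <- generate_phantom(small_phantom_spec(seed = 12), compute_truth_params = FALSE)
  p <- compute_lc_params(ph$truth_labels)
  expect_identical(p$beam_pore_ratio, p$beam_thickness_mean / p$pore_diameter_mean)
  expect_gte(p$pore_aspect_ratio_mean, 1)
  expect_gte(p$pore_count_top_half, 0)
  expect_gte(p$pore_count_bottom_half, 0)
  # single-phase segmentations are rejected
  lab <- array(LABEL_BEAM, c(6, 6, 6))
  expect_error(compute_lc_params(seg_from_labels(lab)), "empty pore")
  lab[] <- LABEL_PORE
  expect_error(compute_lc_params(seg_from_labels(lab)), "empty beam")
})

test_that("3D thickness statistics persist under a 10 degree scan rotation", {
  ph <- generate_phantom(phantom_spec(seed = 13, shadow_fraction = 0),
                         compute_truth_params = FALSE)
  rot <- simulate_repeat_scan(ph, repeat_scan_spec(10, c(0, 0, 0), 1, 3),
                              compute_truth_params = FALSE)
  p0 <- thickness_stats(local_thickness(ph$truth_labels, "pore"))
  p1 <- thickness_stats(local_thickness(rot$truth_labels, "pore"))
  expect_lt(abs(p1["mean"] - p0["mean"]) / p0["mean"], 0.10)
})
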