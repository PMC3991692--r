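# Shared fixtures and independent oracles for the test suite.

# Brute-force maximal-inscribed-sphere local thickness: enumerates every
# candidate sphere centre (all phase voxels) with radius equal to its distance
# to the nearest background voxel centre (in-array background plus the
# virtual background just outside the array), then assigns each phase voxel
# the diameter of the largest sphere strictly containing it. Independent of
# the package's distance-transform implementation.
bf_local_thickness <- function(phase, spacing) {
  d <- dim(phase)
  idx <- which(phase)
  coord <- arrayInd(idx, d)
  xyz <- sweep(coord - 1, 2, spacing, `*`)
  bidx <- which(!phase)
  bxyz <- if (length(bidx)) sweep(arrayInd(bidx, d) - 1, 2, spacing, `*`)
  r2 <- numeric(length(idx))
  for (a in seq_along(idx)) {
    cap <- min(coord[a, 1] * spacing[1], (d[1] - coord[a, 1] + 1) * spacing[1],
               coord[a, 2] * spacing[2], (d[2] - coord[a, 2] + 1) * spacing[2],
               coord[a, 3] * spacing[3], (d[3] - coord[a, 3] + 1) * spacing[3])^2
    r2[a] <- if (length(bidx))
      min(min(colSums((t(bxyz) - xyz[a, ])^2)), cap) else cap
  }
  out <- array(0, d)
  for (a in seq_along(idx)) {
    dd <- colSums((t(xyz) - xyz[a, ])^2)
    out[idx[a]] <- 2 * sqrt(max(r2[dd < r2]))
  }
  out
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# small phantom used by several tests (same spacing as the default study grid
# so the cached microstructure calibration is shared)
small_phantom_spec <- function(seed = 3, speckle = 0, shadows = 0) {
  phantom_spec(grid = voxel_grid(c(64L, 64L, 64L)),
               lc_depth = 180, speckle_contrast = speckle,
               shadow_fraction = shadows, seed = seed)
}

# segmentation container from a plain label array on an isotropic grid
seg_from_labels <- function(labels, spacing = c(1, 1, 1)) {
  lc_segmentation(labels, voxel_grid(dim(labels), spacing))
}
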