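#' Phantom specification
#'
#' Parameters of a synthetic lamina cribrosa (LC) volume with known
#' ground-truth microarchitecture. The microstructure is a thresholded,
#' anisotropically smoothed Gaussian random field whose smoothing scale and
#' threshold are calibrated so that sphere-fitting morphometry on the truth
#' labels recovers the requested pore diameter and beam thickness. Defaults
#' target the microarchitecture of a typical adult LC (pore diameter ~24 um,
#' beam thickness ~49 um, en-face pore aspect ratio ~2) on a desk-scale
#' 128 x 128 x 96 grid at clinical SS-OCT voxel spacing.
#'
#' @param grid a [voxel_grid()].
#' @param true_pore_diameter_mean target mean pore diameter, um.
#' @param true_beam_thickness_mean target mean beam thickness, um.
#' @param pore_aspect_ratio_target target en-face pore elongation (>= 1).
#' @param lc_depth axial extent of the LC slab, um.
#' @param beam_intensity,pore_intensity noise-free intensities (arbitrary
#'   units); `beam_intensity` must exceed `pore_intensity`.
#' @param speckle_contrast coefficient of variation of multiplicative speckle,
#'   in `[0, 1)`.
#' @param shadow_fraction fraction of the en-face area under vessel shadows,
#'   in `[0, 1)`.
#' @param seed integer seed; the phantom is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = voxel_grid(c(128L, 128L, 96L)),
                         true_pore_diameter_mean = 24,
                         true_beam_thickness_mean = 49,
                         pore_aspect_ratio_target = 2,
                         lc_depth = 280,
                         beam_intensity = 180,
                         pore_intensity = 60,
                         speckle_contrast = 0.3,
                         shadow_fraction = 0.1,
                         seed = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (beam_intensity < 0 || pore_intensity < 0 || beam_intensity <= pore_intensity)
    stop("need beam_intensity > pore_intensity >= 0")
  if (pore_aspect_ratio_target < 1) stop("pore_aspect_ratio_target must be >= 1")
  if (speckle_contrast < 0 || speckle_contrast >= 1)
    stop("speckle_contrast must be in [0, 1)")
  if (shadow_fraction < 0 || shadow_fraction >= 1)
    stop("shadow_fraction must be in [0, 1)")
  if (lc_depth <= 0 || lc_depth > grid$shape[3] * grid$spacing[3])
    stop("lc_depth must be positive and fit inside the axial scan depth")
  resolvable <- 2 * max(grid$spacing)
  if (min(true_pore_diameter_mean, true_beam_thickness_mean) < resolvable)
    stop(sprintf(
      "targets unresolvable at this spacing: need >= %.3g um (2 x max voxel spacing)",
      resolvable))
  structure(list(
    grid = grid,
    true_pore_diameter_mean = true_pore_diameter_mean,
    true_beam_thickness_mean = true_beam_thickness_mean,
    pore_aspect_ratio_target = pore_aspect_ratio_target,
    lc_depth = lc_depth,
    beam_intensity = beam_intensity,
    pore_intensity = pore_intensity,
    speckle_contrast = speckle_contrast,
    shadow_fraction = shadow_fraction,
    seed = as.integer(seed)), class = "phantom_spec")
}

# --- Gaussian random field machinery ---------------------------------------

# FFT Gaussian smoothing with per-axis sigma in voxels (periodic boundaries).
smooth_field_fft <- function(noise, sigma_vox) {
  d <- dim(noise)
  H <- 1
  transfer <- function(n, s) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n] / n
    exp(-2 * pi^2 * s^2 * k^2)
  }
  h1 <- transfer(d[1], sigma_vox[1])
  h2 <- transfer(d[2], sigma_vox[2])
  h3 <- transfer(d[3], sigma_vox[3])
  Hk <- outer(outer(h1, h2), h3)
  Re(fft(fft(noise) * Hk, inverse = TRUE)) / prod(d)
}

# per-axis GRF smoothing sigmas (um -> voxels): en-face anisotropy produces
# the target pore elongation; axial sigma equals the lateral geometric mean.
grf_sigmas_vox <- function(s_um, aspect, grid) {
  a <- sqrt(aspect)
  c(s_um * a, s_um / a, s_um) / grid$spacing
}

# labels for a slab-only phase field (used by calibration and generation)
field_to_phase <- function(field, pore_quantile) {
  thr <- quantile(field, pore_quantile, names = FALSE)
  field >= thr  # TRUE = beam phase
}

.calib_cache <- new.env(parent = emptyenv())

# Calibrate (smoothing scale s, pore-phase quantile q) so that local-thickness
# morphometry of the thresholded field hits the target pore diameter and beam
# thickness. Deterministic (fixed internal seed) and cached per target set.
calibrate_microstructure <- function(spec, tol = 0.05, max_iter = 12L,
                                     calib_shape = c(96L, 96L, 64L)) {
  key <- paste(c(signif(spec$grid$spacing, 8), spec$true_pore_diameter_mean,
                 spec$true_beam_thickness_mean, spec$pore_aspect_ratio_target),
               collapse = "|")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)

  tp <- spec$true_pore_diameter_mean
  tb <- spec$true_beam_thickness_mean
  grid <- voxel_grid(calib_shape, spec$grid$spacing)
  noise <- with_seed(987001L, array(rnorm(prod(calib_shape)), calib_shape))

  s <- 0.45 * sqrt(tp * tb)       # um, initial guess for the GRF scale
  q <- tp / (tp + tb)             # initial pore volume fraction
  best <- NULL
  for (it in seq_len(max_iter)) {
    field <- smooth_field_fft(noise, grf_sigmas_vox(s, spec$pore_aspect_ratio_target, grid))
    beam <- field_to_phase(field, q)
    pd <- mean_thickness_of(!beam, grid)
    bt <- mean_thickness_of(beam, grid)
    err_p <- tp / pd
    err_b <- tb / bt
    err <- max(abs(err_p - 1), abs(err_b - 1))
    if (is.null(best) || err < best$err)
      best <- list(s = s, q = q, err = err, measured = c(pore = pd, beam = bt))
    if (err < tol) break
    s <- s * min(1.6, max(0.6, sqrt(err_p * err_b)))
    lq <- log(q / (1 - q)) + 0.8 * log(err_p / err_b)
    q <- min(0.85, max(0.15, 1 / (1 + exp(-lq))))
  }
  .calib_cache[[key]] <- best
  best
}

mean_thickness_of <- function(phase, grid) {
  t <- cpp_local_thickness(as.logical(phase), grid$shape, grid$spacing)
  mean(t[t > 0])
}

REGION_FLOOR <- 0L
REGION_SLAB  <- 1L
REGION_CAP   <- 2L

# labels and noise-free intensities from the continuous tissue model:
# a smooth field, an absolute beam/pore threshold, and a region map.
# The prelaminar cap is a uniformly bright smooth plate (its only texture in
# the scan comes from speckle), so the analyzable-region step has a
# structureless region to exclude above the LC.
render_tissue <- function(field, region, thr, spec) {
  shape <- dim(field)
  labels <- array(LABEL_OUTSIDE, shape)
  slab <- region == REGION_SLAB
  labels[slab & field >= thr] <- LABEL_BEAM
  labels[slab & field < thr] <- LABEL_PORE
  clean <- array(0.15 * spec$pore_intensity, shape)  # noise floor default
  clean[labels == LABEL_BEAM] <- spec$beam_intensity
  clean[labels == LABEL_PORE] <- spec$pore_intensity
  clean[region == REGION_CAP] <- 1.08 * spec$beam_intensity
  list(labels = labels, clean = clean)
}

# axial slice indices of the LC slab (centred in the scan depth)
slab_slices <- function(grid, lc_depth) {
  nz <- grid$shape[3]; dz <- grid$spacing[3]
  n_slab <- max(1L, round(lc_depth / dz))
  k0 <- floor((nz - n_slab) / 2) + 1L
  seq.int(k0, min(nz, k0 + n_slab - 1L))
}

#' Generate a synthetic lamina cribrosa phantom
#'
#' Builds a 3D OCT-like volume containing a connected porous beam lattice
#' (thresholded anisotropically-smoothed Gaussian random field) occupying an
#' axial slab, a smooth high-intensity prelaminar cap above, a low noise floor
#' below, optional vessel shadows and multiplicative speckle. Ground-truth
#' labels and ground-truth morphometry accompany the volume.
#'
#' @param spec a [phantom_spec()].
#' @param compute_truth_params compute the full morphometry of the truth
#'   labels (set `FALSE` to skip the extra sphere-fitting pass when only the
#'   volume and labels are needed).
#' @return An object of class `lc_phantom` with fields `volume` (speckled
#'   scan), `clean` (noise-free, shadowed volume), `truth_labels`
#'   ([lc_segmentation()]), `truth_params` ([compute_lc_params()] output or
#'   `NULL`), `shadow_mask` (en-face logical matrix), `spec`, `speckle_seed`.
#' @examples
#' ph <- generate_phantom(phantom_spec(voxel_grid(c(48L, 48L, 48L)),
#'   lc_depth = 150, shadow_fraction = 0, speckle_contrast = 0, seed = 3),
#'   compute_truth_params = FALSE)
#' table(ph$truth_labels$labels)
#' @export
generate_phantom <- function(spec, compute_truth_params = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  grid <- spec$grid
  calib <- calibrate_microstructure(spec)
  shape <- grid$shape

  noise <- with_seed(spec$seed, array(rnorm(prod(shape)), shape))
  field <- smooth_field_fft(noise, grf_sigmas_vox(calib$s, spec$pore_aspect_ratio_target, grid))

  slab <- slab_slices(grid, spec$lc_depth)
  region <- array(REGION_FLOOR, shape)
  region[, , slab] <- REGION_SLAB
  cap <- seq_len(min(slab) - 1L)
  if (length(cap)) region[, , cap] <- REGION_CAP
  thr <- quantile(field[, , slab], calib$q, names = FALSE)
  pore_quantile <- calib$q

  tissue <- render_tissue(field, region, thr, spec)
  clean_vol <- lc_volume(tissue$clean, grid)
  shadowed <- add_vessel_shadows(clean_vol, fraction = spec$shadow_fraction,
                                 seed = spec$seed + 1L)
  speckle_seed <- spec$seed + 2L
  noisy <- apply_speckle(shadowed$volume, spec$speckle_contrast, speckle_seed)

  ph <- structure(list(
    volume = noisy,
    clean = shadowed$volume,
    truth_labels = lc_segmentation(tissue$labels, grid),
    truth_params = NULL,
    shadow_mask = shadowed$shadow_mask,
    field = field,
    region = region,
    threshold = thr,
    pore_quantile = pore_quantile,
    spec = spec,
    speckle_seed = speckle_seed), class = "lc_phantom")
  if (compute_truth_params)
    ph$truth_params <- compute_lc_params(ph$truth_labels)
  ph
}

#' @method print lc_phantom
#' @export
print.lc_phantom <- function(x, ...) {
  cat("lc_phantom\n  ")
  print(x$volume$grid)
  cat(sprintf("  targets: pore %.3g um, beam %.3g um; speckle %.2g, shadows %.2g, seed %d\n",
              x$spec$true_pore_diameter_mean, x$spec$true_beam_thickness_mean,
              x$spec$speckle_contrast, x$spec$shadow_fraction, x$spec$seed))
  invisible(x)
}

#' Multiplicative speckle noise
#'
#' Applies unit-mean multiplicative gamma noise with coefficient of variation
#' `contrast` to a volume, a statistical surrogate for OCT speckle.
#'
#' @param volume an [lc_volume()].
#' @param contrast coefficient of variation of the noise, in `[0, 1)`;
#'   `0` returns the input unchanged.
#' @param seed integer seed.
#' @return A new [lc_volume()].
#' @export
apply_speckle <- function(volume, contrast, seed) {
  stopifnot(inherits(volume, "lc_volume"))
  if (contrast < 0) stop("speckle contrast must be >= 0")
  if (contrast == 0) return(volume)
  shape <- volume$grid$shape
  k <- 1 / contrast^2  # gamma shape: mean 1, CV = contrast
  mult <- with_seed(seed, array(rgamma(prod(shape), shape = k, scale = 1 / k), shape))
  lc_volume(volume$data * mult, volume$grid)
}

#' Vessel shadow simulation
#'
#' Attenuates random straight lateral bands ("vessel shadows") through the
#' full axial extent of the volume until approximately `fraction` of the
#' en-face area is covered. The returned mask records affected columns.
#'
#' @param volume an [lc_volume()].
#' @param fraction target en-face area fraction in `[0, 1)`.
#' @param seed integer seed.
#' @param attenuation multiplicative intensity factor inside shadows.
#' @return list with `volume` (shadowed [lc_volume()]) and `shadow_mask`
#'   (logical `n_fast x n_slow` matrix).
#' @export
add_vessel_shadows <- function(volume, fraction, seed, attenuation = 0.25) {
  stopifnot(inherits(volume, "lc_volume"))
  if (fraction < 0 || fraction >= 1) stop("shadow fraction must be in [0, 1)")
  nx <- volume$grid$shape[1]; ny <- volume$grid$shape[2]
  mask <- matrix(FALSE, nx, ny)
  if (fraction > 0) {
    xs <- (seq_len(nx) - 0.5) * volume$grid$spacing[1]
    ys <- (seq_len(ny) - 0.5) * volume$grid$spacing[2]
    X <- matrix(xs, nx, ny)
    Y <- matrix(ys, nx, ny, byrow = TRUE)
    ext <- c(max(xs), max(ys))
    mask <- with_seed(seed, {
      m <- matrix(FALSE, nx, ny)
      for (i in 1:200) {
        theta <- runif(1, 0, pi)
        # line through a random point, direction theta; vessels 50-120 um wide
        px <- runif(1, 0, ext[1]); py <- runif(1, 0, ext[2])
        w <- runif(1, 50, 120)
        d <- abs(-sin(theta) * (X - px) + cos(theta) * (Y - py))
        cand <- m | (d < w / 2)
        # accept a band only if it brings coverage closer to the target
        if (abs(mean(cand) - fraction) < abs(mean(m) - fraction)) m <- cand
        if (mean(m) >= fraction) break
      }
      m
    })
  }
  data <- volume$data
  if (any(mask)) {
    att <- ifelse(mask, attenuation, 1)
    data <- data * array(rep(att, volume$grid$shape[3]), volume$grid$shape)
  }
  list(volume = lc_volume(data, volume$grid), shadow_mask = mask)
}

#' Repeat-scan perturbation specification
#'
#' Describes the between-scan differences of a rescan of the same eye: a small
#' rotation about the slow scanning axis, a sub-voxel translation, a
#' refocus-like multiplicative contrast change, and fresh speckle.
#'
#' @param rotation_deg rotation about the slow scanning axis, degrees,
#'   `|rotation_deg| <= 15`.
#' @param shift_vox numeric length-3 translation in voxels (fast, slow, axial).
#' @param contrast_scale multiplicative intensity factor (> 0).
#' @param new_speckle_seed integer seed for the rescan's speckle.
#' @return An object of class `repeat_scan_spec`.
#' @export
repeat_scan_spec <- function(rotation_deg = 0, shift_vox = c(0, 0, 0),
                             contrast_scale = 1, new_speckle_seed = 1L) {
  if (abs(rotation_deg) > 15) stop("|rotation_deg| must be <= 15")
  if (contrast_scale <= 0) stop("contrast_scale must be > 0")
  stopifnot(length(shift_vox) == 3)
  structure(list(rotation_deg = rotation_deg, shift_vox = as.numeric(shift_vox),
                 contrast_scale = contrast_scale,
                 new_speckle_seed = as.integer(new_speckle_seed)),
            class = "repeat_scan_spec")
}

#' Simulate a repeat scan of a phantom
#'
#' Re-scans the same simulated tissue under the perturbation of `rs`. The
#' phantom's underlying tissue is its *continuous* model — the smooth random
#' field plus the region map — so the rescan applies the rigid transform to
#' the smooth field (tricubic interpolation, accurate on smooth data) and to
#' the region map (nearest neighbour), re-derives beam/pore labels with the
#' phantom's fixed tissue threshold, rebuilds the noise-free intensities,
#' scales the contrast, and draws fresh speckle with `rs$new_speckle_seed`.
#' Both scans are therefore statistically exchangeable samples of the same
#' tissue, exactly as two real scans of one eye are; resampling the already
#' rasterised labels instead would blur (linear) or jag (nearest-neighbour)
#' only the rescan and masquerade as measurement error. Vessel shadows keep
#' their en-face position. The grid is unchanged; tissue rotated out of the
#' volume becomes OUTSIDE.
#'
#' @param phantom an [generate_phantom()] result.
#' @param rs a [repeat_scan_spec()].
#' @param compute_truth_params recompute truth morphometry of the transformed
#'   labels (default `TRUE`).
#' @return A new `lc_phantom`.
#' @export
simulate_repeat_scan <- function(phantom, rs, compute_truth_params = TRUE) {
  stopifnot(inherits(phantom, "lc_phantom"), inherits(rs, "repeat_scan_spec"))
  grid <- phantom$volume$grid
  spec <- phantom$spec
  identity_tf <- rs$rotation_deg == 0 && all(rs$shift_vox == 0)
  if (identity_tf) {
    field <- phantom$field
    region <- phantom$region
    clean <- phantom$clean$data
    labels <- phantom$truth_labels$labels
  } else {
    field <- array(cpp_rigid_resample(phantom$field, grid$shape, grid$spacing,
                                      rs$rotation_deg, rs$shift_vox, 2L,
                                      min(phantom$field), 1L),
                   grid$shape)
    region <- array(as.integer(round(cpp_rigid_resample(
      as.numeric(phantom$region), grid$shape, grid$spacing,
      rs$rotation_deg, rs$shift_vox, 0L, REGION_FLOOR, 1L))), grid$shape)
    # interpolation slightly compresses the field's marginal distribution;
    # re-thresholding at the same slab quantile keeps the beam/pore volume
    # fractions of the two scans statistically matched
    thr2 <- quantile(field[region == REGION_SLAB], phantom$pore_quantile,
                     names = FALSE)
    tissue <- render_tissue(field, region, thr2, spec)
    labels <- tissue$labels
    att <- ifelse(phantom$shadow_mask, 0.25, 1)
    clean <- tissue$clean * array(rep(att, grid$shape[3]), grid$shape)
  }
  clean_vol <- lc_volume(clean * rs$contrast_scale, grid)
  noisy <- apply_speckle(clean_vol, spec$speckle_contrast, rs$new_speckle_seed)
  ph <- structure(list(
    volume = noisy,
    clean = clean_vol,
    truth_labels = lc_segmentation(labels, grid),
    truth_params = NULL,
    shadow_mask = phantom$shadow_mask,
    field = field,
    region = region,
    threshold = if (identity_tf) phantom$threshold else thr2,
    pore_quantile = phantom$pore_quantile,
    spec = spec,
    speckle_seed = rs$new_speckle_seed), class = "lc_phantom")
  if (compute_truth_params)
    ph$truth_params <- compute_lc_params(ph$truth_labels)
  ph
}
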