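#' Segmentation configuration
#'
#' Tunable parameters of the beam/pore segmentation, all in physical units so
#' they are independent of voxel spacing. Defaults suit LC-scale structures
#' (beams ~50 um) at SS-OCT resolution.
#'
#' @param denoise_radius median-filter ball radius, um. Radii smaller than
#'   one voxel on every axis make [denoise_volume()] a no-op.
#' @param local_window full width of the adaptive-threshold neighbourhood, um
#'   (~1.5 beam widths by default). Must exceed `denoise_radius`.
#' @param min_component smallest connected component kept by speck removal,
#'   um^3.
#' @param mask_quality_quantile conservatism of the analyzable-LC mask, in
#'   (0, 1): the position of the acceptance threshold between the robust low
#'   (5th percentile) and high (95th percentile) levels of the local signal
#'   and local contrast statistics. Larger is more conservative.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(denoise_radius = 10, local_window = 75,
                       min_component = 1000, mask_quality_quantile = 0.2) {
  if (denoise_radius < 0 || local_window <= 0 || min_component <= 0)
    stop("all segmentation parameters must be positive")
  if (mask_quality_quantile <= 0 || mask_quality_quantile >= 1)
    stop("mask_quality_quantile must be in (0, 1)")
  if (local_window <= denoise_radius)
    stop("local_window must exceed denoise_radius")
  structure(list(denoise_radius = denoise_radius, local_window = local_window,
                 min_component = min_component,
                 mask_quality_quantile = mask_quality_quantile),
            class = "seg_config")
}

#' Noise removal
#'
#' Edge-preserving 3D median filter over a physical ball of radius
#' `denoise_radius` um (an ellipsoidal voxel neighbourhood on anisotropic
#' grids). A radius below one voxel on every axis leaves the volume unchanged
#' (with a warning).
#'
#' @param volume an [lc_volume()].
#' @param cfg a [seg_config()].
#' @return The denoised [lc_volume()].
#' @export
denoise_volume <- function(volume, cfg = seg_config()) {
  stopifnot(inherits(volume, "lc_volume"), inherits(cfg, "seg_config"))
  if (all(cfg$denoise_radius < volume$grid$spacing)) {
    warning("denoise radius below one voxel on every axis; returning input unchanged")
    return(volume)
  }
  out <- cpp_median3d(volume$data, volume$grid$shape, volume$grid$spacing,
                      cfg$denoise_radius)
  lc_volume(array(out, volume$grid$shape), volume$grid)
}

# local window mean and SD via separable box sums (border-clipped windows)
local_moments <- function(data, grid, window_um) {
  r <- len_to_radius(window_um / 2, grid, min_radius = 1L)
  n <- cpp_box_sum(array(1, grid$shape), grid$shape, r)
  s1 <- cpp_box_sum(data, grid$shape, r)
  s2 <- cpp_box_sum(data^2, grid$shape, r)
  m <- s1 / n
  v <- pmax(s2 / n - m^2, 0)
  list(mean = array(m, grid$shape), sd = array(sqrt(v), grid$shape))
}

box_erode <- function(mask, shape, r) {
  n <- cpp_box_sum(array(1, shape), shape, r)
  s <- cpp_box_sum(array(as.numeric(mask), shape), shape, r)
  array(s >= n - 0.5, shape)
}

box_dilate <- function(mask, shape, r) {
  s <- cpp_box_sum(array(as.numeric(mask), shape), shape, r)
  array(s > 0.5, shape)
}

#' Determine the analyzable LC region
#'
#' Conservative mask of the scan region where LC microstructure is actually
#' visible. Vessel-shadowed columns are excluded first: an en-face column
#' whose mean intensity falls below half the median column signal is treated
#' as shadowed. LC tissue is then located by its *texture*: voxels whose
#' local signal (window mean) and local contrast (window coefficient of
#' variation, SD/mean — CV, because OCT speckle is multiplicative and the
#' bright but structureless prelaminar cap has high noise SD yet low CV)
#' both clear a threshold placed `mask_quality_quantile` of the way between
#' the robust low (5th percentile) and high (95th percentile) levels of each
#' statistic; the contrast threshold is calibrated among signal-carrying
#' voxels only, so the noise floor's huge CV over a near-zero mean cannot
#' distort it. Because the interior of a thick beam is itself low-contrast,
#' the mask is not the marked voxels directly: each column's analyzable
#' depth interval runs from its first to its last marked voxel (the
#' prelaminar cap lies above the first textured depth, the noise floor
#' below the last), and the interval's interior — including low-contrast
#' beam cores — is analyzable. Columns with fewer than 3 marked voxels are
#' dropped. The result is morphologically opened and restricted to its
#' largest 26-connected component; shadow columns are removed last so a
#' shadow band punches holes in the region instead of disconnecting it.
#'
#' @param volume a denoised [lc_volume()].
#' @param cfg a [seg_config()].
#' @return A logical 3D array (the mask).
#' @export
find_analyzable_region <- function(volume, cfg = seg_config()) {
  stopifnot(inherits(volume, "lc_volume"), inherits(cfg, "seg_config"))
  grid <- volume$grid
  v <- volume$data
  nz <- grid$shape[3]
  col_signal <- rowSums(v, dims = 2) / nz
  good_col <- col_signal >= 0.5 * stats::median(col_signal)
  w <- array(rep(as.numeric(good_col), nz), grid$shape)
  # lateral support from the analysis window; axially short (~12 um) so the
  # cap-LC and LC-floor transitions stay sharp
  r <- len_to_radius(cfg$local_window / 2, grid, min_radius = 1L)
  r[3] <- max(1L, as.integer(round(12 / grid$spacing[3])))
  n <- cpp_box_sum(w, grid$shape, r)
  s1 <- cpp_box_sum(v * w, grid$shape, r)
  s2 <- cpp_box_sum(v^2 * w, grid$shape, r)
  m <- s1 / pmax(n, 1)
  sdv <- sqrt(pmax(s2 / pmax(n, 1) - m^2, 0))
  cv <- sdv / pmax(m, .Machine$double.eps)
  q <- cfg$mask_quality_quantile
  thr_of <- function(x, sel) {
    xs <- x[sel]
    lo <- quantile(xs, 0.05, names = FALSE)
    hi <- quantile(xs, 0.95, names = FALSE)
    lo + q * (hi - lo)
  }
  sig_ok <- array(m > thr_of(m, w > 0), grid$shape) & (w > 0)
  if (!any(sig_ok)) stop("no analyzable LC: quality mask is empty")
  marked <- sig_ok & array(cv > thr_of(cv, sig_ok), grid$shape)
  if (!any(marked)) stop("no analyzable LC: quality mask is empty")
  # per-column analyzable depth interval: first to last marked voxel
  after_first <- aperm(apply(marked, c(1, 2), cummax), c(2, 3, 1)) > 0
  before_last <- aperm(apply(marked[, , nz:1, drop = FALSE], c(1, 2), cummax),
                       c(2, 3, 1))[, , nz:1, drop = FALSE] > 0
  col_ok <- rowSums(marked, dims = 2) >= 3
  mask <- after_first & before_last &
    array(rep(col_ok, nz), grid$shape)
  r1 <- c(1L, 1L, 1L)
  mask <- box_dilate(box_erode(mask, grid$shape, r1), grid$shape, r1)
  if (!any(mask)) stop("no analyzable LC: quality mask is empty")
  # connectivity is judged with shadow columns treated as connective tissue
  # (they hide LC, they do not interrupt it); the largest component is kept
  # and the shadow columns are then removed, so a shadow band punches holes
  # in the region instead of splitting it into competing islands
  bridge <- mask | array(rep(!good_col, nz), grid$shape)
  lab <- cpp_label_components(bridge, grid$shape)
  tab <- tabulate(lab[lab > 0L])
  biggest <- which.max(tab)
  mask <- mask & array(lab == biggest, grid$shape) & (w > 0)
  if (!any(mask)) stop("no analyzable LC: quality mask is empty")
  mask
}

# iterate small-component reassignment to a fixed point so cleanup is
# idempotent: specks below min_vox voxels merge into the surrounding phase.
# A small component with no in-mask opposite-phase neighbour (an isolated
# mask islet) has no surrounding phase to merge into and is left alone —
# otherwise it would oscillate between phases forever.
remove_specks <- function(beam, mask, shape, min_vox) {
  for (pass in 1:50) {
    changed <- FALSE
    for (ph in c(TRUE, FALSE)) {
      sel <- if (ph) beam & mask else (!beam) & mask
      lab <- cpp_label_components(sel, shape)
      if (max(lab) == 0L) next
      sizes <- tabulate(lab[lab > 0L])
      small <- which(sizes < min_vox)
      if (length(small)) {
        opp <- mask & !sel
        oppd <- box_dilate(opp, shape, c(1L, 1L, 1L))
        mergeable <- intersect(small, unique(lab[lab > 0L & oppd]))
        if (length(mergeable)) {
          flip <- array(lab %in% mergeable, shape)
          beam[flip] <- !ph
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  beam
}

#' Beam/pore segmentation by adaptive local thresholding
#'
#' Within the analyzable mask, voxels are first labelled BEAM when their
#' (denoised) intensity exceeds the mean intensity of their local
#' neighbourhood (window mean over mask voxels only, zero offset). Because
#' beams occupy more volume than pores, this plain local mean sits above the
#' midpoint between the two phase intensities and biases boundary voxels
#' toward PORE; the threshold is therefore refined by local isodata
#' (Ridler-Calvard) iterations — the threshold at each voxel becomes the
#' midpoint of the window means of the two current classes — until the
#' labelling is stable. Connected components of either phase smaller than
#' `min_component` um^3 (26-connectivity) are then merged into the
#' surrounding phase, iterated to a fixed point. All thresholds are relative
#' to local averages, so the segmentation is invariant to global intensity
#' rescaling.
#'
#' @param volume a denoised [lc_volume()].
#' @param mask logical array from [find_analyzable_region()].
#' @param cfg a [seg_config()].
#' @return An [lc_segmentation()].
#' @export
segment_volume <- function(volume, mask, cfg = seg_config()) {
  stopifnot(inherits(volume, "lc_volume"), inherits(cfg, "seg_config"))
  grid <- volume$grid
  if (!any(mask)) stop("mask is empty")
  r <- len_to_radius(cfg$local_window / 2, grid, min_radius = 1L)
  v <- volume$data
  m_num <- cpp_box_sum(v * mask, grid$shape, r)
  m_den <- cpp_box_sum(array(as.numeric(mask), grid$shape), grid$shape, r)
  local_mean <- m_num / pmax(m_den, 1)
  beam <- array(v > local_mean, grid$shape) & mask
  for (it in 1:10) {  # local isodata refinement to a stable labelling
    nb <- cpp_box_sum(v * beam, grid$shape, r)
    db <- cpp_box_sum(array(as.numeric(beam), grid$shape), grid$shape, r)
    pore <- mask & !beam
    np <- cpp_box_sum(v * pore, grid$shape, r)
    dp <- cpp_box_sum(array(as.numeric(pore), grid$shape), grid$shape, r)
    ok <- db > 0 & dp > 0
    thr <- local_mean
    thr[ok] <- 0.5 * (nb[ok] / db[ok] + np[ok] / dp[ok])
    beam_new <- array(v > thr, grid$shape) & mask
    if (identical(beam_new, beam)) break
    beam <- beam_new
  }
  min_vox <- max(1, ceiling(cfg$min_component / prod(grid$spacing)))
  beam <- remove_specks(beam, mask, grid$shape, min_vox)
  labels <- array(LABEL_OUTSIDE, grid$shape)
  labels[mask] <- LABEL_PORE
  labels[beam] <- LABEL_BEAM
  lc_segmentation(labels, grid)
}
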