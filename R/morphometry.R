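#' Local thickness transform (maximal inscribed sphere)
#'
#' For every voxel of the chosen phase, the local thickness is the diameter of
#' the largest sphere that contains the voxel and fits entirely inside the
#' phase. Spheres are physical spheres in micrometres: the underlying distance
#' transform uses the per-axis voxel spacing, so anisotropic grids are handled
#' correctly. OUTSIDE voxels (and everything beyond the array) count as
#' background, so spheres cannot cross the analyzable-mask boundary; this
#' deliberately biases thickness low at the mask edge.
#'
#' @param seg an [lc_segmentation()].
#' @param phase `"beam"` or `"pore"`.
#' @return An object of class `lc_thickness_map` with fields `values` (3D um
#'   array, 0 off-phase), `grid`, `phase`.
#' @export
local_thickness <- function(seg, phase = c("beam", "pore")) {
  stopifnot(inherits(seg, "lc_segmentation"))
  phase <- match.arg(phase)
  code <- if (phase == "beam") LABEL_BEAM else LABEL_PORE
  sel <- seg$labels == code
  if (!any(sel)) {
    warning(sprintf("empty %s phase: thickness map is all zero", phase))
    values <- array(0, seg$grid$shape)
  } else {
    values <- array(cpp_local_thickness(sel, seg$grid$shape, seg$grid$spacing),
                    seg$grid$shape)
  }
  structure(list(values = values, grid = seg$grid, phase = phase),
            class = "lc_thickness_map")
}

#' @method print lc_thickness_map
#' @export
print.lc_thickness_map <- function(x, ...) {
  v <- x$values[x$values > 0]
  if (length(v))
    cat(sprintf("lc_thickness_map (%s): mean %.2f um, sd %.2f um, max %.2f um over %d voxels\n",
                x$phase, mean(v), sd(v), max(v), length(v)))
  else cat(sprintf("lc_thickness_map (%s): empty phase\n", x$phase))
  invisible(x)
}

#' Voxel-weighted thickness statistics
#'
#' Mean and population SD of a thickness map over the voxels of its phase
#' (every voxel contributes equally, following the convention of averaging
#' all pore diameters / beam thicknesses).
#'
#' @param tmap an [local_thickness()] result.
#' @return Named numeric vector `c(mean = , sd = )` in um.
#' @export
thickness_stats <- function(tmap) {
  stopifnot(inherits(tmap, "lc_thickness_map"))
  v <- tmap$values[tmap$values > 0]
  if (!length(v)) stop("thickness map has no positive voxels")
  m <- mean(v)
  c(mean = m, sd = sqrt(mean((v - m)^2)))
}

#' Per-C-mode-slice pore morphometry
#'
#' Finds 8-connected pore components on every C-mode (en-face) slice,
#' excludes components that touch the analyzable-mask boundary (adjacent to
#' OUTSIDE or the image edge) and components smaller than 4 pixels, and
#' measures each remaining pore: area (pixel count x dx x dy) and the major /
#' minor axes of the moment-equivalent ellipse of its pixel set (second
#' central moments in physical coordinates, including the per-pixel moment of
#' a dx x dy rectangle).
#'
#' @param seg an [lc_segmentation()].
#' @return A data frame with one row per pore: `slice_index`, `n_pixels`,
#'   `area` (um^2), `major_axis`, `minor_axis` (um), `aspect_ratio`,
#'   `centroid_x`, `centroid_y` (um).
#' @export
slice_pores <- function(seg) {
  stopifnot(inherits(seg, "lc_segmentation"))
  grid <- seg$grid
  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  dx <- grid$spacing[1]; dy <- grid$spacing[2]
  rows <- vector("list", nz)
  for (k in seq_len(nz)) {
    sl <- seg$labels[, , k]
    if (!any(sl == LABEL_PORE)) next
    lab <- cpp_label_components(sl == LABEL_PORE, c(nx, ny, 1L))
    dim(lab) <- c(nx, ny)
    nlab <- max(lab)
    if (nlab == 0L) next
    # a component touches the boundary when one of its pixels is 4-adjacent
    # to an OUTSIDE pixel or lies on the image edge
    outside <- sl == LABEL_OUTSIDE
    edge_adj <- matrix(FALSE, nx, ny)
    edge_adj[1, ] <- edge_adj[nx, ] <- TRUE
    edge_adj[, 1] <- edge_adj[, ny] <- TRUE
    edge_adj[-nx, ] <- edge_adj[-nx, ] | outside[-1, ]
    edge_adj[-1, ]  <- edge_adj[-1, ]  | outside[-nx, ]
    edge_adj[, -ny] <- edge_adj[, -ny] | outside[, -1]
    edge_adj[, -1]  <- edge_adj[, -1]  | outside[, -ny]
    bad <- unique(lab[lab > 0L & edge_adj])
    idx <- which(lab > 0L)
    comp <- lab[idx]
    keep <- !(comp %in% bad)
    if (!any(keep)) next
    idx <- idx[keep]; comp <- comp[keep]
    ci <- ((idx - 1L) %% nx) + 1L
    cj <- ((idx - 1L) %/% nx) + 1L
    px <- (ci - 0.5) * dx
    py <- (cj - 0.5) * dy
    n_pix <- tabulate(comp, nbins = nlab)
    sx <- rowsum(px, comp); sy <- rowsum(py, comp)
    sxx <- rowsum(px^2, comp); syy <- rowsum(py^2, comp)
    sxy <- rowsum(px * py, comp)
    ids <- as.integer(rownames(sx))
    n <- n_pix[ids]
    ok <- n >= 4L
    if (!any(ok)) next
    mx <- sx[ok] / n[ok]; my <- sy[ok] / n[ok]
    # central second moments + uniform-rectangle pixel moment
    mxx <- sxx[ok] / n[ok] - mx^2 + dx^2 / 12
    myy <- syy[ok] / n[ok] - my^2 + dy^2 / 12
    mxy <- sxy[ok] / n[ok] - mx * my
    tr <- mxx + myy
    det_root <- sqrt(pmax((mxx - myy)^2 / 4 + mxy^2, 0))
    l1 <- tr / 2 + det_root
    l2 <- pmax(tr / 2 - det_root, 0)
    rows[[k]] <- data.frame(
      slice_index = k,
      n_pixels = n[ok],
      area = n[ok] * dx * dy,
      major_axis = 4 * sqrt(l1),
      minor_axis = 4 * sqrt(l2),
      aspect_ratio = sqrt(l1) / pmax(sqrt(l2), .Machine$double.eps),
      centroid_x = mx,
      centroid_y = my)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(slice_index = integer(), n_pixels = integer(),
                      area = numeric(), major_axis = numeric(),
                      minor_axis = numeric(), aspect_ratio = numeric(),
                      centroid_x = numeric(), centroid_y = numeric())
  rownames(out) <- NULL
  out
}

#' Lamina cribrosa microarchitecture parameters
#'
#' Computes the seven standard LC microarchitecture parameters from a
#' segmentation: voxel-weighted mean and SD of pore diameter and beam
#' thickness (maximal-inscribed-sphere local thickness), their ratio, and the
#' per-C-mode-slice pore area and aspect ratio, plus pore-count summaries by
#' depth half. Pore counts depend on the analyzed region of each individual
#' scan, so they are reported for inspection but are not fed into
#' repeatability statistics by default.
#'
#' @param seg an [lc_segmentation()] containing both phases.
#' @param per_slice_pore_area if `TRUE`, average pore area within each slice
#'   first and then across slices; the default pools all pores.
#' @return An object of class `lc_params` (see Details), convertible with
#'   `as.data.frame()`.
#' @details Fields: `pore_diameter_mean`, `pore_diameter_sd`,
#'   `beam_thickness_mean`, `beam_thickness_sd`, `beam_pore_ratio`
#'   (= beam mean / pore mean, exactly), `pore_area_mean`,
#'   `pore_aspect_ratio_mean`, `n_slices_with_pores`, `pore_count_top_half`,
#'   `pore_count_bottom_half`. The top/bottom split is at the axial midpoint
#'   of the mask's occupied slice range; a pore on the midpoint slice counts
#'   as top.
#' @export
compute_lc_params <- function(seg, per_slice_pore_area = FALSE) {
  stopifnot(inherits(seg, "lc_segmentation"))
  if (!any(seg$labels == LABEL_PORE)) stop("empty pore phase")
  if (!any(seg$labels == LABEL_BEAM)) stop("empty beam phase")
  ps <- thickness_stats(local_thickness(seg, "pore"))
  bs <- thickness_stats(local_thickness(seg, "beam"))
  pores <- slice_pores(seg)
  if (nrow(pores)) {
    if (per_slice_pore_area) {
      by_slice <- tapply(pores$area, pores$slice_index, mean)
      pore_area_mean <- mean(by_slice)
    } else pore_area_mean <- mean(pores$area)
    aspect_mean <- mean(pores$aspect_ratio)
    n_slices <- length(unique(pores$slice_index))
  } else {
    pore_area_mean <- NA_real_; aspect_mean <- NA_real_; n_slices <- 0L
  }
  occ <- which(apply(seg$labels != LABEL_OUTSIDE, 3, any))
  mid <- floor((min(occ) + max(occ)) / 2)
  structure(list(
    pore_diameter_mean = unname(ps["mean"]),
    pore_diameter_sd = unname(ps["sd"]),
    beam_thickness_mean = unname(bs["mean"]),
    beam_thickness_sd = unname(bs["sd"]),
    beam_pore_ratio = unname(bs["mean"]) / unname(ps["mean"]),
    pore_area_mean = pore_area_mean,
    pore_aspect_ratio_mean = aspect_mean,
    n_slices_with_pores = as.integer(n_slices),
    pore_count_top_half = sum(pores$slice_index <= mid),
    pore_count_bottom_half = sum(pores$slice_index > mid)),
    class = "lc_params")
}

#' @method as.data.frame lc_params
#' @export
as.data.frame.lc_params <- function(x, ...) {
  data.frame(lapply(unclass(x), function(v) v), stringsAsFactors = FALSE)
}

#' @method print lc_params
#' @export
print.lc_params <- function(x, ...) {
  cat("LC microarchitecture parameters\n")
  cat(sprintf("  pore diameter     %.2f (SD %.2f) um\n",
              x$pore_diameter_mean, x$pore_diameter_sd))
  cat(sprintf("  beam thickness    %.2f (SD %.2f) um\n",
              x$beam_thickness_mean, x$beam_thickness_sd))
  cat(sprintf("  beam/pore ratio   %.3f\n", x$beam_pore_ratio))
  cat(sprintf("  pore area         %.1f um^2, aspect ratio %.2f\n",
              x$pore_area_mean, x$pore_aspect_ratio_mean))
  cat(sprintf("  slices with pores %d; pores top/bottom half %d/%d\n",
              x$n_slices_with_pores, x$pore_count_top_half,
              x$pore_count_bottom_half))
  invisible(x)
}

# canonical parameter names used in repeated-measurement tables and reports
lc_parameter_names <- function() {
  c("pore_diameter_mean", "pore_diameter_sd", "beam_thickness_mean",
    "beam_thickness_sd", "beam_pore_ratio", "pore_area_mean",
    "pore_aspect_ratio_mean")
}
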