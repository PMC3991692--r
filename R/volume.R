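#' Voxel grid geometry
#'
#' Describes the raster geometry of a scan volume: voxel counts along the
#' (fast lateral, slow lateral, axial) axes and the physical voxel spacing in
#' micrometres. The default matches a swept-source OCT optic-nerve-head cube
#' of 3.5 x 3.5 x 3.64 mm sampled at 400 x 400 x 896 voxels, i.e. 8.75 um
#' lateral and 4.0625 um axial spacing.
#'
#' @param shape integer vector of length 3: voxel counts (fast, slow, axial).
#' @param spacing numeric vector of length 3: voxel spacing in um per voxel.
#' @return An object of class `voxel_grid`.
#' @examples
#' voxel_grid(c(128, 128, 96))
#' @export
voxel_grid <- function(shape = c(400L, 400L, 896L),
                       spacing = c(8.75, 8.75, 4.0625)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3, length(spacing) == 3)
  if (any(shape < 1L)) stop("voxel counts must all be >= 1")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("voxel spacings must all be > 0")
  structure(list(shape = shape, spacing = spacing), class = "voxel_grid")
}

#' @method print voxel_grid
#' @export
print.voxel_grid <- function(x, ...) {
  ext <- x$shape * x$spacing / 1000
  cat(sprintf("voxel_grid: %d x %d x %d voxels @ (%.4g, %.4g, %.4g) um = %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              ext[1], ext[2], ext[3]))
  invisible(x)
}

grid_equal <- function(a, b) {
  identical(a$shape, b$shape) && isTRUE(all.equal(a$spacing, b$spacing))
}

#' Scan volume container
#'
#' A 3D non-negative scalar intensity grid together with its [voxel_grid()]
#' geometry. Array index order is (fast, slow, axial); C-mode slices are
#' `data[, , k]` planes.
#'
#' @param data numeric 3D array of intensities, finite and >= 0.
#' @param grid a [voxel_grid()] whose shape matches `dim(data)`.
#' @return An object of class `lc_volume` with fields `data` and `grid`.
#' @export
lc_volume <- function(data, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  data <- as.array(data)
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("volume data shape does not match grid shape")
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0))
    stop("volume intensities must be finite and >= 0")
  structure(list(data = data, grid = grid), class = "lc_volume")
}

#' @method print lc_volume
#' @export
print.lc_volume <- function(x, ...) {
  cat("lc_volume\n  ")
  print(x$grid)
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Beam/pore segmentation container
#'
#' Voxel labels over \{OUTSIDE = 0, PORE = 1, BEAM = 2\}. BEAM and PORE voxels
#' together form the analyzable-LC mask; everything else is OUTSIDE.
#'
#' @param labels integer 3D array with values in \{0, 1, 2\}.
#' @param grid the matching [voxel_grid()].
#' @return An object of class `lc_segmentation`.
#' @export
lc_segmentation <- function(labels, grid) {
  stopifnot(inherits(grid, "voxel_grid"))
  labels <- as.array(labels)
  storage.mode(labels) <- "integer"
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label shape does not match grid shape")
  if (!all(labels %in% c(LABEL_OUTSIDE, LABEL_PORE, LABEL_BEAM)))
    stop("labels must be in {0 = OUTSIDE, 1 = PORE, 2 = BEAM}")
  structure(list(labels = labels, grid = grid), class = "lc_segmentation")
}

#' @method print lc_segmentation
#' @export
print.lc_segmentation <- function(x, ...) {
  n <- length(x$labels)
  cat(sprintf("lc_segmentation: %.1f%% beam, %.1f%% pore, %.1f%% outside\n",
              100 * sum(x$labels == LABEL_BEAM) / n,
              100 * sum(x$labels == LABEL_PORE) / n,
              100 * sum(x$labels == LABEL_OUTSIDE) / n))
  invisible(x)
}

# physical length (um) -> per-axis voxel radii, never below 0
len_to_radius <- function(len_um, grid, min_radius = 0L) {
  pmax(as.integer(round(len_um / grid$spacing)), min_radius)
}
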