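#' Write a volume as a multi-page TIFF stack with a JSON sidecar
#'
#' One TIFF page per C-mode slice (page index = axial index). Intensities are
#' stored as 32-bit floats normalised to `[0, 1]`; the normalisation scale and
#' the voxel spacing travel in a JSON sidecar next to the stack.
#'
#' @param volume an [lc_volume()].
#' @param dir output directory (created if needed).
#' @param name base file name (`<name>.tif`, `<name>.json`).
#' @param extra named list merged into the sidecar (e.g. seed, spec).
#' @return Invisibly, the TIFF path.
#' @export
write_volume <- function(volume, dir, name = "volume", extra = list()) {
  stopifnot(inherits(volume, "lc_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(volume$data, 1e-12)
  pages <- lapply(seq_len(volume$grid$shape[3]),
                  function(k) volume$data[, , k] / scale)
  tif <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L)
  sidecar <- c(list(shape = volume$grid$shape,
                    spacing_um = volume$grid$spacing,
                    intensity_scale = scale,
                    kind = "volume"), extra)
  jsonlite::write_json(sidecar, file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(tif)
}

#' Read a volume written by [write_volume()]
#'
#' @param dir directory containing the stack.
#' @param name base file name.
#' @return An [lc_volume()].
#' @export
read_volume <- function(dir, name = "volume") {
  tif <- file.path(dir, paste0(name, ".tif"))
  sc <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(tif)) stop("no TIFF stack at ", tif)
  if (!file.exists(sc))
    stop("missing sidecar ", sc,
         ": voxel spacing unknown; supply a JSON sidecar with spacing_um")
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif, all = TRUE)
  shape <- as.integer(meta$shape)
  data <- array(0, shape)
  for (k in seq_along(pages)) data[, , k] <- pages[[k]]
  data <- data * meta$intensity_scale
  data[data < 0] <- 0  # guard against float round-off
  lc_volume(data, voxel_grid(shape, as.numeric(meta$spacing_um)))
}

#' Write a segmentation as an 8-bit labelled TIFF stack
#'
#' Labels 0 = OUTSIDE, 1 = PORE, 2 = BEAM, stored one C-mode slice per page.
#'
#' @param seg an [lc_segmentation()].
#' @param dir output directory.
#' @param name base file name.
#' @return Invisibly, the TIFF path.
#' @export
write_segmentation <- function(seg, dir, name = "segmentation") {
  stopifnot(inherits(seg, "lc_segmentation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(seq_len(seg$grid$shape[3]),
                  function(k) seg$labels[, , k] / 255)
  tif <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 8L)
  jsonlite::write_json(list(shape = seg$grid$shape,
                            spacing_um = seg$grid$spacing,
                            labels = list(OUTSIDE = 0, PORE = 1, BEAM = 2),
                            kind = "segmentation"),
                       file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(tif)
}

#' Read a segmentation written by [write_segmentation()]
#'
#' @param dir directory containing the stack.
#' @param name base file name.
#' @return An [lc_segmentation()].
#' @export
read_segmentation <- function(dir, name = "segmentation") {
  tif <- file.path(dir, paste0(name, ".tif"))
  sc <- file.path(dir, paste0(name, ".json"))
  if (!file.exists(sc)) stop("missing sidecar ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(tif, all = TRUE)
  shape <- as.integer(meta$shape)
  labels <- array(0L, shape)
  for (k in seq_along(pages)) labels[, , k] <- as.integer(round(pages[[k]] * 255))
  lc_segmentation(labels, voxel_grid(shape, as.numeric(meta$spacing_um)))
}

#' Write a thickness map as a 32-bit float TIFF stack
#'
#' @param tmap an [local_thickness()] result.
#' @param dir output directory.
#' @param name base file name.
#' @return Invisibly, the TIFF path.
#' @export
write_thickness_map <- function(tmap, dir, name = paste0("thickness_", tmap$phase)) {
  stopifnot(inherits(tmap, "lc_thickness_map"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- max(tmap$values, 1e-12)
  pages <- lapply(seq_len(tmap$grid$shape[3]),
                  function(k) tmap$values[, , k] / scale)
  tif <- file.path(dir, paste0(name, ".tif"))
  tiff::writeTIFF(pages, tif, bits.per.sample = 32L)
  jsonlite::write_json(list(shape = tmap$grid$shape,
                            spacing_um = tmap$grid$spacing,
                            value_scale_um = scale, phase = tmap$phase,
                            kind = "thickness"),
                       file.path(dir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(tif)
}

#' Write LC parameters (one row per scan) as CSV
#'
#' @param params an `lc_params` object or a list of them.
#' @param path output CSV path.
#' @param ids optional character vector of scan identifiers.
#' @return Invisibly, the path.
#' @export
write_params_csv <- function(params, path, ids = NULL) {
  if (inherits(params, "lc_params")) params <- list(params)
  df <- do.call(rbind, lapply(params, as.data.frame))
  if (!is.null(ids)) df <- cbind(scan_id = ids, df)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
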