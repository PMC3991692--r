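#' Pipeline configuration
#'
#' A single serialisable configuration object for the end-to-end pipeline:
#' phantom generation defaults, segmentation parameters, repeat-scan
#' perturbation defaults, and statistics settings. Unknown keys are rejected
#' so typos fail loudly.
#'
#' @param phantom named list overriding [phantom_spec()] arguments
#'   (`grid_shape` and `grid_spacing` replace the `grid` argument).
#' @param seg named list overriding [seg_config()] arguments.
#' @param repeat_scan named list overriding [repeat_scan_spec()] arguments
#'   (except `new_speckle_seed`, which the experiment driver assigns).
#' @param stats named list: `n_eyes`, `n_two_eyed`, `bootstrap_draws`.
#' @param seed master seed for experiment drivers.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = list(), seg = list(),
                            repeat_scan = list(), stats = list(), seed = 1L) {
  defaults <- list(
    phantom = list(
      grid_shape = c(128L, 128L, 96L),
      grid_spacing = c(8.75, 8.75, 4.0625),
      true_pore_diameter_mean = 24,
      true_beam_thickness_mean = 49,
      pore_aspect_ratio_target = 2,
      lc_depth = 280,
      beam_intensity = 180,
      pore_intensity = 60,
      speckle_contrast = 0.3,
      shadow_fraction = 0.1),
    seg = list(denoise_radius = 10, local_window = 75,
               min_component = 1000, mask_quality_quantile = 0.2),
    repeat_scan = list(rotation_deg = 1, shift_vox = c(0.5, 0.5, 0.5),
                       contrast_scale = 1.1),
    stats = list(n_eyes = 12L, n_two_eyed = 4L, bootstrap_draws = 1000L),
    seed = 1L)
  user <- list(phantom = phantom, seg = seg, repeat_scan = repeat_scan,
               stats = stats, seed = seed)
  for (section in c("phantom", "seg", "repeat_scan", "stats")) {
    unknown <- setdiff(names(user[[section]]), names(defaults[[section]]))
    if (length(unknown))
      stop("unknown ", section, " config keys: ", paste(unknown, collapse = ", "))
    defaults[[section]] <- modifyList(defaults[[section]], user[[section]])
  }
  defaults$seed <- as.integer(seed)
  structure(defaults, class = "pipeline_config")
}

#' Serialise / parse a pipeline configuration
#'
#' `config_to_json()` writes a single JSON document; `config_from_json()`
#' parses one back into an identical [pipeline_config()] (unknown keys are
#' rejected).
#'
#' @param config a [pipeline_config()].
#' @param path file path; for `config_to_json` use `NULL` to return the JSON
#'   string instead of writing.
#' @return `config_to_json`: the path or JSON string; `config_from_json`: a
#'   [pipeline_config()].
#' @export
config_to_json <- function(config, path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  js <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  path
}

#' @rdname config_to_json
#' @param json a JSON string (used when `path` is `NULL`).
#' @export
config_from_json <- function(path = NULL, json = NULL) {
  x <- if (!is.null(path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else jsonlite::fromJSON(json, simplifyVector = TRUE)
  top_unknown <- setdiff(names(x), c("phantom", "seg", "repeat_scan", "stats", "seed"))
  if (length(top_unknown))
    stop("unknown config keys: ", paste(top_unknown, collapse = ", "))
  # JSON has one number type; restore the configuration's native types
  numify <- function(l) lapply(l, function(v) if (is.numeric(v)) as.numeric(v) else v)
  ph <- numify(as.list(x$phantom))
  if (!is.null(ph$grid_shape)) ph$grid_shape <- as.integer(ph$grid_shape)
  st <- lapply(as.list(x$stats), function(v) if (is.numeric(v)) as.integer(v) else v)
  pipeline_config(phantom = ph, seg = numify(as.list(x$seg)),
                  repeat_scan = numify(as.list(x$repeat_scan)), stats = st,
                  seed = as.integer(x$seed))
}

config_phantom_spec <- function(config, seed) {
  p <- config$phantom
  phantom_spec(grid = voxel_grid(p$grid_shape, p$grid_spacing),
               true_pore_diameter_mean = p$true_pore_diameter_mean,
               true_beam_thickness_mean = p$true_beam_thickness_mean,
               pore_aspect_ratio_target = p$pore_aspect_ratio_target,
               lc_depth = p$lc_depth,
               beam_intensity = p$beam_intensity,
               pore_intensity = p$pore_intensity,
               speckle_contrast = p$speckle_contrast,
               shadow_fraction = p$shadow_fraction,
               seed = seed)
}

config_seg <- function(config) do.call(seg_config, config$seg)

# deterministic seed fan-out: a counter scheme so adding eyes or replicates
# never perturbs the sub-seeds of earlier ones (kept below 2^31)
fanout_seed <- function(master, eye, rep = 0L) {
  as.integer((as.numeric(master) %% 65536) * 32749 + eye * 131 + rep) %% 2147483647L
}

#' Measure one scan volume end to end
#'
#' Reads a TIFF stack + sidecar (or takes an [lc_volume()] directly), then
#' runs denoise -> analyzable-region mask -> local-threshold segmentation ->
#' morphometry. Optionally writes the segmentation, thickness maps, parameter
#' CSV and a small JSON log.
#'
#' @param volume an [lc_volume()], or a directory containing `volume.tif` +
#'   `volume.json` written by [write_volume()].
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory for segmentation, thickness maps,
#'   `params.csv` and `log.json`.
#' @return The scan's [compute_lc_params()] result.
#' @export
run_single_scan <- function(volume, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(volume)) volume <- read_volume(volume)
  stopifnot(inherits(volume, "lc_volume"))
  cfg <- config_seg(config)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    attr(out, "elapsed_s") <- proc.time()[["elapsed"]] - t0
    out
  }
  den <- stage("denoise", denoise_volume(volume, cfg))
  mask <- stage("analyzable_region", find_analyzable_region(den, cfg))
  seg <- stage("segment", segment_volume(den, mask, cfg))
  params <- stage("morphometry", compute_lc_params(seg))
  if (!is.null(out_dir)) {
    write_segmentation(seg, out_dir)
    write_thickness_map(local_thickness(seg, "beam"), out_dir)
    write_thickness_map(local_thickness(seg, "pore"), out_dir)
    write_params_csv(params, file.path(out_dir, "params.csv"))
    log <- list(config_hash = config_hash(config),
                seg_config = unclass(cfg),
                timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  params
}

config_hash <- function(config) {
  js <- config_to_json(config)
  # small stable polynomial hash of the serialised config (logging only)
  h <- 0
  for (b in utf8ToInt(js)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' In-silico scan-rescan reproducibility experiment
#'
#' The computational analogue of a clinical repeatability study: `n_eyes`
#' phantom eyes are each "scanned" twice — the second scan differs by the
#' configured rigid perturbation, contrast change and fresh speckle — the
#' full pipeline measures every scan, and the nested measurement-error model
#' estimates each parameter's imprecision SD and relative imprecision.
#' A share of eyes is paired into two-eyed subjects so the model's
#' eye-within-subject level is exercised. Deterministic under the master
#' seed; sub-seeds fan out per eye and replicate via a counter scheme.
#'
#' @param config a [pipeline_config()] (`config$stats$n_eyes`,
#'   `config$stats$n_two_eyed`, `config$repeat_scan`, `config$seed`).
#' @param progress print per-eye progress.
#' @return List with `report` (data frame: parameter, mean_value,
#'   imprecision_sd, relative_imprecision_pct, n_eyes, n_subjects),
#'   `table` (the long repeated-measurements table) and `estimates`
#'   (list of `lc_imprecision`).
#' @export
run_repro_experiment <- function(config = pipeline_config(), progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  n_eyes <- config$stats$n_eyes
  n_two <- config$stats$n_two_eyed
  stopifnot(2 * n_two <= n_eyes)
  rows <- list()
  for (e in seq_len(n_eyes)) {
    if (progress) message("eye ", e, "/", n_eyes)
    seed_e <- fanout_seed(config$seed, e, 0L)
    ph <- generate_phantom(config_phantom_spec(config, seed_e),
                           compute_truth_params = FALSE)
    rp <- config$repeat_scan
    identity_perturbation <- rp$rotation_deg == 0 && all(rp$shift_vox == 0) &&
      rp$contrast_scale == 1
    rs <- repeat_scan_spec(
      rotation_deg = rp$rotation_deg,
      shift_vox = rp$shift_vox,
      contrast_scale = rp$contrast_scale,
      # an identity perturbation means "nothing changed between scans",
      # including the speckle realisation: the rescan is bit-identical
      new_speckle_seed = if (identity_perturbation) ph$speckle_seed
                         else fanout_seed(config$seed, e, 2L))
    ph2 <- simulate_repeat_scan(ph, rs, compute_truth_params = FALSE)
    p1 <- run_single_scan(ph$volume, config)
    p2 <- run_single_scan(ph2$volume, config)
    # eyes 1..2*n_two pair into two-eyed subjects; the rest are single
    subject <- if (e <= 2 * n_two) sprintf("S%03d", ceiling(e / 2))
               else sprintf("S%03d", n_two + (e - 2 * n_two))
    eye_lab <- if (e <= 2 * n_two && e %% 2 == 0) "OS" else "OD"
    for (pn in lc_parameter_names()) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subject, eye_id = eye_lab, group = "simulated",
        replicate = 1:2, parameter = pn,
        value = c(unclass(p1)[[pn]], unclass(p2)[[pn]]))
    }
  }
  table <- do.call(rbind, rows)
  ests <- lapply(lc_parameter_names(), function(pn)
    fit_measurement_error_model(table, pn))
  names(ests) <- lc_parameter_names()
  report <- do.call(rbind, lapply(ests, function(est) data.frame(
    parameter = est$parameter,
    mean_value = est$mean_value,
    imprecision_sd = est$imprecision_sd,
    relative_imprecision_pct = est$relative_imprecision,
    n_eyes = est$n_eyes,
    n_subjects = est$n_subjects)))
  rownames(report) <- NULL
  list(report = report, table = table, estimates = ests)
}
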