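## Pipeline configuration: one flat key-value list holding every tunable
## threshold and geometry default, with validation, file round-trip (YAML)
## and a content hash echoed into output artifacts.

#' Default pipeline configuration
#'
#' Acquisition values follow the screening protocol the package models
#' (30 z-slices at dZ = 4 um, 700 um autofocus search, bright-field at 60%
#' LED / 10 ms, GFP470 at 100% LED / 20 ms, 2048x2048 camera); analysis
#' thresholds carry the published heuristics (blur variance < 400, blank
#' Laplacian variance > 124, ellipse major axis > 299 px, Feret >= 70 px,
#' particle number < 11).  The absolute QC variance thresholds transfer only
#' to data with matching bit depth and gain; [calibrate_qc()] re-derives
#' them from labelled images.
#'
#' @return named list of class `ks_config`.
#' @export
default_config <- function() {
  structure(list(
    ## acquisition geometry
    prescan_camera_px   = 2048L,   # overview frame edge, pixels
    rescan_camera_px    = 2048L,   # high-resolution frame edge, pixels
    pixel_size_4x_um    = 1.625,   # lateral calibration at 4x (6.5 um pitch)
    pixel_size_10x_um   = 0.65,    # lateral calibration at 10x
    n_z                 = 30L,     # rescan z-slices
    dz_um               = 4,       # z spacing, um
    autofocus_range_um  = 700,     # software autofocus search volume, um
    bf_led_percent      = 60,
    bf_exposure_ms      = 10,
    gfp_led_percent     = 100,
    gfp_exposure_ms     = 20,
    rescan_channels     = "BF,GFP470",
    ## smart acquisition
    detect_method       = "li",    # overview auto-threshold method
    detect_min_area_px  = 50L,     # below this foreground area: blank signal
    detect_min_contrast = 5,       # min foreground/background mean ratio
    detect_weighting    = "intensity", # or "binary" centroid
    stage_flip_x        = 1,       # stage axis orientation signs
    stage_flip_y        = 1,
    ## preprocessing
    substack_size       = 7L,
    crop_px             = 512L,
    recrop_factor       = 1.6,
    denoise_method      = "median", # "median" or "none"
    focus_metric        = "laplacian", # or "variance"
    ## quality control
    blur_threshold      = 400,
    blank_threshold     = 124,
    blank_above         = TRUE,    # blank when Laplacian variance ABOVE threshold
    background_radius   = 50L,     # rolling-ball disc radius, px
    qc_calibrate        = TRUE,    # pipeline: re-derive QC thresholds from a
    qc_calibration_n    = 20L,     # labelled synthetic set of this size/class
    ## phenotype classification
    phenotype_blur_sigma = 2,      # Gaussian sigma before Li masking, px
    profile_min_run     = 3L,      # minimum zero-run length, columns
    profile_epsilon     = 2,       # counts at/below which a profile value is "zero"
    roi_margin          = 0.15,    # ROI bounding-box expansion per side
    axis_threshold_px   = 299,     # ellipse major axis: wildtype if greater
    connectivity        = 8L,
    ## quantification
    feret_min_px        = 70,
    particle_index_max  = 10L,
    particle_order      = "area",  # cystic particle numbering: "area" or "raster"
    min_particle_area_px2 = 50,
    central_band        = 0.8,     # pronephric particles: centroid within middle band
    circularity_min     = 0,
    circularity_max     = 1,
    include_ambiguous   = FALSE,
    ## synthetic scenes
    seed                = 1L
  ), class = "ks_config")
}

#' Validate and merge configuration overrides
#'
#' Unknown keys are rejected (listed exhaustively); values are checked for
#' basic sanity.
#'
#' @param overrides named list (possibly empty) of keys to replace.
#' @param base configuration to start from (default [default_config()]).
#' @return validated `ks_config`.
#' @export
build_config <- function(overrides = list(), base = default_config()) {
  stopifnot(is.list(overrides))
  if (length(overrides) > 0L) {
    bad <- setdiff(names(overrides), names(base))
    if (length(bad) > 0L) {
      stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
           call. = FALSE)
    }
    for (k in names(overrides)) base[[k]] <- overrides[[k]]
  }
  validate_config(base)
}

#' @rdname build_config
#' @param config configuration list to validate.
#' @export
validate_config <- function(config) {
  template <- default_config()
  bad <- setdiff(names(config), names(template))
  if (length(bad) > 0L) {
    stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  missing <- setdiff(names(template), names(config))
  if (length(missing) > 0L) {
    stop(sprintf("missing config key(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  problems <- character(0)
  need_pos <- c("pixel_size_4x_um", "pixel_size_10x_um", "dz_um",
                "autofocus_range_um", "recrop_factor", "bf_exposure_ms",
                "gfp_exposure_ms")
  for (k in need_pos) if (!is.numeric(config[[k]]) || config[[k]] <= 0) {
    problems <- c(problems, sprintf("%s must be > 0", k))
  }
  need_nonneg <- c("blur_threshold", "blank_threshold", "feret_min_px",
                   "axis_threshold_px", "profile_epsilon", "min_particle_area_px2",
                   "phenotype_blur_sigma", "roi_margin")
  for (k in need_nonneg) if (!is.numeric(config[[k]]) || config[[k]] < 0) {
    problems <- c(problems, sprintf("%s must be >= 0", k))
  }
  if (config$n_z < 1L) problems <- c(problems, "n_z must be >= 1")
  if (config$substack_size %% 2L != 1L) {
    problems <- c(problems, "substack_size must be odd")
  }
  if (!config$denoise_method %in% c("median", "none")) {
    problems <- c(problems, "denoise_method must be 'median' or 'none'")
  }
  if (!config$focus_metric %in% c("laplacian", "variance")) {
    problems <- c(problems, "focus_metric must be 'laplacian' or 'variance'")
  }
  if (!config$connectivity %in% c(4L, 8L)) {
    problems <- c(problems, "connectivity must be 4 or 8")
  }
  if (!(config$bf_led_percent > 0 && config$bf_led_percent <= 100) ||
      !(config$gfp_led_percent > 0 && config$gfp_led_percent <= 100)) {
    problems <- c(problems, "LED percentages must be in (0, 100]")
  }
  if (length(problems) > 0L) {
    stop(paste(c("invalid configuration:", problems), collapse = "\n  "),
         call. = FALSE)
  }
  class(config) <- "ks_config"
  config
}

#' Read configuration overrides from a YAML key-value file
#'
#' @param path YAML file of flat key: value pairs.
#' @param base configuration the file overrides.
#' @return validated `ks_config`.
#' @export
read_config <- function(path, base = default_config()) {
  stopifnot(file.exists(path))
  build_config(yaml::read_yaml(path), base = base)
}

#' Write the fully-resolved configuration next to output artifacts
#'
#' @param config a `ks_config`.
#' @param dir output directory (created if needed).
#' @return the config file path, invisibly.
#' @export
write_config <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Content hash of a configuration
#'
#' MD5 of the canonical YAML serialisation; stamped into every CSV artifact
#' so outputs are traceable to the exact configuration that produced them.
#'
#' @param config a `ks_config`.
#' @return 32-character hash string.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
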