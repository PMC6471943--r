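## Ground-truthed synthetic plate generator.
##
## The pronephros is modelled as an elongated soft-edged bar (full length
## ~280 um, full width ~60 um at 2 dpf) in the GFP470 channel, with a dim
## midline seam so the bilateral tubule lobes read as two bright stripes at
## overview magnification.  The cystic phenotype inserts a zero-intensity
## lumen strip of width `cyst_gap_um` across the glomerular (central)
## region, splitting the structure in two -- the dark gap the downstream
## zero-run and ellipse classifiers key on.  Defocus is applied
## analytically: every edge profile is the exact 1-D Gaussian blur of the
## underlying indicator (a pair of normal CDFs), with the blur width growing
## linearly with distance from the best-focus plane.  Camera noise is
## Poisson shot noise on the signal plus additive Gaussian read noise and a
## small uniform pedestal, applied after the optics, so a fixed seed yields
## bit-identical frames.

SYN_SIGMA_BASE_UM <- 0.8     # in-focus PSF width
SYN_DEFOCUS_RATE <- 0.2      # blur sigma growth per um of defocus (NA 0.3)
SYN_WELL_PITCH_UM <- 9000
SYN_A1_CENTER_UM <- c(14380, 11240)  # ANSI plate: A1 centre offset

#' Stage coordinates of a well centre
#'
#' @param well canonical well string or `well_address`.
#' @return numeric (X, Y) in micrometres.
#' @export
well_center_um <- function(well) {
  if (is.character(well)) well <- parse_well(well)
  c(SYN_A1_CENTER_UM[1] + (well$column - 1L) * SYN_WELL_PITCH_UM,
    SYN_A1_CENTER_UM[2] + (match(well$row, PLATE_ROWS) - 1L) * SYN_WELL_PITCH_UM)
}

#' Per-well synthetic scene specification
#'
#' @param phenotype "wildtype", "cystic" or "blank".
#' @param embryo_center_um absolute stage (X, Y) of the pronephros centre, um.
#' @param orientation_deg rotation of the pronephros long axis.
#' @param lobe_length_um full length of the fused structure, um.
#' @param lobe_width_um full width (both lobes plus midline), um.
#' @param cyst_gap_um lumen strip width, um; must be 0 iff not cystic.
#' @param midline_dip fractional intensity dip along the midline seam.
#' @param focus_offset_um displacement of the best-focus plane from the
#'   stack centre, um.
#' @param blur_sigma_um extra defocus blur (quality-control "blurred well"
#'   dial); 0 for a well-focused well.
#' @param amplitude peak GFP signal, camera counts.
#' @param background_offset camera pedestal, counts.
#' @param gain camera gain, counts per photoelectron.
#' @param read_noise_sd Gaussian read noise, counts.
#' @param seed RNG seed for this well's noise.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(phenotype = c("wildtype", "cystic", "blank"),
                       embryo_center_um,
                       orientation_deg = 0,
                       lobe_length_um = 280,
                       lobe_width_um = 60,
                       cyst_gap_um = if (phenotype == "cystic") 50 else 0,
                       midline_dip = 0.35,
                       focus_offset_um = 0,
                       blur_sigma_um = 0,
                       amplitude = 20000,
                       background_offset = 4,
                       gain = 2,
                       read_noise_sd = 2,
                       seed = 1L) {
  phenotype <- match.arg(phenotype)
  if (phenotype == "cystic" && cyst_gap_um <= 0) {
    stop("cystic spec requires cyst_gap_um > 0", call. = FALSE)
  }
  if (phenotype != "cystic" && cyst_gap_um != 0) {
    stop("cyst_gap_um must be 0 unless phenotype is cystic", call. = FALSE)
  }
  stopifnot(length(embryo_center_um) == 2L, lobe_length_um > 0,
            lobe_width_um > 0, amplitude > 0, gain > 0, read_noise_sd >= 0,
            blur_sigma_um >= 0)
  structure(list(phenotype = phenotype,
                 embryo_center_um = as.numeric(embryo_center_um),
                 orientation_deg = orientation_deg,
                 lobe_length_um = lobe_length_um,
                 lobe_width_um = lobe_width_um,
                 cyst_gap_um = cyst_gap_um,
                 midline_dip = midline_dip,
                 focus_offset_um = focus_offset_um,
                 blur_sigma_um = blur_sigma_um,
                 amplitude = amplitude,
                 background_offset = background_offset,
                 gain = gain,
                 read_noise_sd = read_noise_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

## imaging field: centre in stage um, pixel size, frame edge (square)
syn_field <- function(center_um, pixel_size_um, n_px) {
  list(center_um = as.numeric(center_um), pixel_size_um = pixel_size_um,
       nx = as.integer(n_px), ny = as.integer(n_px))
}

## rotated in-structure coordinates (u along axis, v across), um, one matrix each
syn_coords <- function(spec, field) {
  xs <- field$center_um[1] + (seq_len(field$nx) - 1 - (field$nx - 1) / 2) * field$pixel_size_um
  ys <- field$center_um[2] + (seq_len(field$ny) - 1 - (field$ny - 1) / 2) * field$pixel_size_um
  dx <- outer(rep(1, field$ny), xs - spec$embryo_center_um[1])
  dy <- outer(ys - spec$embryo_center_um[2], rep(1, field$nx))
  th <- spec$orientation_deg * pi / 180
  list(u = cos(th) * dx + sin(th) * dy, v = -sin(th) * dx + cos(th) * dy)
}

## exact Gaussian blur of the indicator |t| <= h
blur_rect <- function(t, h, sigma) {
  if (h <= 0) return(array(0, dim = dim(t)))
  stats::pnorm((h - t) / sigma) - stats::pnorm((-h - t) / sigma)
}

#' Noise-free GFP signal of a scene in a given field
#'
#' @param spec a [scene_spec()].
#' @param field internal field description.
#' @param sigma_um total optical blur width, um.
#' @return matrix of expected signal counts (no pedestal, no noise).
#' @keywords internal
render_gfp_signal <- function(spec, field, sigma_um) {
  if (spec$phenotype == "blank") {
    return(matrix(0, field$ny, field$nx))
  }
  co <- syn_coords(spec, field)
  a <- spec$lobe_length_um / 2
  b <- spec$lobe_width_um / 2
  f_len <- blur_rect(co$u, a, sigma_um)
  if (spec$phenotype == "cystic") {
    f_len <- f_len - blur_rect(co$u, spec$cyst_gap_um / 2, sigma_um)
  }
  f_wid <- blur_rect(co$v, b, sigma_um)
  s_mid <- 5                        # midline seam half-width, um
  s_eff <- sqrt(s_mid^2 + sigma_um^2)
  dip <- spec$midline_dip * s_mid / s_eff
  seam <- 1 - dip * exp(-co$v^2 / (2 * s_eff^2))
  spec$amplitude * f_len * f_wid * seam
}

## noise-free bright-field signal: bright background with a darker embryo
## body oval and a faint deterministic texture
render_bf_signal <- function(spec, field, sigma_um) {
  base <- 30000
  if (spec$phenotype == "blank") {
    return(matrix(base, field$ny, field$nx))
  }
  co <- syn_coords(spec, field)
  body <- blur_rect(co$u, 1500, sigma_um + 10) * blur_rect(co$v, 400, sigma_um + 10)
  tex <- 0.04 * sin(2 * pi * co$u / 37) * sin(2 * pi * co$v / 53)
  base * (1 - (0.35 + tex) * body)
}

#' Apply the camera noise model
#'
#' Poisson shot noise on the expected photoelectron count, Gaussian read
#' noise, pedestal offset, rounding and clamping to the 16-bit range.
#' Draws from the current RNG stream.
#'
#' @param signal expected signal in counts.
#' @param spec a [scene_spec()] (supplies gain, offset, read noise).
#' @return integer-valued count matrix.
#' @keywords internal
add_camera_noise <- function(signal, spec) {
  n <- length(signal)
  photons <- stats::rpois(n, as.numeric(signal) / spec$gain)
  counts <- spec$gain * photons + spec$background_offset +
    stats::rnorm(n, 0, spec$read_noise_sd)
  clamp16(round(matrix(counts, nrow(signal), ncol(signal))))
}

#' Ground-truth footprint masks of a scene
#'
#' The lobe mask is the un-blurred geometric footprint of GFP tissue; the
#' lumen mask is the cyst strip clipped to the structure envelope.  Both are
#' evaluated at pixel centres of the given field, so mask pixel counts are
#' the exact rendered-geometry areas.
#'
#' @param spec a [scene_spec()].
#' @param field internal field description.
#' @return list of logical matrices `lobe` and `lumen`.
#' @keywords internal
footprint_masks <- function(spec, field) {
  if (spec$phenotype == "blank") {
    z <- matrix(FALSE, field$ny, field$nx)
    return(list(lobe = z, lumen = z))
  }
  co <- syn_coords(spec, field)
  a <- spec$lobe_length_um / 2
  b <- spec$lobe_width_um / 2
  env <- abs(co$u) <= a & abs(co$v) <= b
  if (spec$phenotype == "cystic") {
    strip <- abs(co$u) <= spec$cyst_gap_um / 2
    list(lobe = env & !strip, lumen = env & strip)
  } else {
    list(lobe = env, lumen = matrix(FALSE, field$ny, field$nx))
  }
}

#' Render a 4x whole-well overview plane
#'
#' One GFP pre-scan frame centred on the well, plus the ground-truth pixel
#' coordinates (0-based x, y) of the pronephros centroid.
#'
#' @param spec a [scene_spec()].
#' @param well canonical well string or `well_address`.
#' @param settings an [acquisition_settings()] with `objective_mag = 4`.
#' @return list with `image` (counts matrix) and `truth` (list: phenotype,
#'   `centroid_px` or NULL for blank wells, `field`).
#' @export
render_overview <- function(spec, well, settings = acquisition_settings(objective_mag = 4)) {
  stopifnot(inherits(spec, "scene_spec"))
  field <- syn_field(well_center_um(well), settings$pixel_size_um,
                     settings$camera_px)
  sigma_um <- sqrt(SYN_SIGMA_BASE_UM^2 + spec$blur_sigma_um^2)
  signal <- render_gfp_signal(spec, field, sigma_um)
  set.seed(spec$seed %% 2147483647L)
  img <- add_camera_noise(signal, spec)
  centroid <- NULL
  if (spec$phenotype != "blank") {
    centroid <- (spec$embryo_center_um - field$center_um) / field$pixel_size_um +
      (c(field$nx, field$ny) - 1) / 2
  }
  list(image = img,
       truth = list(phenotype = spec$phenotype, centroid_px = centroid,
                    field = field))
}

#' Render a 10x two-channel high-resolution z-stack
#'
#' Stacks are rendered as if the objective were centred at
#' `stage_center_um`; one best-focus plane (the stack centre shifted by the
#' spec's `focus_offset_um`) is sharpest, with Gaussian defocus growing
#' linearly away from it.
#'
#' @param spec a [scene_spec()].
#' @param well well the job belongs to (bounds check).
#' @param stage_center_um commanded stage centre (X, Y), um.
#' @param settings an [acquisition_settings()] with `objective_mag = 10`.
#' @return list with `gfp` and `bf` [zstack()]s (bf NULL when not in
#'   `settings$channels`), and `truth`: the geometric `lobe`/`lumen`
#'   footprint masks shared by every plane, the exact areas
#'   `pronephric_area_px2`/`cyst_area_px2`, `centroid_px` (0-based, may be
#'   NULL), `focus_index` (0-based) and the `field`.
#' @export
render_highres_stack <- function(spec, well, stage_center_um,
                                 settings = acquisition_settings(objective_mag = 10)) {
  stopifnot(inherits(spec, "scene_spec"), length(stage_center_um) == 2L)
  wc <- well_center_um(well)
  if (any(abs(stage_center_um - wc) > SYN_WELL_PITCH_UM / 2)) {
    stop(sprintf("stage centre (%.1f, %.1f) outside well %s bounds",
                 stage_center_um[1], stage_center_um[2],
                 if (is.character(well)) well else format_well(well)),
         call. = FALSE)
  }
  field <- syn_field(stage_center_um, settings$pixel_size_um, settings$camera_px)
  n_z <- settings$n_z
  ## 0-based index of the best-focus plane (z indices are 0-based throughout)
  focus_index <- max(0L, min(n_z - 1L, as.integer(ceiling(n_z / 2)) - 1L +
                               as.integer(round(spec$focus_offset_um / settings$dz_um))))
  sigma_z <- function(k) {                     # k is the 1-based plane number
    dz_off <- abs((k - 1L) - focus_index) * settings$dz_um
    sqrt(SYN_SIGMA_BASE_UM^2 + (SYN_DEFOCUS_RATE * dz_off)^2 + spec$blur_sigma_um^2)
  }
  set.seed((spec$seed + 7L) %% 2147483647L)
  channels <- settings$channels$name
  gfp <- bf <- NULL
  if ("GFP470" %in% channels) {
    planes <- lapply(seq_len(n_z), function(k) {
      add_camera_noise(render_gfp_signal(spec, field, sigma_z(k)), spec)
    })
    gfp <- zstack(planes, dz_um = settings$dz_um,
                  pixel_size_um = settings$pixel_size_um, channel = "GFP470")
  }
  if ("BF" %in% channels) {
    planes <- lapply(seq_len(n_z), function(k) {
      add_camera_noise(render_bf_signal(spec, field, sigma_z(k)), spec)
    })
    bf <- zstack(planes, dz_um = settings$dz_um,
                 pixel_size_um = settings$pixel_size_um, channel = "BF")
  }
  masks <- footprint_masks(spec, field)
  centroid <- NULL
  if (spec$phenotype != "blank") {
    centroid <- (spec$embryo_center_um - field$center_um) / field$pixel_size_um +
      (c(field$nx, field$ny) - 1) / 2
  }
  list(gfp = gfp, bf = bf,
       truth = list(phenotype = spec$phenotype,
                    lobe = masks$lobe, lumen = masks$lumen,
                    pronephric_area_px2 = sum(masks$lobe),
                    cyst_area_px2 = sum(masks$lumen),
                    centroid_px = centroid, focus_index = focus_index,
                    field = field))
}

#' Build a randomised full-plate scene
#'
#' Samples per-well phenotypes and geometry once, from one seed, emulating
#' a screening plate: embryos centred by the mounting tool with small
#' positional jitter (+/- 200 um) and near-horizontal orientation
#' (+/- 8 deg); structure length ~N(280, 15) um, width ~N(60, 5) um
#' (truncated); lumen widths uniform over `lumen_range_um`; ~5% empty wells
#' and ~5% badly focused wells by default.
#'
#' @param plate_id plate identifier.
#' @param wells wells to populate (default all 96).
#' @param p_cystic,p_blank phenotype mix.
#' @param p_blurred fraction of non-blank wells rendered defocused.
#' @param blur_sigma_um defocus blur applied to blurred wells.
#' @param lumen_range_um cyst lumen width range, um.
#' @param phenotypes optional explicit phenotype vector (overrides sampling).
#' @param blurred optional explicit logical vector marking blurred wells.
#' @param seed plate seed; per-well seeds are derived from it.
#' @return object of class `plate_scene`: list with `plate_id`, `seed` and
#'   named per-well `scene_spec`s in `wells`.
#' @export
make_plate_scene <- function(plate_id = "P01", wells = plate_wells(),
                             p_cystic = 0.45, p_blank = 0.05,
                             p_blurred = 0.05, blur_sigma_um = 10,
                             lumen_range_um = c(20, 80),
                             phenotypes = NULL, blurred = NULL, seed = 1L) {
  n <- length(wells)
  set.seed(seed %% 2147483647L)
  if (is.null(phenotypes)) {
    phenotypes <- sample(c("cystic", "blank", "wildtype"), n, replace = TRUE,
                         prob = c(p_cystic, p_blank, 1 - p_cystic - p_blank))
  }
  stopifnot(length(phenotypes) == n,
            all(phenotypes %in% c("wildtype", "cystic", "blank")))
  if (is.null(blurred)) {
    blurred <- stats::runif(n) < p_blurred & phenotypes != "blank"
  }
  stopifnot(length(blurred) == n)
  rtrunc <- function(n, mean, sd, lo, hi) {
    pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
  }
  specs <- vector("list", n)
  names(specs) <- wells
  for (i in seq_len(n)) {
    wc <- well_center_um(wells[i])
    specs[[i]] <- scene_spec(
      phenotype = phenotypes[i],
      embryo_center_um = wc + stats::runif(2, -200, 200),
      orientation_deg = stats::runif(1, -8, 8),
      lobe_length_um = rtrunc(1, 280, 15, 240, 320),
      lobe_width_um = rtrunc(1, 60, 5, 45, 75),
      cyst_gap_um = if (phenotypes[i] == "cystic")
        stats::runif(1, lumen_range_um[1], lumen_range_um[2]) else 0,
      blur_sigma_um = if (blurred[i]) blur_sigma_um else 0,
      amplitude = 20000 * exp(stats::rnorm(1, 0, 0.08)),
      seed = (seed * 1009L + i * 7L) %% 2147483647L)
  }
  structure(list(plate_id = plate_id, seed = as.integer(seed), wells = specs),
            class = "plate_scene")
}

#' @export
print.plate_scene <- function(x, ...) {
  ph <- vapply(x$wells, `[[`, "", "phenotype")
  cat(sprintf("<plate_scene %s: %d wells (%s)>\n", x$plate_id, length(ph),
              paste(sprintf("%s=%d", names(table(ph)), table(ph)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic plate's pre-scan images and ground truth to disk
#'
#' Writes one GFP pre-scan TIFF per well (package filename convention) plus
#' `truth.csv` (well, phenotype, overview centroid in 0-based pixels, and
#' exact footprint areas in px^2 at the 10x scale for a centred acquisition)
#' and `scene.json` with every per-well parameter.
#'
#' @param scene a [make_plate_scene()] result.
#' @param out_dir output directory; must be empty unless `force`.
#' @param config a `ks_config` (camera sizes and pixel calibrations).
#' @param force write into a non-empty directory.
#' @return invisible list with `truth` (data.frame) and `dir`.
#' @export
generate_plate <- function(scene, out_dir, config = default_config(),
                           force = FALSE) {
  stopifnot(inherits(scene, "plate_scene"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force) {
    stop(sprintf("output directory %s is not empty (use force = TRUE)", out_dir),
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  s4 <- settings_from_config(config, objective_mag = 4)
  s10 <- settings_from_config(config, objective_mag = 10)
  rows <- vector("list", length(scene$wells))
  for (i in seq_along(scene$wells)) {
    w <- names(scene$wells)[i]
    spec <- scene$wells[[i]]
    ov <- render_overview(spec, w, s4)
    path <- file.path(out_dir, format_filename(scene$plate_id, "prescan", w,
                                               "GFP470", 0L))
    write_tiff(ov$image, path, force = force)
    tf <- syn_field(spec$embryo_center_um, s10$pixel_size_um, s10$camera_px)
    masks <- footprint_masks(spec, tf)
    cen <- if (is.null(ov$truth$centroid_px)) c(NA_real_, NA_real_) else
      ov$truth$centroid_px
    rows[[i]] <- data.frame(well = w, phenotype = spec$phenotype,
                            centroid_x_px = cen[1], centroid_y_px = cen[2],
                            cyst_area_px2 = sum(masks$lumen),
                            pronephric_area_px2 = sum(masks$lobe),
                            stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, rows)
  utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  jsonlite::write_json(lapply(scene$wells, unclass),
                       file.path(out_dir, "scene.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, dir = out_dir))
}
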