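## Validation harnesses: self-contained simulation studies that exercise
## the pipeline against the generator's ground truth.  These back the
## package's own quality claims (closed-loop centring, QC discrimination,
## classification accuracy, cyst-area recovery) and are what
## scripts/acceptance.R re-runs; frame sizes are chosen so each study runs
## in about a minute on one core (the methods vignette discusses the
## choices).

## test-scale configuration used by the validation studies: 512 px frames
## at the instrument pixel calibration keep the full structure and every
## published pixel threshold meaningful
bench_config <- function(...) {
  build_config(list(prescan_camera_px = 512L, rescan_camera_px = 512L, ...))
}

#' Closed-loop smart-acquisition benchmark
#'
#' Simulates a plate, runs detection + job generation + mock
#' re-acquisition, and scores each truly non-blank well by the distance
#' between the true pronephros centroid and the rescan field centre,
#' in percent of the field width.
#'
#' @param seed study seed.
#' @param n_wells wells simulated (default 96).
#' @param n_z rescan planes per well (the centring score does not depend
#'   on stack depth; 5 keeps the study fast).
#' @param tol_frac success tolerance as a fraction of field width.
#' @return list: `success_pct`, `n`, per-well `errors_um`, `tol_um`.
#' @export
benchmark_closed_loop <- function(seed = 1L, n_wells = 96L, n_z = 5L,
                                  tol_frac = 0.05) {
  config <- bench_config(n_z = as.integer(n_z), substack_size = 5L,
                         rescan_channels = "GFP470",
                         seed = as.integer(seed))
  scene <- make_plate_scene(wells = plate_wells()[seq_len(n_wells)],
                            seed = config$seed)
  dir <- tempfile("closedloop")
  on.exit(unlink(dir, recursive = TRUE))
  generate_plate(scene, file.path(dir, "prescan"), config)
  acq <- smart_acquire_plate(file.path(dir, "prescan"), scene, dir, config)
  truth_blank <- vapply(scene$wells, function(s) s$phenotype == "blank",
                        logical(1))
  nonblank <- names(scene$wells)[!truth_blank]
  err <- acq$center_error_um[match(nonblank, acq$well)]
  err[is.na(err)] <- Inf                       # undetected non-blank well
  field_um <- config$rescan_camera_px * config$pixel_size_10x_um
  tol_um <- tol_frac * field_um
  list(success_pct = 100 * mean(err < tol_um), n = length(nonblank),
       errors_um = err, tol_um = tol_um)
}

#' QC discrimination benchmark
#'
#' Renders a labelled set (ok / blurred / blank in equal numbers),
#' calibrates the QC thresholds on it, and reports per-class precision and
#' recall plus the blur-metric monotonicity check under growing Gaussian
#' blur.
#'
#' @param seed study seed.
#' @param n_per_class images per class (default 100).
#' @param blur_sigma_um defocus of the blurred class.
#' @param n_monotonic wells for the monotonicity check.
#' @return list: `precision`, `recall` (named per class),
#'   `min_precision_pct`, `min_recall_pct`, `monotonic_fraction`,
#'   `calibration`, `n`.
#' @export
benchmark_qc <- function(seed = 1L, n_per_class = 100L, blur_sigma_um = 10,
                         n_monotonic = 20L) {
  ## compact frames: QC statistics are calibrated on the same set, so the
  ## absolute scale is free; 256 px at 1.3 um/px keeps the whole structure.
  ## The rolling-ball radius follows the pixel size (25 px here = the same
  ## 32.5 um ball as 50 px at 0.65 um/px) -- the ball must stay comparable
  ## to the structure width for background subtraction to discriminate
  config <- bench_config(prescan_camera_px = 256L, rescan_camera_px = 256L,
                         pixel_size_10x_um = 1.3, crop_px = 256L,
                         background_radius = 25L,
                         n_z = 1L, seed = as.integer(seed))
  labels <- rep(c("ok", "blurred", "blank"), each = n_per_class)
  wells <- rep_len(plate_wells(), length(labels))
  s10 <- settings_from_config(config, 10)
  s10$n_z <- 1L
  set.seed(seed %% 2147483647L)
  phen <- ifelse(labels == "blank", "blank",
                 sample(c("wildtype", "cystic"), length(labels), TRUE))
  images <- vector("list", length(labels))
  rtrunc <- function(mean, sd, lo, hi) min(max(stats::rnorm(1, mean, sd), lo), hi)
  for (i in seq_along(labels)) {
    wc <- well_center_um(wells[i])
    spec <- scene_spec(phen[i], embryo_center_um = wc + stats::runif(2, -20, 20),
                       orientation_deg = stats::runif(1, -8, 8),
                       lobe_length_um = rtrunc(280, 15, 240, 320),
                       lobe_width_um = rtrunc(60, 5, 45, 75),
                       cyst_gap_um = if (phen[i] == "cystic")
                         stats::runif(1, 20, 80) else 0,
                       blur_sigma_um = if (labels[i] == "blurred")
                         blur_sigma_um else 0,
                       amplitude = 20000 * exp(stats::rnorm(1, 0, 0.08)),
                       seed = (seed * 2711L + i) %% 2147483647L)
    st <- render_highres_stack(spec, wells[i], wc, s10)
    images[[i]] <- process_well(st$gfp, config, wells[i])$projection
  }
  cal <- calibrate_qc(images, labels, config)
  config2 <- build_config(list(blur_threshold = cal$blur_threshold,
                               background_radius = cal$background_radius,
                               blank_threshold = cal$blank_threshold,
                               blank_above = cal$blank_above), base = config)
  called <- vapply(images, function(img) qc_well(img, config2)$label, "")
  classes <- c("ok", "blurred", "blank")
  precision <- vapply(classes, function(cl) {
    p <- sum(called == cl & labels == cl) / max(sum(called == cl), 1)
    p
  }, numeric(1))
  recall <- vapply(classes, function(cl) {
    sum(called == cl & labels == cl) / sum(labels == cl)
  }, numeric(1))
  ## blur metric monotonicity under growing Gaussian sigma, at the
  ## calibrated ball radius (the one QC deploys; a ball the size of the
  ## structure half-width sits in a degenerate regime the calibration
  ## avoids)
  ok_imgs <- images[labels == "ok"][seq_len(min(n_monotonic, n_per_class))]
  mono <- vapply(ok_imgs, function(img) {
    v <- vapply(c(0, 2, 4, 8), function(s) {
      b <- if (s == 0) img else round(gaussian_blur(img, s))
      detect_blur(b, background_radius = cal$background_radius)$variance
    }, numeric(1))
    all(diff(v) <= 0)
  }, logical(1))
  list(precision = precision, recall = recall,
       min_precision_pct = 100 * min(precision),
       min_recall_pct = 100 * min(recall),
       monotonic_fraction = mean(mono),
       calibration = cal[c("blur_threshold", "background_radius",
                           "blank_threshold", "blank_above")],
       n = length(labels))
}

#' Phenotype classification benchmark
#'
#' Balanced wild-type/cystic set with lumen widths sampled uniformly over
#' `lumen_range_um`; accuracy counts ambiguous calls as errors.
#'
#' @param seed study seed.
#' @param n_wells total wells (half per class; default 288).
#' @param lumen_range_um cyst lumen width range.
#' @return list: `accuracy_pct`, `n`, `confusion` table, `calls`.
#' @export
benchmark_phenotype <- function(seed = 1L, n_wells = 288L,
                                lumen_range_um = c(20, 80)) {
  config <- bench_config(n_z = 1L, seed = as.integer(seed))
  s10 <- settings_from_config(config, 10)
  s10$n_z <- 1L
  set.seed(seed %% 2147483647L)
  phen <- rep(c("wildtype", "cystic"), each = n_wells %/% 2L)
  wells <- rep_len(plate_wells(), length(phen))
  calls <- character(length(phen))
  for (i in seq_along(phen)) {
    wc <- well_center_um(wells[i])
    spec <- scene_spec(phen[i], embryo_center_um = wc + stats::runif(2, -20, 20),
                       orientation_deg = stats::runif(1, -8, 8),
                       lobe_length_um = min(max(stats::rnorm(1, 280, 15), 240), 320),
                       lobe_width_um = min(max(stats::rnorm(1, 60, 5), 45), 75),
                       cyst_gap_um = if (phen[i] == "cystic")
                         stats::runif(1, lumen_range_um[1], lumen_range_um[2]) else 0,
                       amplitude = 20000 * exp(stats::rnorm(1, 0, 0.08)),
                       seed = (seed * 4519L + i) %% 2147483647L)
    st <- render_highres_stack(spec, wells[i], wc, s10)
    pw <- process_well(st$gfp, config, wells[i])
    calls[i] <- classify_well(pw, config)$label
  }
  list(accuracy_pct = 100 * mean(calls == phen), n = length(phen),
       confusion = table(truth = phen, call = calls), calls = calls)
}

#' Cyst-area recovery benchmark
#'
#' Sweeps rendered lumen widths with several noise seeds per width and
#' compares the measured cystic area against the exact rendered lumen
#' pixel count.
#'
#' @param seed study seed.
#' @param widths_um lumen widths swept.
#' @param seeds_per_width noise replicates per width.
#' @return list: `median_abs_rel_error_pct`, `n`, per-well `rel_errors`.
#' @export
benchmark_cyst_recovery <- function(seed = 1L, widths_um = seq(20, 80, 10),
                                    seeds_per_width = 10L) {
  config <- bench_config(n_z = 1L, seed = as.integer(seed))
  s10 <- settings_from_config(config, 10)
  s10$n_z <- 1L
  set.seed(seed %% 2147483647L)
  rel <- numeric(0)
  for (w in widths_um) for (r in seq_len(seeds_per_width)) {
    well <- plate_wells()[(length(rel) %% 96L) + 1L]
    wc <- well_center_um(well)
    spec <- scene_spec("cystic", embryo_center_um = wc + stats::runif(2, -20, 20),
                       orientation_deg = stats::runif(1, -8, 8),
                       cyst_gap_um = w,
                       amplitude = 20000 * exp(stats::rnorm(1, 0, 0.08)),
                       seed = (seed * 6073L + length(rel) + 1L) %% 2147483647L)
    st <- render_highres_stack(spec, well, wc, s10)
    pw <- process_well(st$gfp, config, well)
    prep <- prepare_binary(pw$recrop, config$phenotype_blur_sigma)
    ca <- cystic_area(prep$mask, config)
    rel <- c(rel, (ca$area_px2 - st$truth$cyst_area_px2) / st$truth$cyst_area_px2)
  }
  list(median_abs_rel_error_pct = 100 * stats::median(abs(rel)),
       n = length(rel), rel_errors = rel)
}
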