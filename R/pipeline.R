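## End-to-end orchestration: simulate -> smart-acquire (mock) -> preprocess
## -> qc -> classify -> quantify -> report, on one directory tree, with
## per-stage counts and bit-deterministic outputs for a fixed seed.

## CSV artifact helpers: every artifact names the config hash that
## produced it in a leading comment line.
write_artifact_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kidneyscreen config %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a kidneyscreen CSV artifact
#'
#' @param path CSV written by the pipeline (leading `#` comment lines hold
#'   the config hash).
#' @return data.frame.
#' @export
read_artifact_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Build a labelled QC calibration set
#'
#' Renders `n_per_class` synthetic wells per class (ok, blurred, blank)
#' with the generator defaults, reduces them with the standard
#' preprocessing chain and returns the projections plus labels -- the
#' input [calibrate_qc()] expects.
#'
#' @param config a `ks_config`.
#' @param n_per_class images per class.
#' @param seed RNG seed.
#' @param blur_sigma_um defocus blur of the blurred class, um.
#' @return list with `images` (projection matrices) and `labels`.
#' @export
qc_calibration_set <- function(config = default_config(), n_per_class = 20L,
                               seed = 1L, blur_sigma_um = 10) {
  s10 <- settings_from_config(config, objective_mag = 10)
  s10$n_z <- as.integer(config$substack_size)   # projection depth of the pipeline
  labels <- rep(c("ok", "blurred", "blank"), each = n_per_class)
  wells <- rep_len(plate_wells(), length(labels))
  set.seed(seed %% 2147483647L)
  phen <- ifelse(labels == "blank", "blank",
                 sample(c("wildtype", "cystic"), length(labels), replace = TRUE))
  images <- vector("list", length(labels))
  rtrunc <- function(mean, sd, lo, hi) min(max(stats::rnorm(1, mean, sd), lo), hi)
  for (i in seq_along(labels)) {
    wc <- well_center_um(wells[i])
    ## geometry sampled like make_plate_scene so the calibrated threshold
    ## covers the plate's real variability, not just the default shape
    spec <- scene_spec(
      phenotype = phen[i],
      embryo_center_um = wc + stats::runif(2, -20, 20),
      orientation_deg = stats::runif(1, -8, 8),
      lobe_length_um = rtrunc(280, 15, 240, 320),
      lobe_width_um = rtrunc(60, 5, 45, 75),
      cyst_gap_um = if (phen[i] == "cystic") stats::runif(1, 20, 80) else 0,
      blur_sigma_um = if (labels[i] == "blurred") blur_sigma_um else 0,
      amplitude = 20000 * exp(stats::rnorm(1, 0, 0.08)),
      seed = (seed * 3331L + i) %% 2147483647L)
    st <- render_highres_stack(spec, wells[i], wc, s10)
    images[[i]] <- process_well(st$gfp, config, well = wells[i])$projection
  }
  list(images = images, labels = labels)
}

#' Run the whole screening pipeline on synthetic data
#'
#' Stages: build a plate scene from the seed; write pre-scan overviews and
#' ground truth; run the closed smart-acquisition loop against the mock
#' microscope; preprocess every rescan stack; self-calibrate the QC
#' thresholds on a labelled synthetic set (unless `qc_calibrate` is off);
#' quality-control, classify and quantify; write the plate summary.  All
#' randomness derives from `config$seed`, so two runs produce bit-identical
#' CSV artifacts.
#'
#' @param out_dir output directory tree.
#' @param config a `ks_config`.
#' @param n_wells number of wells to simulate (from A01, row-major).
#' @param force overwrite existing outputs.
#' @param quiet suppress per-stage messages.
#' @return invisible list with every stage's results (`scene`,
#'   `acquisition`, `processed`, `qc`, `calls`, `measurements`, `matrix`,
#'   `config`, `counts`).
#' @export
run_pipeline <- function(out_dir, config = default_config(), n_wells = 96L,
                         force = FALSE, quiet = TRUE) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage 1/7: simulating plate (%d wells, seed %d)", n_wells, config$seed)
  scene <- make_plate_scene(wells = plate_wells()[seq_len(n_wells)],
                            seed = config$seed)
  prescan_dir <- file.path(out_dir, "prescan")
  generate_plate(scene, prescan_dir, config, force = force)

  say("stage 2/7: smart acquisition")
  acq <- smart_acquire_plate(prescan_dir, scene, out_dir, config, force = force)

  say("stage 3/7: preprocessing")
  processed <- process_plate(file.path(out_dir, "rescan"), config, quiet = quiet)

  if (config$qc_calibrate) {
    say("stage 4/7: QC threshold calibration (%d per class)",
        config$qc_calibration_n)
    cal_set <- qc_calibration_set(config, config$qc_calibration_n,
                                  seed = (config$seed + 599L) %% 2147483647L)
    cal <- calibrate_qc(cal_set$images, cal_set$labels, config)
    config <- build_config(list(blur_threshold = cal$blur_threshold,
                                background_radius = cal$background_radius,
                                blank_threshold = cal$blank_threshold,
                                blank_above = cal$blank_above), base = config)
  } else say("stage 4/7: QC calibration skipped")

  say("stage 5/7: quality control")
  qc <- qc_plate(processed, config, quiet = quiet)

  say("stage 6/7: phenotype classification")
  calls <- classify_plate(qc$ok, config, quiet = quiet)

  say("stage 7/7: quantification")
  meas <- list()
  if (!is.null(calls)) {
    for (i in seq_len(nrow(calls))) {
      m <- measure_well(qc$ok[[calls$well[i]]], calls[i, ], config)
      if (!is.null(m)) meas[[length(meas) + 1L]] <- m
    }
  }
  measurements <- if (length(meas)) do.call(rbind, meas) else
    data.frame(well = character(0), label = character(0),
               pronephric_area_px2 = numeric(0), cystic_area_px2 = numeric(0),
               total_kidney_area_px2 = numeric(0),
               pronephric_area_um2 = numeric(0), cystic_area_um2 = numeric(0),
               total_kidney_area_um2 = numeric(0))

  hash <- config_hash(config)
  write_config(config, out_dir)
  write_artifact_csv(acq, file.path(out_dir, "acquisition.csv"), hash)
  write_artifact_csv(qc$records, file.path(out_dir, "qc.csv"), hash)
  if (!is.null(calls)) {
    write_artifact_csv(calls, file.path(out_dir, "phenotype.csv"), hash)
  }
  write_artifact_csv(measurements, file.path(out_dir, "measurements.csv"), hash)
  mat <- plate_summary(measurements, file.path(out_dir, "report"))

  counts <- list(
    wells_simulated = n_wells,
    wells_detected = sum(!acq$blank),
    wells_blank_prescan = sum(acq$blank),
    wells_processed = length(processed),
    qc_ok = sum(qc$records$label == "ok"),
    qc_blurred = sum(qc$records$label == "blurred"),
    qc_blank = sum(qc$records$label == "blank"),
    wildtype = if (is.null(calls)) 0L else sum(calls$label == "wildtype"),
    cystic = if (is.null(calls)) 0L else sum(calls$label == "cystic"),
    ambiguous = if (is.null(calls)) 0L else sum(calls$label == "ambiguous"),
    measured = nrow(measurements))
  jsonlite::write_json(counts, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE)
  say("done: %d/%d wells measured", counts$measured, n_wells)
  invisible(list(scene = scene, acquisition = acq, processed = processed,
                 qc = qc, calls = calls, measurements = measurements,
                 matrix = mat, config = config, counts = counts))
}

#' Rebuild a plate scene from a generated scene.json
#'
#' @param path scene.json written by [generate_plate()].
#' @param plate_id plate identifier.
#' @param seed seed recorded on the rebuilt scene.
#' @return a `plate_scene`.
#' @export
scene_from_json <- function(path, plate_id = "P01", seed = 1L) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  specs <- lapply(raw, function(s) do.call(scene_spec, s))
  structure(list(plate_id = plate_id, seed = as.integer(seed), wells = specs),
            class = "plate_scene")
}
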