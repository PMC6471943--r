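## Feedback ("smart") microscopy: detect the pronephros in a pre-scan
## overview, translate to stage coordinates, emit a high-resolution job
## script, watch a folder for new acquisitions, and execute jobs against a
## mock microscope that renders synthetic scenes.
##
## Job-script grammar (one command per line, uppercase verb, micrometre
## arguments with 1 decimal place):
##   GOTO <X> <Y>
##   AUTOFOCUS <channel> <range>
##   SET_CHANNEL <name> <led_percent> <exposure_ms>
##   STACK <n_z> <dz>

#' Acquisition settings
#'
#' The microscope-facing contract for one imaging pass: objective, camera,
#' z geometry, autofocus range and channel excitation settings.
#'
#' @param objective_mag 4 (overview pre-scan) or 10 (high-resolution rescan).
#' @param objective_na numerical aperture (0.13 at 4x, 0.3 at 10x).
#' @param n_z number of z-slices (>= 1).
#' @param dz_um z spacing, um.
#' @param autofocus_range_um software autofocus search volume, um.
#' @param channels data.frame with columns `name`, `led_percent`,
#'   `exposure_ms`, acquired in row order.
#' @param camera_px square camera frame edge, pixels.
#' @param pixel_size_um lateral calibration; defaults to 1.625 um/px at 4x
#'   and 0.65 um/px at 10x (6.5 um sCMOS pitch assumed -- set explicitly for
#'   real instruments).
#' @return object of class `acquisition_settings`.
#' @export
acquisition_settings <- function(objective_mag = 10,
                                 objective_na = if (objective_mag == 4) 0.13 else 0.3,
                                 n_z = if (objective_mag == 4) 1L else 30L,
                                 dz_um = 4,
                                 autofocus_range_um = 700,
                                 channels = data.frame(
                                   name = c("BF", "GFP470"),
                                   led_percent = c(60, 100),
                                   exposure_ms = c(10, 20)),
                                 camera_px = 2048L,
                                 pixel_size_um = if (objective_mag == 4) 1.625 else 0.65) {
  stopifnot(objective_mag %in% c(4, 10), n_z >= 1L, dz_um > 0,
            autofocus_range_um > 0, camera_px >= 16L, pixel_size_um > 0,
            is.data.frame(channels), nrow(channels) >= 1L,
            all(c("name", "led_percent", "exposure_ms") %in% names(channels)),
            all(channels$name %in% CHANNELS),
            all(channels$led_percent > 0 & channels$led_percent <= 100),
            all(channels$exposure_ms > 0))
  structure(list(objective_mag = objective_mag, objective_na = objective_na,
                 n_z = as.integer(n_z), dz_um = dz_um,
                 autofocus_range_um = autofocus_range_um, channels = channels,
                 camera_px = as.integer(camera_px),
                 pixel_size_um = pixel_size_um),
            class = "acquisition_settings")
}

#' Derive acquisition settings from a pipeline configuration
#'
#' @param config a `ks_config`.
#' @param objective_mag 4 or 10.
#' @return an [acquisition_settings()].
#' @export
settings_from_config <- function(config, objective_mag = 10) {
  chn <- trimws(strsplit(config$rescan_channels, ",")[[1]])
  channels <- data.frame(
    name = chn,
    led_percent = ifelse(chn == "BF", config$bf_led_percent, config$gfp_led_percent),
    exposure_ms = ifelse(chn == "BF", config$bf_exposure_ms, config$gfp_exposure_ms))
  if (objective_mag == 4) {
    channels <- data.frame(name = "GFP470",
                           led_percent = config$gfp_led_percent,
                           exposure_ms = config$gfp_exposure_ms)
  }
  acquisition_settings(
    objective_mag = objective_mag,
    n_z = if (objective_mag == 4) 1L else config$n_z,
    dz_um = config$dz_um,
    autofocus_range_um = config$autofocus_range_um,
    channels = channels,
    camera_px = if (objective_mag == 4) config$prescan_camera_px else config$rescan_camera_px,
    pixel_size_um = if (objective_mag == 4) config$pixel_size_4x_um else config$pixel_size_10x_um)
}

#' Stage-coordinate calibration of an overview field
#'
#' Pixel (0, 0) is the centre of the top-left pixel, x rightward, y
#' downward; stage axis orientation is set by sign flips.
#'
#' @param origin_um stage (X, Y) of pixel (0, 0), um.
#' @param pixel_size_um lateral pixel size, um.
#' @param flip c(x, y) in {-1, +1}: stage axis direction per pixel axis.
#' @return object of class `stage_calibration`.
#' @export
stage_calibration <- function(origin_um, pixel_size_um, flip = c(1, 1)) {
  stopifnot(length(origin_um) == 2L, pixel_size_um > 0,
            length(flip) == 2L, all(flip %in% c(-1, 1)))
  structure(list(origin_um = as.numeric(origin_um),
                 pixel_size_um = pixel_size_um, flip = as.numeric(flip)),
            class = "stage_calibration")
}

## calibration of the overview field of a given well
overview_calibration <- function(well, settings) {
  wc <- well_center_um(well)
  stage_calibration(wc - (settings$camera_px - 1) / 2 * settings$pixel_size_um,
                    settings$pixel_size_um)
}

#' Affine pixel/stage coordinate maps
#'
#' @param px numeric (x, y) pixel coordinates (0-based), or an n x 2 matrix.
#' @param cal a [stage_calibration()].
#' @return stage (X, Y) in um (same shape as input).
#' @export
pixel_to_stage <- function(px, cal) {
  stopifnot(inherits(cal, "stage_calibration"))
  if (is.matrix(px)) {
    cbind(cal$origin_um[1] + px[, 1] * cal$pixel_size_um * cal$flip[1],
          cal$origin_um[2] + px[, 2] * cal$pixel_size_um * cal$flip[2])
  } else {
    cal$origin_um + px * cal$pixel_size_um * cal$flip
  }
}

#' @rdname pixel_to_stage
#' @param stage_um stage (X, Y) in um, or an n x 2 matrix.
#' @export
stage_to_pixel <- function(stage_um, cal) {
  stopifnot(inherits(cal, "stage_calibration"))
  if (is.matrix(stage_um)) {
    cbind((stage_um[, 1] - cal$origin_um[1]) / (cal$pixel_size_um * cal$flip[1]),
          (stage_um[, 2] - cal$origin_um[2]) / (cal$pixel_size_um * cal$flip[2]))
  } else {
    (stage_um - cal$origin_um) / (cal$pixel_size_um * cal$flip)
  }
}

#' Detect the pronephros centre in an overview plane
#'
#' Automatic threshold (Li by default) then intensity-weighted centre of
#' mass of the foreground pixels.  Returns NULL (blank signal) when the
#' foreground area is below `min_area_px`, when the foreground/background
#' mean contrast is below `detect_min_contrast` (a noise-only well also
#' splits under an automatic threshold, but with no real contrast), or
#' when the image cannot be thresholded at all (constant).
#'
#' @param overview single GFP pre-scan plane (counts matrix).
#' @param config a `ks_config` (`detect_min_area_px`, `detect_weighting`).
#' @param cal optional [stage_calibration()]; when given, stage coordinates
#'   are attached.
#' @param well optional well identity recorded in the result.
#' @return NULL, or list with `px` (0-based x, y), `stage_um` (or NULL),
#'   `foreground_area_px`, `well`.
#' @export
detect_pronephros_center <- function(overview, config = default_config(),
                                     cal = NULL, well = NULL) {
  check_image(overview)
  th <- tryCatch(li_threshold(overview), error = function(e) NULL)
  if (is.null(th)) return(NULL)
  mask <- th$mask
  area <- sum(mask)
  if (area < config$detect_min_area_px) return(NULL)
  mu_fg <- mean(overview[mask])
  mu_bg <- mean(overview[!mask])
  if (mu_fg < config$detect_min_contrast * max(mu_bg, 1)) return(NULL)
  idx <- which(mask, arr.ind = TRUE)          # [row, col] 1-based
  w <- if (identical(config$detect_weighting, "binary")) rep(1, nrow(idx))
       else overview[mask]
  px <- c(sum((idx[, 2] - 1) * w), sum((idx[, 1] - 1) * w)) / sum(w)
  list(px = px,
       stage_um = if (!is.null(cal)) pixel_to_stage(px, cal) else NULL,
       foreground_area_px = area,
       well = well)
}

#' Compose a high-resolution imaging job script
#'
#' Emits, in order, GOTO to the detected stage centre, AUTOFOCUS in the GFP
#' channel over the configured search range, then one SET_CHANNEL + STACK
#' pair per channel.  Output text is byte-deterministic.
#'
#' @param roi detection result from [detect_pronephros_center()] with
#'   `stage_um` set.
#' @param settings an [acquisition_settings()].
#' @return object of class `job_script`: list(well, lines, path = NULL).
#' @export
make_job_script <- function(roi, settings = acquisition_settings()) {
  stopifnot(!is.null(roi$stage_um))
  lines <- c(
    sprintf("GOTO %.1f %.1f", roi$stage_um[1], roi$stage_um[2]),
    sprintf("AUTOFOCUS GFP470 %.1f", settings$autofocus_range_um))
  for (i in seq_len(nrow(settings$channels))) {
    ch <- settings$channels[i, ]
    lines <- c(lines,
               sprintf("SET_CHANNEL %s %g %g", ch$name, ch$led_percent, ch$exposure_ms),
               sprintf("STACK %d %.1f", settings$n_z, settings$dz_um))
  }
  structure(list(well = roi$well, lines = lines, path = NULL),
            class = "job_script")
}

#' Write a job script atomically
#'
#' Writes to a temporary file in the target directory and renames, so a
#' folder-watching consumer never sees a partial script.
#'
#' @param job a `job_script`.
#' @param dir destination directory.
#' @return the job file path.
#' @export
write_job_script <- function(job, dir) {
  stopifnot(inherits(job, "job_script"), !is.null(job$well))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  well <- if (is.character(job$well)) job$well else format_well(job$well)
  path <- file.path(dir, sprintf("job_%s.txt", well))
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  writeLines(job$lines, tmp)
  file.rename(tmp, path)
  job$path <- path
  path
}

#' Parse a job script
#'
#' @param lines character vector of script lines (or a `job_script`).
#' @return list of command records (verb plus typed arguments).
#' @export
parse_job_script <- function(lines) {
  if (inherits(lines, "job_script")) lines <- lines$lines
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    verb <- tok[1]
    cmd <- switch(verb,
      GOTO = {
        if (length(tok) != 3L) stop(sprintf("line %d: GOTO needs 2 args", i), call. = FALSE)
        list(verb = "GOTO", x = as.numeric(tok[2]), y = as.numeric(tok[3]))
      },
      AUTOFOCUS = {
        if (length(tok) != 3L) stop(sprintf("line %d: AUTOFOCUS needs 2 args", i), call. = FALSE)
        list(verb = "AUTOFOCUS", channel = tok[2], range_um = as.numeric(tok[3]))
      },
      SET_CHANNEL = {
        if (length(tok) != 4L) stop(sprintf("line %d: SET_CHANNEL needs 3 args", i), call. = FALSE)
        list(verb = "SET_CHANNEL", name = tok[2],
             led_percent = as.numeric(tok[3]), exposure_ms = as.numeric(tok[4]))
      },
      STACK = {
        if (length(tok) != 3L) stop(sprintf("line %d: STACK needs 2 args", i), call. = FALSE)
        list(verb = "STACK", n_z = as.integer(tok[2]), dz_um = as.numeric(tok[3]))
      },
      stop(sprintf("line %d: unknown command '%s'", i, verb), call. = FALSE))
    out[[i]] <- cmd
  }
  out
}

#' Poll a directory and dispatch new files exactly once
#'
#' Each matching file is passed to `handler` exactly once, only after its
#' size is stable across two consecutive polls (so partially written files
#' are never dispatched).  Processed paths are appended to a plain-text
#' ledger; re-running with a persisted ledger dispatches nothing twice.
#' Handler errors are caught: the file is marked failed and the loop
#' continues.
#'
#' @param dir directory to watch.
#' @param handler function(path) called per stable new file.
#' @param poll_interval seconds between polls.
#' @param stop_condition optional function(state) -> logical; checked after
#'   each poll with state = list(processed, failed, pending).
#' @param ledger_path optional ledger file (one processed path per line).
#' @param pattern file name filter.
#' @param idle_polls stop after this many consecutive polls with no new or
#'   pending files (when no `stop_condition` fires first).
#' @param max_polls hard poll-count limit.
#' @return invisible list with `processed` and `failed` path vectors.
#' @export
watch_folder <- function(dir, handler, poll_interval = 0.2,
                         stop_condition = NULL, ledger_path = NULL,
                         pattern = "\\.tif$", idle_polls = 3L,
                         max_polls = 10000L) {
  stopifnot(dir.exists(dir), is.function(handler))
  processed <- character(0)
  if (!is.null(ledger_path) && file.exists(ledger_path)) {
    processed <- readLines(ledger_path)
  }
  failed <- character(0)
  prev_sizes <- NULL
  idle <- 0L
  for (poll in seq_len(max_polls)) {
    paths <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
    sizes <- file.size(paths); names(sizes) <- paths
    new <- setdiff(paths, c(processed, failed))
    ready <- new[!is.na(prev_sizes[new]) & prev_sizes[new] == sizes[new]]
    for (p in ready) {
      ok <- tryCatch({ handler(p); TRUE },
                     error = function(e) {
                       warning(sprintf("handler failed for %s: %s", p,
                                       conditionMessage(e)), call. = FALSE)
                       FALSE
                     })
      if (ok) {
        processed <- c(processed, p)
        if (!is.null(ledger_path)) cat(p, "\n", sep = "", file = ledger_path,
                                       append = TRUE)
      } else failed <- c(failed, p)
    }
    pending <- setdiff(new, ready)
    state <- list(processed = processed, failed = failed, pending = pending)
    if (!is.null(stop_condition) && isTRUE(stop_condition(state))) break
    idle <- if (length(ready) == 0L && length(pending) == 0L) idle + 1L else 0L
    if (is.null(stop_condition) && idle >= idle_polls) break
    prev_sizes <- sizes
    if (poll_interval > 0) Sys.sleep(poll_interval)
  }
  invisible(list(processed = processed, failed = failed))
}

#' Execute a job script against the mock microscope
#'
#' Parses the script, renders the well's synthetic scene at the commanded
#' stage centre and writes the rescan planes as single-plane TIFFs under the
#' package filename convention.
#'
#' @param job a `job_script` (or character lines plus `well`).
#' @param spec the well's [scene_spec()].
#' @param out_dir directory for the rescan TIFFs.
#' @param settings base [acquisition_settings()] supplying camera frame and
#'   pixel calibration; channel and stack geometry come from the script.
#' @param plate_id plate identifier used in file names.
#' @param well well (defaults to `job$well`).
#' @param force overwrite existing files.
#' @return invisible list with `files` written, `truth` from the renderer,
#'   and the commanded `stage_um`.
#' @export
mock_microscope_execute <- function(job, spec, out_dir,
                                    settings = acquisition_settings(),
                                    plate_id = "P01", well = NULL,
                                    force = FALSE) {
  cmds <- parse_job_script(job)
  well <- well %||% job$well
  if (is.null(well)) stop("job has no well", call. = FALSE)
  if (inherits(well, "well_address")) well <- format_well(well)
  verbs <- vapply(cmds, `[[`, "", "verb")
  if (!"GOTO" %in% verbs) stop("job script has no GOTO", call. = FALSE)
  goto <- cmds[[which(verbs == "GOTO")[1]]]
  stage <- c(goto$x, goto$y)
  ## channel list in acquisition order: SET_CHANNEL followed by STACK
  chans <- list(); nz <- settings$n_z; dz <- settings$dz_um
  cur <- NULL
  for (cmd in cmds) {
    if (cmd$verb == "SET_CHANNEL") cur <- cmd
    if (cmd$verb == "STACK" && !is.null(cur)) {
      chans[[length(chans) + 1L]] <- data.frame(
        name = cur$name, led_percent = cur$led_percent,
        exposure_ms = cur$exposure_ms)
      nz <- cmd$n_z; dz <- cmd$dz_um
    }
  }
  channels <- if (length(chans)) do.call(rbind, chans) else settings$channels
  s <- acquisition_settings(objective_mag = 10, n_z = nz, dz_um = dz,
                            autofocus_range_um = settings$autofocus_range_um,
                            channels = channels,
                            camera_px = settings$camera_px,
                            pixel_size_um = settings$pixel_size_um)
  res <- render_highres_stack(spec, well, stage, s)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (ch in channels$name) {
    stk <- if (ch == "GFP470") res$gfp else res$bf
    for (k in seq_len(length(stk))) {
      path <- file.path(out_dir, format_filename(plate_id, "rescan", well, ch,
                                                 k - 1L))
      write_tiff(stk$planes[[k]], path, force = force)
      files <- c(files, path)
    }
  }
  invisible(list(files = files, truth = res$truth, stage_um = stage))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the closed smart-acquisition loop over a pre-scan directory
#'
#' For every pre-scan overview: detect the pronephros, translate to stage
#' coordinates, write a job script, and execute it against the mock
#' microscope.  Blank detections produce no job.
#'
#' @param prescan_dir directory of pre-scan TIFFs (package convention).
#' @param scene the [make_plate_scene()] the mock microscope renders.
#' @param out_dir output root; jobs under `jobs/`, rescans under `rescan/`.
#' @param config a `ks_config`.
#' @param force overwrite existing rescan files.
#' @return data.frame per well: detection pixel/stage coordinates,
#'   foreground area, blank flag, job path, and (for executed jobs) the
#'   distance in um between the commanded centre and the true embryo
#'   centre.
#' @export
smart_acquire_plate <- function(prescan_dir, scene, out_dir,
                                config = default_config(), force = FALSE) {
  s4 <- settings_from_config(config, objective_mag = 4)
  s10 <- settings_from_config(config, objective_mag = 10)
  recs <- list_plate_dir(prescan_dir)
  recs <- recs[recs$scan_phase == "prescan" & recs$channel == "GFP470", ,
               drop = FALSE]
  if (nrow(recs) == 0L) stop("no prescan GFP470 files found", call. = FALSE)
  job_dir <- file.path(out_dir, "jobs")
  rescan_dir <- file.path(out_dir, "rescan")
  rows <- vector("list", nrow(recs))
  for (i in seq_len(nrow(recs))) {
    w <- recs$well[i]
    img <- read_tiff(recs$path[i])
    cal <- overview_calibration(w, s4)
    roi <- detect_pronephros_center(img, config, cal = cal, well = w)
    if (is.null(roi)) {
      rows[[i]] <- data.frame(well = w, blank = TRUE, px_x = NA_real_,
                              px_y = NA_real_, stage_x_um = NA_real_,
                              stage_y_um = NA_real_, foreground_area_px = 0L,
                              job_path = NA_character_, center_error_um = NA_real_,
                              stringsAsFactors = FALSE)
      next
    }
    job <- make_job_script(roi, s10)
    jp <- write_job_script(job, job_dir)
    job$path <- jp
    exec <- mock_microscope_execute(job, scene$wells[[w]], rescan_dir,
                                    settings = s10, plate_id = scene$plate_id,
                                    well = w, force = force)
    err <- sqrt(sum((exec$stage_um - scene$wells[[w]]$embryo_center_um)^2))
    rows[[i]] <- data.frame(well = w, blank = FALSE, px_x = roi$px[1],
                            px_y = roi$px[2], stage_x_um = roi$stage_um[1],
                            stage_y_um = roi$stage_um[2],
                            foreground_area_px = roi$foreground_area_px,
                            ## path relative to out_dir so run artifacts are
                            ## reproducible byte for byte across directories
                            job_path = file.path("jobs", basename(jp)),
                            center_error_um = err,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
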