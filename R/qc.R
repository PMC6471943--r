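## Image quality control: label each processed well ok, blurred or blank
## before phenotyping.
##
## Blur detection: population variance of the background-subtracted cropped
## projection; below the threshold means blurred.  Blank detection:
## population variance of the 3x3 Laplacian response; the published rule
## flags wells ABOVE the threshold as blank (the comparison direction is
## configurable -- on denoised data blanks give the LOWER Laplacian
## variance, and the calibration sweep selects the direction that actually
## separates labelled data).  Absolute variance thresholds are
## instrument-specific; calibrate before trusting them on new data.

#' Blur detection
#'
#' @param image cropped projection (counts matrix).
#' @param threshold variance threshold (blurred when strictly below).
#' @param background_radius rolling-ball disc radius, px.
#' @return list: `is_blurred`, `variance`.
#' @export
detect_blur <- function(image, threshold = 400, background_radius = 50) {
  v <- img_variance(subtract_background(image, background_radius)$image)
  list(is_blurred = v < threshold, variance = v)
}

#' Blank detection
#'
#' @param image cropped projection (counts matrix).
#' @param threshold Laplacian-variance threshold (strict comparison).
#' @param above if TRUE (published rule) blank when variance is above the
#'   threshold; if FALSE, below.
#' @return list: `is_blank`, `variance`.
#' @export
detect_blank <- function(image, threshold = 124, above = TRUE) {
  v <- img_variance(laplacian3x3(image))
  list(is_blank = if (above) v > threshold else v < threshold, variance = v)
}

#' Quality-control one processed well
#'
#' The blank test is applied first (so empty wells are never reported as
#' merely blurred), then the blur test.
#'
#' @param pw a `processed_well` (or a bare projection matrix).
#' @param config a `ks_config`.
#' @return one-row data.frame: `well`, `label` (ok | blurred | blank),
#'   `blur_variance`, `blank_variance`, thresholds used.
#' @export
qc_well <- function(pw, config = default_config()) {
  img <- if (inherits(pw, "processed_well")) pw$projection else pw
  well <- if (inherits(pw, "processed_well")) pw$well else NA_character_
  blank <- detect_blank(img, config$blank_threshold, config$blank_above)
  blur <- detect_blur(img, config$blur_threshold, config$background_radius)
  label <- if (blank$is_blank) "blank" else if (blur$is_blurred) "blurred" else "ok"
  data.frame(well = well, label = label,
             blur_variance = blur$variance, blank_variance = blank$variance,
             blur_threshold = config$blur_threshold,
             blank_threshold = config$blank_threshold,
             stringsAsFactors = FALSE)
}

#' Quality-control a whole plate
#'
#' @param processed named list of `processed_well` objects.
#' @param config a `ks_config`.
#' @param quiet suppress the per-class count message.
#' @return list with `records` (data.frame, one row per well) and `ok`
#'   (the processed wells that passed).
#' @export
qc_plate <- function(processed, config = default_config(), quiet = TRUE) {
  if (length(processed) == 0L) {
    return(list(records = data.frame(well = character(0), label = character(0),
                                     blur_variance = numeric(0),
                                     blank_variance = numeric(0),
                                     blur_threshold = numeric(0),
                                     blank_threshold = numeric(0)),
                ok = list()))
  }
  records <- do.call(rbind, lapply(processed, qc_well, config = config))
  rownames(records) <- NULL
  keep <- records$well[records$label == "ok"]
  if (!quiet) {
    tb <- table(factor(records$label, levels = c("ok", "blurred", "blank")))
    message(sprintf("qc: %d ok, %d blurred, %d blank",
                    tb[["ok"]], tb[["blurred"]], tb[["blank"]]))
  }
  list(records = records, ok = processed[keep])
}

#' Calibrate the QC thresholds on labelled images
#'
#' Sweeps candidate thresholds over the observed blur and blank statistics
#' of a labelled image set and returns the values (and, for the blank test,
#' the comparison direction) that maximise balanced accuracy.  Blur
#' calibration separates ok from blurred (blank wells excluded) and jointly
#' sweeps the rolling-ball radius: the ball must sit between the width of a
#' sharp structure (which it must strip completely from the background
#' estimate) and that of a defocus-spread one (which it must absorb), so
#' the radius is as data-dependent as the threshold itself.  Blank
#' calibration separates blank from everything else.
#'
#' @param images list of projection matrices (or `processed_well`s).
#' @param labels character vector: "ok", "blurred" or "blank".
#' @param config a `ks_config` (supplies the centre of the radius grid).
#' @param radii candidate rolling-ball radii; default a short grid around
#'   `config$background_radius`.
#' @return list: `blur_threshold`, `background_radius`, `blank_threshold`,
#'   `blank_above`, balanced accuracies, and the per-image statistics used
#'   (blur variances at the selected radius).
#' @export
calibrate_qc <- function(images, labels, config = default_config(),
                         radii = NULL) {
  stopifnot(length(images) == length(labels),
            all(labels %in% c("ok", "blurred", "blank")))
  ## the grid starts at the configured radius: a ball smaller than the
  ## structures it must preserve sits in a degenerate regime (structure
  ## leaks into the background estimate), so only equal-or-larger balls
  ## are candidates
  if (is.null(radii)) {
    radii <- unique(pmax(2L, as.integer(round(
      config$background_radius * c(1, 1.1, 1.2, 1.4)))))
  }
  imgs <- lapply(images, function(x)
    if (inherits(x, "processed_well")) x$projection else x)
  blank_v <- vapply(imgs, function(i) detect_blank(i)$variance, numeric(1))

  midpoints <- function(v) {
    s <- sort(unique(v))
    if (length(s) < 2L) return(s)
    (s[-1] + s[-length(s)]) / 2
  }
  ## blank: sweep threshold and direction, balanced accuracy blank vs rest
  is_blank <- labels == "blank"
  best <- list(acc = -1, thr = config$blank_threshold, above = config$blank_above)
  for (thr in midpoints(blank_v)) {
    for (above in c(TRUE, FALSE)) {
      call_blank <- if (above) blank_v > thr else blank_v < thr
      acc <- (mean(call_blank[is_blank]) + mean(!call_blank[!is_blank])) / 2
      if (acc > best$acc) best <- list(acc = acc, thr = thr, above = above)
    }
  }
  ## blur: ok vs blurred among non-blank wells, rule fixed as "below =
  ## blurred"; joint sweep over ball radius and threshold
  sel <- labels != "blank"
  is_blur <- labels[sel] == "blurred"
  best_b <- list(acc = -1, margin = -Inf, thr = config$blur_threshold,
                 radius = config$background_radius, blur_v = NULL)
  for (r in radii) {
    bv <- vapply(imgs, function(i)
      detect_blur(i, background_radius = r)$variance, numeric(1))
    bl <- bv[sel]
    r_best <- list(acc = -1, thr = NA_real_)
    for (thr in midpoints(bl)) {
      call_blur <- bl < thr
      acc <- (mean(call_blur[is_blur]) + mean(!call_blur[!is_blur])) / 2
      if (acc > r_best$acc) r_best <- list(acc = acc, thr = thr)
    }
    ## ties between radii break on the separation margin between the
    ## slowest ok well and the sharpest blurred well
    margin <- min(bl[!is_blur]) / max(max(bl[is_blur]), 1e-12)
    if (r_best$acc > best_b$acc ||
        (r_best$acc == best_b$acc && margin > best_b$margin)) {
      best_b <- list(acc = r_best$acc, margin = margin, thr = r_best$thr,
                     radius = r, blur_v = bv)
    }
  }
  list(blur_threshold = best_b$thr,
       background_radius = best_b$radius,
       blank_threshold = best$thr,
       blank_above = best$above,
       blur_balanced_accuracy = best_b$acc,
       blank_balanced_accuracy = best$acc,
       blur_variance = best_b$blur_v, blank_variance = blank_v,
       labels = labels)
}
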