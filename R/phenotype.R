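## Wild-type versus cystic classification of QC-passing wells.
##
## Primary vote: the horizontal mean-intensity profile of a bounding-box
## ROI around the segmented pronephros, checked for a run of (near-)zero
## values -- the dark lumen of a glomerular cyst interrupts the GFP signal.
## Confirmatory vote: best-fit ellipses of the mask's connected components;
## an intact wild-type pronephros is one elongated particle whose ellipse
## major axis exceeds 299 px (at 0.65 um/px), while a cyst splits the
## structure into shorter particles.  The final label is the common vote
## when the two agree and "ambiguous" otherwise.

#' Gaussian-blur + Li mask of the glomerular recrop
#'
#' @param recrop glomerular recrop (counts matrix).
#' @param blur_sigma Gaussian sigma in px before thresholding (default 2).
#' @return list: `mask` (logical), `threshold`, `area_fraction_pct`.
#' @export
prepare_binary <- function(recrop, blur_sigma = 2) {
  check_image(recrop)
  smoothed <- round(gaussian_blur(recrop, blur_sigma))
  smoothed[smoothed < 0] <- 0
  th <- li_threshold(smoothed)
  list(mask = th$mask, threshold = th$threshold,
       area_fraction_pct = 100 * mean(th$mask))
}

#' Bounding-box ROI around the segmented pronephros
#'
#' Union bounding box of the foreground, expanded by a margin fraction per
#' side (clamped to the image) so that both the fluorescent tissue and any
#' cystic gap fall inside.  Masks with 100% area fraction are inverted
#' first (the blank-exclusion branch of the published scheme).
#'
#' @param mask logical matrix from [prepare_binary()].
#' @param area_fraction foreground percentage of `mask`.
#' @param margin expansion fraction per side (default 0.15).
#' @return ROI as a list with 1-based inclusive matrix index ranges
#'   `row1`, `row2`, `col1`, `col2`.
#' @export
select_roi <- function(mask, area_fraction = 100 * mean(mask), margin = 0.15) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (area_fraction >= 100) mask <- !mask
  if (!any(mask)) stop("no foreground object in mask", call. = FALSE)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  dh <- round(margin * (rows[2] - rows[1] + 1L))
  dw <- round(margin * (cols[2] - cols[1] + 1L))
  list(row1 = max(1L, rows[1] - dh), row2 = min(nrow(mask), rows[2] + dh),
       col1 = max(1L, cols[1] - dw), col2 = min(ncol(mask), cols[2] + dw))
}

#' Horizontal mean-intensity profile of an ROI
#'
#' One value per ROI column: the mean intensity over the ROI's rows.
#' Applied to the denoised, background-subtracted grayscale image, not the
#' mask.
#'
#' @param image counts matrix.
#' @param roi ROI from [select_roi()].
#' @return numeric vector of length `roi$col2 - roi$col1 + 1`.
#' @export
horizontal_profile <- function(image, roi) {
  check_image(image)
  stopifnot(roi$row1 >= 1L, roi$row2 <= nrow(image), roi$col1 >= 1L,
            roi$col2 <= ncol(image))
  if (roi$row2 < roi$row1 || roi$col2 < roi$col1) {
    stop("degenerate ROI (zero width or height)", call. = FALSE)
  }
  colMeans(image[roi$row1:roi$row2, roi$col1:roi$col2, drop = FALSE])
}

#' Zero-run profile vote
#'
#' Cystic if the profile contains a run of values <= `epsilon` of length
#' >= `min_run` that is flanked by tissue-level signal on both sides: a
#' dark lumen interrupts the GFP profile between two bright humps.  Runs
#' touching either profile end, or bounded only by near-background noise
#' columns, are flanking background around the ROI margin, not a lumen,
#' and are ignored.  Tissue level is 5% of the profile maximum (at least
#' `epsilon`).
#'
#' @param profile numeric vector from [horizontal_profile()].
#' @param min_run minimum qualifying run length in columns (default 3).
#' @param epsilon value at or below which a column counts as zero
#'   (default 0).
#' @return list: `vote` ("wildtype" or "cystic"), `zero_run_length` (the
#'   longest qualifying zero run, 0 if none).
#' @export
profile_vote <- function(profile, min_run = 3L, epsilon = 0) {
  stopifnot(length(profile) >= 1L)
  tissue_level <- max(epsilon, 0.05 * max(profile))
  zero <- profile <= epsilon
  tissue <- profile > tissue_level
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run <- 0L
  for (j in which(r$values)) {
    before <- starts[j] > 1L && any(tissue[seq_len(starts[j] - 1L)])
    after <- ends[j] < length(profile) &&
      any(tissue[(ends[j] + 1L):length(profile)])
    if (before && after) run <- max(run, r$lengths[j])
  }
  list(vote = if (run >= min_run) "cystic" else "wildtype",
       zero_run_length = as.integer(run))
}

#' Best-fit ellipses of mask particles
#'
#' Per 8-connected component: the ellipse with the component's centroid and
#' second central moments (with the 1/12 single-pixel variance term), axes
#' rescaled so the ellipse area equals the component pixel area -- the
#' standard particle-analysis ellipse.  Axis lengths are full axes in
#' pixels.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @param connectivity 4 or 8.
#' @return data.frame: `particle` (raster-order id), `area`,
#'   `major_axis_px`, `minor_axis_px`, `centroid_x`, `centroid_y` (0-based).
#' @export
fit_particle_ellipses <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("no foreground object in mask", call. = FALSE)
  lab <- label_components(mask, connectivity)
  comps <- component_stats(lab)
  rows <- lapply(comps, function(cm) {
    x <- cm$pixels[, 1]; y <- cm$pixels[, 2]
    n <- cm$area
    mxx <- mean((x - mean(x))^2) + 1 / 12
    myy <- mean((y - mean(y))^2) + 1 / 12
    mxy <- mean((x - mean(x)) * (y - mean(y)))
    tr <- mxx + myy
    det_ <- mxx * myy - mxy^2
    disc <- sqrt(max(0, (tr / 2)^2 - det_))
    l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
    a0 <- 2 * sqrt(l1); b0 <- 2 * sqrt(l2)
    s <- sqrt(n / (pi * a0 * b0))           # area normalisation
    data.frame(particle = cm$id, area = n,
               major_axis_px = 2 * a0 * s, minor_axis_px = 2 * b0 * s,
               centroid_x = cm$centroid[1], centroid_y = cm$centroid[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ellipse confirmatory vote
#'
#' Selects the particle with the largest ellipse major axis (ties: larger
#' area, then lower raster id); wildtype iff that axis is strictly greater
#' than the threshold.
#'
#' @param ellipses data.frame from [fit_particle_ellipses()].
#' @param axis_threshold major-axis threshold in px (default 299).
#' @return list: `vote`, `largest_major_axis_px`.
#' @export
ellipse_vote <- function(ellipses, axis_threshold = 299) {
  stopifnot(is.data.frame(ellipses), nrow(ellipses) >= 1L)
  ord <- order(-ellipses$major_axis_px, -ellipses$area, ellipses$particle)
  big <- ellipses[ord[1], ]
  list(vote = if (big$major_axis_px > axis_threshold) "wildtype" else "cystic",
       largest_major_axis_px = big$major_axis_px)
}

#' Classify one processed well
#'
#' Runs the zero-run profile vote and the ellipse confirmatory vote; the
#' label is their common value when they agree and "ambiguous" otherwise.
#'
#' @param pw a `processed_well` that passed QC.
#' @param config a `ks_config`.
#' @return one-row data.frame: `well`, `label` (wildtype | cystic |
#'   ambiguous), `profile_vote`, `ellipse_vote`, `zero_run_length`,
#'   `largest_major_axis_px`, `area_fraction_pct`.
#' @export
classify_well <- function(pw, config = default_config()) {
  stopifnot(inherits(pw, "processed_well"))
  prep <- prepare_binary(pw$recrop, config$phenotype_blur_sigma)
  roi <- select_roi(prep$mask, prep$area_fraction_pct, config$roi_margin)
  gray <- subtract_background(pw$recrop, config$background_radius)$image
  prof <- horizontal_profile(gray, roi)
  pv <- profile_vote(prof, config$profile_min_run, config$profile_epsilon)
  ell <- fit_particle_ellipses(prep$mask, config$connectivity)
  ev <- ellipse_vote(ell, config$axis_threshold_px)
  label <- if (pv$vote == ev$vote) pv$vote else "ambiguous"
  data.frame(well = pw$well, label = label,
             profile_vote = pv$vote, ellipse_vote = ev$vote,
             zero_run_length = pv$zero_run_length,
             largest_major_axis_px = ev$largest_major_axis_px,
             area_fraction_pct = prep$area_fraction_pct,
             stringsAsFactors = FALSE)
}

#' Classify every QC-passing well of a plate
#'
#' @param processed named list of `processed_well`s (QC survivors).
#' @param config a `ks_config`.
#' @param quiet suppress the summary message.
#' @return data.frame, one row per well (see [classify_well()]).
#' @export
classify_plate <- function(processed, config = default_config(), quiet = TRUE) {
  calls <- do.call(rbind, lapply(processed, classify_well, config = config))
  rownames(calls) <- NULL
  if (!quiet && !is.null(calls)) {
    tb <- table(factor(calls$label, levels = c("wildtype", "cystic", "ambiguous")))
    message(sprintf("phenotype: %d wildtype, %d cystic, %d ambiguous",
                    tb[["wildtype"]], tb[["cystic"]], tb[["ambiguous"]]))
  }
  calls
}
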