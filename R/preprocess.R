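## Reduce each rescan z-stack to one denoised, cropped maximum projection of
## the pronephric area plus its binary mask: focus detection, 7-slice
## sub-stack, per-plane denoising, maximum projection, centred 512x512 crop,
## glomerular recrop (height / 1.6) and Li auto-thresholding.
##
## All z indices are 0-based, matching the Z000-style file names.

#' Find the best-focused slice of a z-stack
#'
#' Argmax over planes of a focus metric: variance of the Laplacian-filtered
#' plane (default) or plain intensity variance.  Ties break to the lowest
#' index.
#'
#' @param stack a [zstack()].
#' @param metric "laplacian" or "variance".
#' @return 0-based plane index.
#' @export
find_focused_slice <- function(stack, metric = c("laplacian", "variance")) {
  stopifnot(inherits(stack, "zstack"), length(stack) >= 1L)
  metric <- match.arg(metric)
  score <- vapply(stack$planes, function(p) {
    if (metric == "laplacian") img_variance(laplacian3x3(p)) else img_variance(p)
  }, numeric(1))
  which.max(score) - 1L
}

#' Extract a fixed-size sub-stack around a centre slice
#'
#' Keeps `size` consecutive planes centred on `center_index`; when the
#' window would overrun either end of the stack it is clamped so exactly
#' `size` planes are always returned.
#'
#' @param stack a [zstack()].
#' @param center_index 0-based centre plane.
#' @param size odd window length (default 7).
#' @return a [zstack()] of `size` planes.
#' @export
extract_substack <- function(stack, center_index, size = 7L) {
  stopifnot(inherits(stack, "zstack"))
  size <- as.integer(size)
  if (size %% 2L != 1L) stop("size must be odd", call. = FALSE)
  n <- length(stack)
  if (n < size) {
    stop(sprintf("stack has %d plane(s); need at least %d", n, size), call. = FALSE)
  }
  stopifnot(center_index >= 0L, center_index < n)
  half <- (size - 1L) %/% 2L
  start <- min(max(center_index - half, 0L), n - size)   # 0-based
  zstack(stack$planes[(start + 1L):(start + size)], dz_um = stack$dz_um,
         pixel_size_um = stack$pixel_size_um, channel = stack$channel)
}

#' Maximum intensity projection
#'
#' @param stack a [zstack()].
#' @return matrix of per-pixel maxima over all planes.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "zstack"), length(stack) >= 1L)
  Reduce(pmax, stack$planes)
}

#' Denoise a plane
#'
#' @param img counts matrix.
#' @param method "median" (3x3 median filter) or "none".
#' @return filtered matrix.
#' @export
denoise <- function(img, method = c("median", "none")) {
  method <- match.arg(method)
  if (method == "none") return(img)
  median3x3(img)
}

#' Centred square crop
#'
#' @param img matrix at least `size` in each dimension.
#' @param size crop edge, pixels (default 512).
#' @return the centred `size` x `size` window.
#' @export
center_crop <- function(img, size = 512L) {
  check_image(img)
  size <- as.integer(size)
  if (nrow(img) < size || ncol(img) < size) {
    stop(sprintf(paste("image is %dx%d but the crop needs %dx%d;",
                       "check the pixel-size calibration"),
                 nrow(img), ncol(img), size, size), call. = FALSE)
  }
  r0 <- (nrow(img) - size) %/% 2L
  c0 <- (ncol(img) - size) %/% 2L
  img[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size), drop = FALSE]
}

#' Glomerular recrop
#'
#' Keeps the full width but reduces the height by `factor` (vertically
#' centred), isolating the glomerular and tubular band: 512 -> round(512 /
#' 1.6) = 320 rows.
#'
#' @param img the square centre crop.
#' @param factor height reduction factor (default 1.6).
#' @return recropped matrix.
#' @export
glomerular_recrop <- function(img, factor = 1.6) {
  check_image(img)
  stopifnot(factor >= 1)
  h <- as.integer(round(nrow(img) / factor))
  r0 <- (nrow(img) - h) %/% 2L
  img[(r0 + 1L):(r0 + h), , drop = FALSE]
}

#' Li minimum cross-entropy threshold
#'
#' Exhaustive minimisation of the cross entropy between the image and its
#' binarised version over all integer thresholds (computed on values + 1 so
#' zero-valued backgrounds are well defined).  Foreground is strictly above
#' the returned threshold.
#'
#' @param img counts matrix with at least two distinct values.
#' @return list with `mask` (logical matrix) and `threshold` (numeric, on
#'   the original intensity scale).
#' @export
li_threshold <- function(img) {
  check_image(img)
  v <- as.integer(round(as.numeric(img)))
  if (min(v) < 0L) stop("negative intensities", call. = FALSE)
  g <- v + 1L                                  # work on values >= 1
  if (min(g) == max(g)) {
    stop("constant image cannot be thresholded", call. = FALSE)
  }
  h <- tabulate(g, nbins = max(g))
  vals <- seq_along(h)
  n_cum <- cumsum(h)
  s_cum <- cumsum(h * vals)
  n <- n_cum[length(n_cum)]
  s <- s_cum[length(s_cum)]
  ## candidate thresholds: both classes non-empty
  cand <- which(n_cum > 0L & n_cum < n)
  mu0 <- s_cum[cand] / n_cum[cand]
  mu1 <- (s - s_cum[cand]) / (n - n_cum[cand])
  ce <- -(s_cum[cand] * log(mu0) + (s - s_cum[cand]) * log(mu1))
  t_shift <- cand[which.min(ce)]               # lowest index on ties
  threshold <- t_shift - 1L                    # back to original scale
  list(mask = matrix(v > threshold, nrow(img), ncol(img)),
       threshold = as.numeric(threshold))
}

#' Process one well's GFP rescan stack
#'
#' Focus detection, sub-stack extraction, per-plane denoising, maximum
#' projection, centred crop, glomerular recrop and Li masking.  Every step
#' records itself (with parameters) in the provenance list, so identical
#' inputs and configuration reproduce bit-identical outputs.
#'
#' @param stack the GFP470 rescan [zstack()].
#' @param config a `ks_config`.
#' @param well canonical well string recorded in the result.
#' @return object of class `processed_well`: `well`, `projection` (the
#'   square crop), `recrop`, `mask`, `threshold`, `focus_index` (0-based),
#'   `pixel_size_um`, `provenance`.
#' @export
process_well <- function(stack, config = default_config(), well = NA_character_) {
  stopifnot(inherits(stack, "zstack"))
  prov <- list()
  note <- function(step, ...) {
    prov[[length(prov) + 1L]] <<- c(list(step = step), list(...))
  }
  focus <- find_focused_slice(stack, config$focus_metric)
  note("find_focused_slice", metric = config$focus_metric, index = focus)
  sub <- if (length(stack) >= config$substack_size) {
    extract_substack(stack, focus, config$substack_size)
  } else stack
  note("extract_substack", size = length(sub))
  planes <- lapply(sub$planes, denoise, method = config$denoise_method)
  note("denoise", method = config$denoise_method)
  proj <- max_project(zstack(planes, sub$dz_um, sub$pixel_size_um, sub$channel))
  note("max_project", planes = length(planes))
  crop <- center_crop(proj, config$crop_px)
  note("center_crop", size = config$crop_px)
  recrop <- glomerular_recrop(crop, config$recrop_factor)
  note("glomerular_recrop", factor = config$recrop_factor,
       height = nrow(recrop))
  th <- tryCatch(li_threshold(recrop), error = function(e) NULL)
  note("li_threshold", threshold = if (is.null(th)) NA else th$threshold)
  structure(list(well = well,
                 projection = crop,
                 recrop = recrop,
                 mask = if (is.null(th)) matrix(FALSE, nrow(recrop), ncol(recrop))
                        else th$mask,
                 threshold = if (is.null(th)) NA_real_ else th$threshold,
                 focus_index = focus,
                 pixel_size_um = stack$pixel_size_um,
                 provenance = prov),
            class = "processed_well")
}

#' @export
print.processed_well <- function(x, ...) {
  cat(sprintf("<processed_well %s: %dx%d projection, focus z=%d>\n",
              x$well, nrow(x$projection), ncol(x$projection), x$focus_index))
  invisible(x)
}

#' Process every well of a rescan directory
#'
#' Assembles the GFP470 rescan stack of each well present and reduces it
#' with [process_well()]: a full plate of single-plane files becomes exactly
#' one processed image per well.
#'
#' @param dir rescan directory (package filename convention).
#' @param config a `ks_config`.
#' @param quiet suppress per-well progress messages.
#' @return named list of `processed_well` objects.
#' @export
process_plate <- function(dir, config = default_config(), quiet = TRUE) {
  recs <- list_plate_dir(dir)
  recs <- recs[recs$scan_phase == "rescan", , drop = FALSE]
  wells <- sort(unique(recs$well[recs$channel == "GFP470"]))
  if (length(wells) == 0L) stop("no processed wells found: no rescan GFP470 files",
                                call. = FALSE)
  out <- vector("list", length(wells))
  names(out) <- wells
  for (w in wells) {
    stk <- assemble_stack(recs, w, "GFP470", "rescan",
                          dz_um = config$dz_um,
                          pixel_size_um = config$pixel_size_10x_um)
    out[[w]] <- process_well(stk, config, well = w)
    if (!quiet) message(sprintf("preprocess: %s (%d planes)", w, length(stk)))
  }
  out
}

#' Write a processed well to disk
#'
#' Projection, recrop and mask TIFFs plus a JSON provenance sidecar.
#'
#' @param pw a `processed_well`.
#' @param dir output directory.
#' @param force overwrite.
#' @return invisible vector of written paths.
#' @export
write_processed_well <- function(pw, dir, force = FALSE) {
  stopifnot(inherits(pw, "processed_well"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    projection = file.path(dir, sprintf("%s_projection.tif", pw$well)),
    recrop = file.path(dir, sprintf("%s_recrop.tif", pw$well)),
    mask = file.path(dir, sprintf("%s_mask.tif", pw$well)),
    provenance = file.path(dir, sprintf("%s_provenance.json", pw$well)))
  write_tiff(pw$projection, paths[["projection"]], force = force)
  write_tiff(pw$recrop, paths[["recrop"]], force = force)
  write_tiff(pw$mask * 65535, paths[["mask"]], force = force)
  jsonlite::write_json(list(well = pw$well, focus_index = pw$focus_index,
                            threshold = pw$threshold,
                            pixel_size_um = pw$pixel_size_um,
                            provenance = pw$provenance),
                       paths[["provenance"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read back a processed well written by [write_processed_well()]
#'
#' @param dir directory holding the per-well files.
#' @param well canonical well string.
#' @return a `processed_well`.
#' @export
read_processed_well <- function(dir, well) {
  meta <- jsonlite::read_json(file.path(dir, sprintf("%s_provenance.json", well)),
                              simplifyVector = TRUE)
  structure(list(well = well,
                 projection = read_tiff(file.path(dir, sprintf("%s_projection.tif", well))),
                 recrop = read_tiff(file.path(dir, sprintf("%s_recrop.tif", well))),
                 mask = read_tiff(file.path(dir, sprintf("%s_mask.tif", well))) > 0,
                 threshold = meta$threshold,
                 focus_index = meta$focus_index,
                 pixel_size_um = meta$pixel_size_um,
                 provenance = meta$provenance),
            class = "processed_well")
}
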