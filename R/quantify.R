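## Morphometric quantification: pronephric tissue area, cystic lumen area
## (background particles enclosed by the convex hull of the tissue,
## filtered by Feret diameter and particle number), total kidney area by
## phenotype, and plate-level summaries.

#' Convex hull (monotone chain)
#'
#' @param points n x 2 numeric matrix of (x, y) points.
#' @return hull vertices in counter-clockwise order (y axis pointing down
#'   gives clockwise on screen), one row per vertex, no repetition.
#'   Collinear sets return the two extreme points; a single point returns
#'   itself.
#' @export
convex_hull <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2L, nrow(points) >= 1L)
  ## only the per-x vertical extremes can be hull vertices; this reduction
  ## keeps the sequential chain scan short on large pixel sets
  o <- order(points[, 1], points[, 2])
  x <- points[o, 1]; y <- points[o, 2]
  keep <- !duplicated(x) | !duplicated(x, fromLast = TRUE)
  px <- x[keep]; py <- y[keep]
  dup <- duplicated(cbind(px, py))
  px <- px[!dup]; py <- py[!dup]
  n <- length(px)
  if (n <= 2L) return(cbind(px, py, deparse.level = 0))
  build <- function(idx) {
    h <- integer(0); top <- 0L
    for (i in idx) {
      while (top >= 2L) {
        a <- h[top - 1L]; b <- h[top]
        if ((px[b] - px[a]) * (py[i] - py[a]) -
            (py[b] - py[a]) * (px[i] - px[a]) <= 0) top <- top - 1L else break
      }
      top <- top + 1L
      h[top] <- i
    }
    h[seq_len(top)]
  }
  lower <- build(seq_len(n))
  upper <- build(rev(seq_len(n)))
  cbind(px[c(lower[-length(lower)], upper[-length(upper)])],
        py[c(lower[-length(lower)], upper[-length(upper)])], deparse.level = 0)
}

#' Corner points of a set of pixels
#'
#' Each pixel centred at 0-based (x, y) contributes its four corners
#' (x +/- 0.5, y +/- 0.5); duplicates are removed.
#'
#' @param pixels n x 2 matrix of 0-based pixel centres.
#' @return m x 2 matrix of corner coordinates.
#' @export
pixel_corners <- function(pixels) {
  stopifnot(is.matrix(pixels), ncol(pixels) == 2L)
  x <- pixels[, 1]; y <- pixels[, 2]
  cx <- c(x - 0.5, x - 0.5, x + 0.5, x + 0.5)
  cy <- c(y - 0.5, y + 0.5, y - 0.5, y + 0.5)
  ## corners sit on the half-integer grid: dedupe via integer keys
  key <- (round(2 * cx) - 2 * min(round(2 * cx))) * (diff(range(round(2 * cy))) + 3) +
    round(2 * cy)
  keep <- !duplicated(key)
  cbind(cx[keep], cy[keep], deparse.level = 0)
}

#' Feret (maximum caliper) diameter
#'
#' Maximum pairwise distance between convex-hull vertices of the pixel
#' corner points: a single pixel has Feret sqrt(2).
#'
#' @param pixels n x 2 matrix of 0-based pixel centres.
#' @return numeric Feret diameter in pixels.
#' @export
feret_diameter <- function(pixels) {
  h <- convex_hull(pixel_corners(pixels))
  if (nrow(h) == 1L) return(0)
  d2 <- outer(h[, 1], h[, 1], `-`)^2 + outer(h[, 2], h[, 2], `-`)^2
  sqrt(max(d2))
}

#' Test whether points lie inside a convex polygon
#'
#' @param points n x 2 matrix.
#' @param hull convex polygon vertices in order (from [convex_hull()]).
#' @param tol boundary tolerance; points within `tol` of an edge count as
#'   inside.
#' @return logical vector.
#' @export
points_in_hull <- function(points, hull, tol = 1e-9) {
  stopifnot(is.matrix(points), ncol(points) == 2L)
  if (nrow(hull) < 3L) return(rep(FALSE, nrow(points)))
  inside <- rep(TRUE, nrow(points))
  m <- nrow(hull)
  for (i in seq_len(m)) {
    a <- hull[i, ]; b <- hull[if (i == m) 1L else i + 1L, ]
    s <- (b[1] - a[1]) * (points[, 2] - a[2]) - (b[2] - a[2]) * (points[, 1] - a[1])
    inside <- inside & s >= -tol
  }
  inside
}

#' Pronephric tissue area
#'
#' Sums the areas of mask particles that pass the position, size and
#' morphology filters: area at least `min_area`, centroid within the
#' central band of the image width, circularity within bounds.
#'
#' @param mask logical matrix (glomerular recrop mask).
#' @param config a `ks_config`.
#' @return list: `area_px2`, `audit` data.frame (particle, area, feret,
#'   circularity, centroid, kept).
#' @export
pronephric_area <- function(mask, config = default_config()) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) {
    return(list(area_px2 = 0,
                audit = data.frame(particle = integer(0), area = numeric(0),
                                   feret = numeric(0), circularity = numeric(0),
                                   kept = logical(0))))
  }
  lab <- label_components(mask, config$connectivity)
  comps <- component_stats(lab)
  band <- (1 - config$central_band) / 2 * ncol(mask)
  lo <- band - 0.5; hi <- ncol(mask) - band - 0.5       # 0-based centre bounds
  rows <- lapply(comps, function(cm) {
    per <- component_perimeter(lab, cm$id)
    circ <- 4 * pi * cm$area / per^2
    kept <- cm$area >= config$min_particle_area_px2 &&
      cm$centroid[1] >= lo && cm$centroid[1] <= hi &&
      circ >= config$circularity_min && circ <= config$circularity_max
    data.frame(particle = cm$id, area = cm$area, feret = feret_diameter(cm$pixels),
               circularity = circ, kept = kept)
  })
  audit <- do.call(rbind, rows)
  list(area_px2 = sum(audit$area[audit$kept]), audit = audit)
}

#' Cystic lumen area
#'
#' Builds the convex hull of all foreground pixels, inverts the mask within
#' the hull (the hull boundary separates cystic from general background),
#' numbers the enclosed particles (area-descending by default,
#' raster-scan order via `particle_order = "raster"`), and sums those with
#' number <= `particle_index_max` and Feret diameter >= `feret_min`.  A
#' convex solid mask therefore measures exactly 0.
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @param config a `ks_config`.
#' @return list: `area_px2`, `audit` data.frame (particle, area, feret,
#'   kept), `hull` vertices.
#' @export
cystic_area <- function(mask, config = default_config()) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (!any(mask)) stop("no foreground object in mask", call. = FALSE)
  pos <- which(mask)
  fg <- cbind((pos - 1L) %/% nrow(mask), (pos - 1L) %% nrow(mask))  # (x, y)
  hull <- convex_hull(pixel_corners(fg))
  ## the hull boundary separates cystic background from the outer
  ## background: restrict the inverted mask to pixel centres inside the
  ## hull before labelling, so every resulting particle is enclosed
  xr <- floor(min(hull[, 1])):ceiling(max(hull[, 1]))
  yr <- floor(min(hull[, 2])):ceiling(max(hull[, 2]))
  xr <- xr[xr >= 0 & xr < ncol(mask)]
  yr <- yr[yr >= 0 & yr < nrow(mask)]
  in_hull <- matrix(FALSE, nrow(mask), ncol(mask))
  grid <- cbind(rep(xr, each = length(yr)), rep(yr, times = length(xr)))
  in_hull[cbind(grid[, 2] + 1L, grid[, 1] + 1L)] <- points_in_hull(grid, hull)
  lab <- label_components(!mask & in_hull, config$connectivity)
  interior <- component_stats(lab)
  if (length(interior) == 0L) {
    return(list(area_px2 = 0,
                audit = data.frame(particle = integer(0), area = numeric(0),
                                   feret = numeric(0), kept = logical(0)),
                hull = hull))
  }
  ## particle numbering: area-descending by default, so the large cystic
  ## particles receive the low numbers the index filter keeps; raster-scan
  ## numbering (sequential top-left to bottom-right) is the config
  ## alternative
  ord <- if (identical(config$particle_order, "raster")) seq_along(interior)
         else order(-vapply(interior, `[[`, 0L, "area"),
                    vapply(interior, `[[`, 0L, "id"))
  rows <- lapply(seq_along(ord), function(i) {
    cm <- interior[[ord[i]]]
    fer <- feret_diameter(cm$pixels)
    data.frame(particle = i, area = cm$area, feret = fer,
               kept = i <= config$particle_index_max && fer >= config$feret_min_px)
  })
  audit <- do.call(rbind, rows)
  list(area_px2 = sum(audit$area[audit$kept]), audit = audit, hull = hull)
}

#' Total kidney area of one well
#'
#' Wild-type wells are allocated the pronephric area as their total kidney
#' area; cystic wells the sum of pronephric and cystic areas.  Ambiguous
#' wells are skipped (NULL) unless the configuration includes them, in
#' which case they are measured under the cystic (sum) rule.
#'
#' @param call one-row phenotype data.frame from [classify_well()].
#' @param pron_px2 pronephric area, px^2.
#' @param cyst_px2 cystic area, px^2.
#' @param pixel_size_um lateral pixel size for the um^2 conversion.
#' @param config a `ks_config`.
#' @return one-row data.frame of areas in px^2 and um^2, or NULL (skip).
#' @export
total_kidney_area <- function(call, pron_px2, cyst_px2, pixel_size_um = 0.65,
                              config = default_config()) {
  label <- call$label
  if (label == "ambiguous" && !config$include_ambiguous) return(NULL)
  total <- switch(label,
                  wildtype = pron_px2,
                  cystic = pron_px2 + cyst_px2,
                  ambiguous = pron_px2 + cyst_px2)
  cyst_counted <- if (label == "wildtype") 0 else cyst_px2
  um2 <- pixel_size_um^2
  data.frame(well = call$well, label = label,
             pronephric_area_px2 = pron_px2, cystic_area_px2 = cyst_counted,
             total_kidney_area_px2 = total,
             pronephric_area_um2 = pron_px2 * um2,
             cystic_area_um2 = cyst_counted * um2,
             total_kidney_area_um2 = total * um2,
             stringsAsFactors = FALSE)
}

#' Measure one classified well
#'
#' @param pw the `processed_well`.
#' @param call its phenotype call.
#' @param config a `ks_config`.
#' @return one-row measurement data.frame, or NULL for skipped wells.
#' @export
measure_well <- function(pw, call, config = default_config()) {
  prep <- prepare_binary(pw$recrop, config$phenotype_blur_sigma)
  pron <- pronephric_area(prep$mask, config)
  cyst <- if (call$label == "wildtype") list(area_px2 = 0)
          else cystic_area(prep$mask, config)
  total_kidney_area(call, pron$area_px2, cyst$area_px2,
                    pixel_size_um = pw$pixel_size_um, config = config)
}

#' Plate summary matrix, CSV and heatmap
#'
#' @param measurements data.frame of per-well measurements.
#' @param out_dir optional directory; when given, writes
#'   `plate_matrix.csv` and `plate_heatmap.png`.
#' @param value column to summarise (default total kidney area in um^2).
#' @return 8 x 12 matrix (rows A-H); wells without a measurement are NA.
#' @export
plate_summary <- function(measurements, out_dir = NULL,
                          value = "total_kidney_area_um2") {
  if (anyDuplicated(measurements$well)) {
    stop("duplicate wells in measurements", call. = FALSE)
  }
  mat <- matrix(NA_real_, 8, 12, dimnames = list(PLATE_ROWS, sprintf("%02d", PLATE_COLS)))
  for (i in seq_len(nrow(measurements))) {
    w <- parse_well(measurements$well[i])
    mat[w$row, w$column] <- measurements[[value]][i]
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(mat, file.path(out_dir, "plate_matrix.csv"))
    plot_plate_heatmap(mat, file.path(out_dir, "plate_heatmap.png"),
                       main = value)
  }
  mat
}

#' Render a plate heatmap PNG
#'
#' 8 x 12 grid with row letters and column numbers; wells without a value
#' are drawn grey.
#'
#' @param mat 8 x 12 matrix from [plate_summary()].
#' @param path output PNG path.
#' @param main plot title.
#' @return `path`, invisibly.
#' @export
plot_plate_heatmap <- function(mat, path, main = "total kidney area") {
  grDevices::png(path, width = 900, height = 640)
  on.exit(grDevices::dev.off())
  pal <- grDevices::hcl.colors(64, "viridis")
  z <- t(mat)[, rev(seq_len(8)), drop = FALSE]       # row A at the top
  graphics::par(mar = c(3, 3, 3, 6))
  graphics::image(x = 1:12, y = 1:8, z = z, col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = main)
  if (anyNA(z)) {
    na_idx <- which(is.na(z), arr.ind = TRUE)
    graphics::rect(na_idx[, 1] - 0.5, na_idx[, 2] - 0.5,
                   na_idx[, 1] + 0.5, na_idx[, 2] + 0.5,
                   col = "grey80", border = NA)
  }
  graphics::axis(1, at = 1:12, labels = 1:12, tick = FALSE)
  graphics::axis(2, at = 1:8, labels = rev(PLATE_ROWS), las = 1, tick = FALSE)
  graphics::box()
  rng <- range(mat, na.rm = TRUE)
  if (all(is.finite(rng))) {
    graphics::mtext(sprintf("range %.0f - %.0f", rng[1], rng[2]), side = 4,
                    line = 1)
  }
  invisible(path)
}
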