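## Independent brute-force oracles and small scene helpers shared across
## the test files.  Oracles deliberately re-derive each quantity by the
## most literal method available (double loops, O(n^3) geometry) so they
## share no code path with the implementation they check.

## configuration scaled for test-size frames: same physics and thresholds
## as the full-scale defaults, smaller camera
test_config <- function(...) {
  build_config(list(prescan_camera_px = 512L, rescan_camera_px = 512L,
                    n_z = 7L, ...))
}

## brute-force intensity-weighted centre of mass over foreground pixels
bf_center_of_mass <- function(img, mask) {
  sx <- sy <- sw <- 0
  for (r in seq_len(nrow(img))) for (c in seq_len(ncol(img))) {
    if (mask[r, c]) {
      w <- img[r, c]
      sx <- sx + (c - 1) * w
      sy <- sy + (r - 1) * w
      sw <- sw + w
    }
  }
  c(sx, sy) / sw
}

## O(n^3) convex hull: an ordered pair (i, j) is a hull edge iff every
## other point lies strictly to its left (or on the segment); vertices are
## collected from the edges
bf_hull_vertices <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n <= 2L) return(pts[order(pts[, 1], pts[, 2]), , drop = FALSE])
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- pts[i, ]; b <- pts[j, ]
    side <- (b[1] - a[1]) * (pts[, 2] - a[2]) - (b[2] - a[2]) * (pts[, 1] - a[1])
    if (all(side >= -1e-12)) { on_hull[i] <- TRUE; on_hull[j] <- TRUE }
  }
  v <- pts[on_hull, , drop = FALSE]
  ## drop collinear interior points: keep only points that are vertices
  ## (strictly outside the hull of the others)
  keep <- rep(TRUE, nrow(v))
  for (k in seq_len(nrow(v))) {
    others <- v[-k, , drop = FALSE]
    if (nrow(others) >= 3L) {
      h <- grDevices::chull(others)
      inside <- all(point_left_of_all(v[k, ], others[h, , drop = FALSE]))
      if (inside) keep[k] <- FALSE
    }
  }
  v <- v[keep, , drop = FALSE]
  v[order(v[, 1], v[, 2]), , drop = FALSE]
}

point_left_of_all <- function(p, hull_ccw) {
  ## hull from chull is clockwise in standard orientation; test both signs
  m <- nrow(hull_ccw)
  s <- numeric(m)
  for (i in seq_len(m)) {
    a <- hull_ccw[i, ]; b <- hull_ccw[if (i == m) 1L else i + 1L, ]
    s[i] <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
  }
  all(s >= 1e-12) | all(s <= -1e-12)
}

## double-loop second-moment ellipse of one pixel set (0-based x, y)
bf_ellipse_axes <- function(pixels) {
  n <- nrow(pixels)
  mx <- sum(pixels[, 1]) / n
  my <- sum(pixels[, 2]) / n
  sxx <- sxy <- syy <- 0
  for (k in seq_len(n)) {
    dx <- pixels[k, 1] - mx; dy <- pixels[k, 2] - my
    sxx <- sxx + dx * dx; sxy <- sxy + dx * dy; syy <- syy + dy * dy
  }
  mxx <- sxx / n + 1 / 12; myy <- syy / n + 1 / 12; mxy <- sxy / n
  tr <- mxx + myy; det_ <- mxx * myy - mxy^2
  disc <- sqrt(max(0, (tr / 2)^2 - det_))
  a0 <- 2 * sqrt(tr / 2 + disc); b0 <- 2 * sqrt(max(tr / 2 - disc, 1e-12))
  s <- sqrt(n / (pi * a0 * b0))
  c(major = as.numeric(2 * a0 * s), minor = as.numeric(2 * b0 * s))
}

## iterative minimum cross-entropy threshold (Li & Tam 1998): independent
## algorithmic route to the same objective the implementation minimises
## exhaustively
li_iterative <- function(img) {
  v <- as.numeric(img) + 1
  t_old <- -Inf
  t_new <- mean(v)
  while (abs(t_new - t_old) > 0.5) {
    t_old <- t_new
    m0 <- mean(v[v <= t_old]); m1 <- mean(v[v > t_old])
    t_new <- (m0 - m1) / (log(m0) - log(m1))
  }
  t_new - 1
}

## render one focused plane of a well and preprocess it
quick_processed_well <- function(phenotype, well = "A01", gap = 50,
                                 tilt = 0, seed = 1L, config = test_config(),
                                 n_z = 1L, center_offset = c(0, 0), ...) {
  s10 <- settings_from_config(config, 10)
  s10$n_z <- as.integer(n_z)
  wc <- well_center_um(well)
  spec <- scene_spec(phenotype, embryo_center_um = wc + center_offset,
                     orientation_deg = tilt,
                     cyst_gap_um = if (phenotype == "cystic") gap else 0,
                     seed = seed, ...)
  st <- render_highres_stack(spec, well, wc, s10)
  list(pw = process_well(st$gfp, config, well), truth = st$truth, spec = spec)
}

## filled disc / axis-aligned ellipse masks (0-based centre coordinates)
disc_mask <- function(radius, pad = 4L) {
  n <- 2L * (radius + pad) + 1L
  cx <- radius + pad
  xy <- expand.grid(y = 0:(n - 1L), x = 0:(n - 1L))
  matrix((xy$x - cx)^2 + (xy$y - cx)^2 <= radius^2, n, n)
}

ellipse_mask <- function(a, b, pad = 4L) {
  nx <- 2L * (a + pad) + 1L; ny <- 2L * (b + pad) + 1L
  cx <- a + pad; cy <- b + pad
  xy <- expand.grid(y = 0:(ny - 1L), x = 0:(nx - 1L))
  matrix(((xy$x - cx) / a)^2 + ((xy$y - cy) / b)^2 <= 1, ny, nx)
}
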