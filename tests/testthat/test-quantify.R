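test_that("monotone-chain hull matches the O(n^3) brute-force oracle", {
  set.seed(55)
  for (i in 1:200) {
    n <- sample(3:25, 1)
    pts <- matrix(round(runif(2 * n, 0, 20), 3), ncol = 2)
    mine <- convex_hull(pts)
    mine <- mine[order(mine[, 1], mine[, 2]), , drop = FALSE]
    oracle <- bf_hull_vertices(pts)
    expect_equal(mine, oracle, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("hull handles degenerate inputs", {
  seg <- convex_hull(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3)))
  expect_equal(nrow(seg), 2L)
  expect_equal(seg, rbind(c(0, 0), c(3, 3)), ignore_attr = TRUE)
  one <- convex_hull(matrix(c(2, 5), 1, 2))
  expect_equal(nrow(one), 1L)
})

test_that("Feret diameters follow closed-form geometry", {
  ## single pixel: its 4 corners give sqrt(2)
  expect_equal(feret_diameter(matrix(c(3, 4), 1, 2)), sqrt(2))
  ## 2x2 pixel square: corner to corner of a 2x2 square of pixels
  sq <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(feret_diameter(sq), 2 * sqrt(2))
  ## rasterised diameter-70 disc (pixel centres within 35 - 0.5 px, the
  ## half-pixel correction for corner-based calipers): Feret within 1 of 70
  d <- matrix(FALSE, 81, 81)
  xy <- expand.grid(y = 0:80, x = 0:80)
  d[] <- (xy$x - 40)^2 + (xy$y - 40)^2 <= 34.5^2
  pos <- which(d)
  pix <- cbind((pos - 1) %/% nrow(d), (pos - 1) %% nrow(d))
  expect_lt(abs(feret_diameter(pix) - 70), 1)
})

test_that("pronephric_area sums filtered particles", {
  cfg <- test_config()
  mask <- matrix(FALSE, 100, 200)
  mask[31:60, 41:140] <- TRUE              # 30 x 100 = 3000
  mask[71:100, 41:140] <- FALSE
  mask[66:95, 41:140] <- TRUE              # second lobe, 3000
  res <- pronephric_area(mask, cfg)
  expect_equal(res$area_px2, 6000)

  speck <- mask; speck[5, 5:14] <- TRUE    # 10 px noise speck
  res2 <- pronephric_area(speck, cfg)
  expect_equal(res2$area_px2, 6000)        # filtered by min area
  expect_equal(sum(!res2$audit$kept), 1L)

  empty <- pronephric_area(matrix(FALSE, 10, 10), cfg)
  expect_equal(empty$area_px2, 0)
  expect_equal(nrow(empty$audit), 0L)

  ## central-band position filter: a particle hugging the left edge drops
  offside <- matrix(FALSE, 100, 200)
  offside[40:60, 1:8] <- TRUE
  expect_equal(pronephric_area(offside, cfg)$area_px2, 0)
})

test_that("cystic_area keeps only enclosed particles above the Feret cut", {
  cfg <- test_config()
  ## solid convex particle: exactly zero cystic area
  solid <- ellipse_mask(60, 25)
  expect_equal(cystic_area(solid, cfg)$area_px2, 0)

  frame <- function(hole_w, hole_h) {
    m <- matrix(FALSE, 160, 220)
    m[21:140, 21:200] <- TRUE
    r0 <- 80 - hole_h %/% 2; c0 <- 110 - hole_w %/% 2
    m[r0:(r0 + hole_h - 1), c0:(c0 + hole_w - 1)] <- FALSE
    m
  }
  ## interior gap with Feret just under 70 is excluded
  small_hole <- frame(40, 55)              # diag sqrt(40^2 + 55^2) ~ 68 < 70
  res_small <- cystic_area(small_hole, cfg)
  expect_equal(res_small$area_px2, 0)
  expect_true(any(res_small$audit$feret < 70 & res_small$audit$area > 100))
  ## interior gap above the cut is measured in full
  big_hole <- frame(45, 58)                # diag ~ 73 >= 70
  res_big <- cystic_area(big_hole, cfg)
  expect_equal(res_big$area_px2, 45 * 58)
  expect_error(cystic_area(matrix(FALSE, 5, 5), cfg), "no foreground")
})

test_that("rendered lumen area is recovered within ten percent", {
  cfg <- test_config()
  for (seed in 1:3) {
    q <- quick_processed_well("cystic", gap = 50, tilt = seed, seed = 120L + seed)
    prep <- prepare_binary(q$pw$recrop, cfg$phenotype_blur_sigma)
    ca <- cystic_area(prep$mask, cfg)
    expect_lt(abs(ca$area_px2 - q$truth$cyst_area_px2) / q$truth$cyst_area_px2,
              0.10)
  }
})

test_that("measured cystic area grows strictly with rendered lumen width", {
  cfg <- test_config()
  areas <- vapply(c(25, 40, 55, 70), function(gap) {
    q <- quick_processed_well("cystic", gap = gap, seed = 130L)
    prep <- prepare_binary(q$pw$recrop, cfg$phenotype_blur_sigma)
    cystic_area(prep$mask, cfg)$area_px2
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("tissue plus lumen areas never exceed the hull area", {
  cfg <- test_config()
  shoelace <- function(h) {
    n <- nrow(h); s <- 0
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      s <- s + h[i, 1] * h[j, 2] - h[j, 1] * h[i, 2]
    }
    abs(s) / 2
  }
  for (seed in 1:3) {
    q <- quick_processed_well("cystic", gap = 60, seed = 140L + seed)
    prep <- prepare_binary(q$pw$recrop, cfg$phenotype_blur_sigma)
    pron <- pronephric_area(prep$mask, cfg)
    cyst <- cystic_area(prep$mask, cfg)
    expect_lte(pron$area_px2 + cyst$area_px2, shoelace(cyst$hull))
  }
})

test_that("total kidney area follows the phenotype allocation rule", {
  cfg <- test_config()
  wt <- data.frame(well = "A01", label = "wildtype")
  m <- total_kidney_area(wt, 6000, 400, pixel_size_um = 0.65, config = cfg)
  expect_equal(m$total_kidney_area_px2, 6000)
  expect_equal(m$cystic_area_px2, 0)
  expect_equal(m$total_kidney_area_um2, 6000 * 0.65^2)

  cy <- data.frame(well = "A02", label = "cystic")
  m2 <- total_kidney_area(cy, 5000, 2500, config = cfg)
  expect_equal(m2$total_kidney_area_px2, 7500)

  amb <- data.frame(well = "A03", label = "ambiguous")
  expect_null(total_kidney_area(amb, 1, 1, config = cfg))
  cfg_inc <- build_config(list(include_ambiguous = TRUE), base = cfg)
  m3 <- total_kidney_area(amb, 5000, 2500, config = cfg_inc)
  expect_equal(m3$total_kidney_area_px2, 7500)
})

test_that("plate_summary builds the 8x12 matrix and marks missing wells", {
  meas <- data.frame(well = plate_wells(),
                     total_kidney_area_um2 = seq_len(96) * 100)
  full <- plate_summary(meas)
  expect_equal(dim(full), c(8L, 12L))
  expect_equal(sum(is.na(full)), 0L)
  expect_equal(full["A", "01"], 100)
  expect_equal(full["H", "12"], 9600)

  part <- plate_summary(meas[1:90, ])
  expect_equal(sum(is.na(part)), 6L)
  expect_error(plate_summary(rbind(meas, meas[1, ])), "duplicate")

  dir <- withr::local_tempdir()
  plate_summary(meas, dir)
  expect_true(file.exists(file.path(dir, "plate_matrix.csv")))
  expect_true(file.exists(file.path(dir, "plate_heatmap.png")))
})

test_that("row ordering constructed in the scene shows up in the plate matrix", {
  ## rows differing in lumen width by construction give ordered row means
  cfg <- test_config()
  gaps <- c(A = 25, B = 50, C = 75)
  rows <- list()
  for (r in names(gaps)) for (col in 1:2) {
    w <- sprintf("%s%02d", r, col)
    q <- quick_processed_well("cystic", well = w, gap = gaps[[r]],
                              seed = 150L + col)
    prep <- prepare_binary(q$pw$recrop, cfg$phenotype_blur_sigma)
    ca <- cystic_area(prep$mask, cfg)
    rows[[w]] <- data.frame(well = w, cystic_area_px2 = ca$area_px2)
  }
  meas <- do.call(rbind, rows)
  mat <- plate_summary(meas, value = "cystic_area_px2")
  means <- rowMeans(mat[c("A", "B", "C"), ], na.rm = TRUE)
  expect_true(all(diff(means) > 0))
})
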