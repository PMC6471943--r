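test_that("prepare_binary measures the exact area fraction of a clean mask", {
  img <- matrix(100, 320, 512)
  img[101:164, 201:328] <- 25000          # 64 x 128 = 8192 px
  prep <- prepare_binary(img, blur_sigma = 0)
  expect_equal(sum(prep$mask), 8192L)
  expect_equal(prep$area_fraction_pct, 5.0)       # 8192 / 163840
  expect_error(prepare_binary(matrix(5, 8, 8), blur_sigma = 0), "constant")
  ## mixed synthetic image is strictly between the extremes
  q <- quick_processed_well("wildtype", seed = 101L)
  af <- prepare_binary(q$pw$recrop, 2)$area_fraction_pct
  expect_gt(af, 0); expect_lt(af, 100)
})

test_that("select_roi spans both lobes, honours margins and clamps", {
  mask <- matrix(FALSE, 50, 100)
  mask[21:30, 11:30] <- TRUE               # left lobe
  mask[21:30, 61:80] <- TRUE               # right lobe
  roi <- select_roi(mask, margin = 0)
  expect_equal(unlist(roi), c(row1 = 21, row2 = 30, col1 = 11, col2 = 80))

  roi_m <- select_roi(mask, margin = 0.15)
  expect_lt(roi_m$col1, 11); expect_gt(roi_m$col2, 80)

  edge <- matrix(FALSE, 20, 20); edge[1:5, 1:5] <- TRUE
  roi_e <- select_roi(edge, margin = 0.5)
  expect_equal(c(roi_e$row1, roi_e$col1), c(1, 1))

  ## area fraction 100: inversion branch
  solid <- matrix(TRUE, 10, 10)
  expect_error(select_roi(solid), "no foreground")
  holed <- matrix(TRUE, 10, 10); holed[4:6, 5:7] <- FALSE
  roi_h <- select_roi(holed, area_fraction = 100, margin = 0)
  expect_equal(unlist(roi_h), c(row1 = 4, row2 = 6, col1 = 5, col2 = 7))
})

test_that("horizontal_profile is the column mean over ROI rows", {
  img <- matrix(50, 30, 40)
  roi <- list(row1 = 5L, row2 = 14L, col1 = 3L, col2 = 22L)
  expect_equal(horizontal_profile(img, roi), rep(50, 20))

  img2 <- matrix(0, 2, 4); img2[2, ] <- 100
  expect_equal(horizontal_profile(img2, list(row1 = 1L, row2 = 2L, col1 = 1L,
                                             col2 = 4L)), rep(50, 4))
  expect_error(horizontal_profile(img, list(row1 = 10L, row2 = 9L, col1 = 1L,
                                            col2 = 2L)), "degenerate")
})

test_that("profile_vote follows the zero-run rule", {
  expect_equal(profile_vote(c(5, 7, 3, 8, 2.5))$vote, "wildtype")
  expect_equal(profile_vote(c(5, 7, 3, 8, 2.5))$zero_run_length, 0L)

  p <- c(10, 9, 8, rep(0, 10), 7, 9, 11)
  v <- profile_vote(p)
  expect_equal(v$vote, "cystic")
  expect_equal(v$zero_run_length, 10L)

  lone <- c(10, 9, 0, 9, 10)
  expect_equal(profile_vote(lone, min_run = 3)$vote, "wildtype")
  expect_equal(profile_vote(lone, min_run = 1)$vote, "cystic")

  ## zero runs touching the profile ends are flanking background
  expect_equal(profile_vote(c(0, 0, 0, 9, 9, 9))$vote, "wildtype")
  expect_equal(profile_vote(c(9, 9, 9, 0, 0, 0))$vote, "wildtype")
})

test_that("profile_vote with epsilon 0 is invariant to intensity scaling", {
  set.seed(33)
  for (i in 1:20) {
    prof <- round(runif(60, 0, 50)) * sample(0:1, 60, TRUE)
    for (s in c(0.01, 1, 3.7, 1000)) {
      expect_identical(profile_vote(prof)$vote, profile_vote(prof * s)$vote)
      expect_identical(profile_vote(prof)$zero_run_length,
                       profile_vote(prof * s)$zero_run_length)
    }
  }
})

test_that("particle ellipses match analytic moments of discs and ellipses", {
  d <- fit_particle_ellipses(disc_mask(50))
  expect_equal(nrow(d), 1L)
  expect_equal(d$major_axis_px, 100, tolerance = 0.02)
  expect_equal(d$minor_axis_px, 100, tolerance = 0.02)

  e <- fit_particle_ellipses(ellipse_mask(150, 40))
  expect_equal(e$major_axis_px, 300, tolerance = 0.02)
  expect_equal(e$minor_axis_px, 80, tolerance = 0.02)

  two <- matrix(FALSE, 40, 40)
  two[2:8, 2:8] <- TRUE; two[25:38, 20:30] <- TRUE
  expect_equal(nrow(fit_particle_ellipses(two)), 2L)
  expect_error(fit_particle_ellipses(matrix(FALSE, 4, 4)), "no foreground")
})

test_that("ellipse fit equals the brute-force double-loop moments", {
  set.seed(44)
  for (i in 1:10) {
    m <- matrix(runif(48 * 48) < 0.4, 48, 48)
    m[1, ] <- FALSE; m[, 1] <- FALSE            # avoid touching borders
    if (!any(m)) next
    lab <- label_components(m, 8L)
    fits <- fit_particle_ellipses(m, 8L)
    comps <- component_stats(lab)
    for (k in seq_along(comps)) {
      bf <- bf_ellipse_axes(comps[[k]]$pixels)
      expect_equal(fits$major_axis_px[k], unname(bf["major"]), tolerance = 1e-9)
      expect_equal(fits$minor_axis_px[k], unname(bf["minor"]), tolerance = 1e-9)
    }
  }
})

test_that("ellipse_vote selects the biggest ellipse and compares strictly", {
  df <- function(major) data.frame(particle = seq_along(major), area = major,
                                   major_axis_px = major,
                                   minor_axis_px = major / 2)
  expect_equal(ellipse_vote(df(300.1))$vote, "wildtype")
  expect_equal(ellipse_vote(df(299.0))$vote, "cystic")   # strict "> 299"
  v <- ellipse_vote(df(c(120, 310)))
  expect_equal(v$vote, "wildtype")
  expect_equal(v$largest_major_axis_px, 310)
})

test_that("classification recovers rendered phenotypes and flags conflicts", {
  cfg <- test_config()
  wt <- quick_processed_well("wildtype", seed = 111L, tilt = 4)
  call_wt <- classify_well(wt$pw, cfg)
  expect_equal(call_wt$label, "wildtype")
  expect_equal(call_wt$profile_vote, "wildtype")
  expect_equal(call_wt$ellipse_vote, "wildtype")

  cy <- quick_processed_well("cystic", gap = 40, seed = 112L, tilt = -5)
  call_cy <- classify_well(cy$pw, cfg)
  expect_equal(call_cy$label, "cystic")
  expect_gt(call_cy$zero_run_length, 10)
  expect_lt(call_cy$largest_major_axis_px, 299)

  ## constructed conflict: a gap wide enough for a clean zero run in the
  ## profile but thin enough that the Gaussian-blurred Li mask bridges it,
  ## so the ellipse sees one long particle
  recrop <- matrix(0, 320, 512)
  recrop[130:190, 40:253] <- 20000
  recrop[130:190, 258:471] <- 20000        # 4-px gap at columns 254..257
  pw <- structure(list(well = "Z99", projection = recrop, recrop = recrop,
                       mask = recrop > 0, threshold = 1000, focus_index = 0L,
                       pixel_size_um = 0.65, provenance = list()),
                  class = "processed_well")
  call_cf <- classify_well(pw, cfg)
  expect_equal(call_cf$label, "ambiguous")
  expect_equal(call_cf$profile_vote, "cystic")
  expect_equal(call_cf$ellipse_vote, "wildtype")
})
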