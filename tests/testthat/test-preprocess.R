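test_that("focus detection finds the rendered best-focus plane", {
  cfg <- test_config()
  s10 <- settings_from_config(cfg, 10)
  s10$n_z <- 11L
  wc <- well_center_um("A01")
  for (off in c(-8, 0, 8)) {
    spec <- scene_spec("wildtype", wc, focus_offset_um = off, seed = 40L + off)
    st <- render_highres_stack(spec, "A01", wc, s10)
    expect_equal(find_focused_slice(st$gfp), st$truth$focus_index)
    expect_equal(find_focused_slice(st$gfp, "variance"), st$truth$focus_index)
  }
})

test_that("focus ties break to the lowest index and 1-stacks give 0", {
  one <- zstack(matrix(1:9, 3, 3), 4, 0.65)
  expect_equal(find_focused_slice(one), 0L)
  same <- zstack(rep(list(matrix(1:9, 3, 3)), 5), 4, 0.65)
  expect_equal(find_focused_slice(same), 0L)
})

test_that("sub-stack extraction is centred, clamped and size-checked", {
  stk <- zstack(lapply(1:30, function(i) matrix(i, 4, 4)), 4, 0.65)
  centre <- extract_substack(stk, 14L)
  expect_equal(vapply(centre$planes, function(p) p[1, 1], numeric(1)),
               12:18)                       # 0-based z 11..17
  low <- extract_substack(stk, 1L)
  expect_equal(vapply(low$planes, function(p) p[1, 1], numeric(1)), 1:7)
  high <- extract_substack(stk, 29L)
  expect_equal(vapply(high$planes, function(p) p[1, 1], numeric(1)), 24:30)
  short <- zstack(lapply(1:5, function(i) matrix(i, 4, 4)), 4, 0.65)
  expect_error(extract_substack(short, 2L), "at least 7")
  expect_error(extract_substack(stk, 14L, size = 6L), "odd")
})

test_that("maximum projection equals the brute-force triple loop", {
  one <- zstack(matrix(1:16, 4, 4), 4, 0.65)
  expect_identical(max_project(one), matrix(1:16, 4, 4))

  flat <- zstack(list(matrix(0, 4, 4), matrix(100, 4, 4), matrix(0, 4, 4)),
                 4, 0.65)
  expect_identical(max_project(flat), matrix(100, 4, 4))

  set.seed(8)
  planes <- lapply(1:3, function(i) matrix(sample(0:999, 64, TRUE) + 0, 8, 8))
  stk <- zstack(planes, 4, 0.65)
  proj <- max_project(stk)
  bf <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8) for (k in 1:3) {
    bf[r, c] <- max(bf[r, c], planes[[k]][r, c])
  }
  expect_identical(proj, bf)
  ## idempotence
  expect_identical(max_project(zstack(proj, 4, 0.65)), proj)
})

test_that("median denoising removes impulses and respects the no-op option", {
  flat <- matrix(500, 9, 9)
  salt <- flat; salt[5, 5] <- 30000
  expect_identical(denoise(salt), flat)
  expect_identical(denoise(flat), flat)
  expect_identical(denoise(salt, "none"), salt)
})

test_that("centre crop and glomerular recrop have exact pixel arithmetic", {
  big <- matrix(seq_len(2048L * 2048L), 2048, 2048)
  crop <- center_crop(big)
  expect_equal(dim(crop), c(512L, 512L))
  expect_identical(crop, big[769:1280, 769:1280])   # 0-based rows/cols 768..1279

  recrop <- glomerular_recrop(crop)
  expect_equal(dim(recrop), c(320L, 512L))          # round(512 / 1.6)
  expect_identical(recrop, big[865:1184, 769:1280])

  expect_error(center_crop(matrix(0, 300, 300)), "pixel-size")
})

test_that("Li threshold separates two-level images exactly and rejects constants", {
  img <- matrix(1000, 40, 40)
  img[10:20, 5:30] <- 30000
  th <- li_threshold(img)
  expect_identical(th$mask, img == 30000)
  expect_gte(th$threshold, 1000)
  expect_lt(th$threshold, 30000)
  expect_error(li_threshold(matrix(7, 5, 5)), "constant")
})

test_that("exhaustive Li agrees with the iterative fixed-point oracle", {
  set.seed(17)
  for (i in 1:10) {
    bg <- pmax(round(rnorm(600, 300, 60)), 0)
    fg <- round(rnorm(424, 9000, 900))
    img <- matrix(sample(c(bg, fg)), 32, 32)
    mine <- li_threshold(img)$threshold
    oracle <- li_iterative(img)
    ## both thresholds must induce the same bimodal split
    expect_identical(img > mine, img > oracle)
  }
})

test_that("Li mask of a rendered pronephros tracks the true lobe area", {
  q <- quick_processed_well("wildtype", seed = 51L)
  truth_px <- q$truth$pronephric_area_px2
  ## compare within the recrop window (the structure fits inside it)
  mask_px <- sum(q$pw$mask)
  expect_lt(abs(mask_px - truth_px) / truth_px, 0.15)
})

test_that("process_well produces the contracted shapes and provenance", {
  cfg <- test_config()
  q <- quick_processed_well("cystic", gap = 50, seed = 52L, n_z = 7L)
  pw <- q$pw
  expect_s3_class(pw, "processed_well")
  expect_equal(dim(pw$projection), c(512L, 512L))
  expect_equal(dim(pw$recrop), c(320L, 512L))
  expect_equal(dim(pw$mask), dim(pw$recrop))
  expect_gte(pw$focus_index, 0L)
  expect_lt(pw$focus_index, 7L)
  steps <- vapply(pw$provenance, `[[`, "", "step")
  expect_equal(steps, c("find_focused_slice", "extract_substack", "denoise",
                        "max_project", "center_crop", "glomerular_recrop",
                        "li_threshold"))
  ## bit-identical reprocessing
  s10 <- settings_from_config(cfg, 10); s10$n_z <- 7L
  wc <- well_center_um("A01")
  st <- render_highres_stack(q$spec, "A01", wc, s10)
  pw2 <- process_well(st$gfp, cfg, "A01")
  expect_identical(pw$projection, pw2$projection)
  expect_identical(pw$mask, pw2$mask)
})

test_that("a small plate of single-plane files reduces to one processed image per well", {
  cfg <- build_config(list(prescan_camera_px = 128L, rescan_camera_px = 128L,
                           pixel_size_10x_um = 2.6, n_z = 3L, crop_px = 96L,
                           substack_size = 3L))
  s10 <- settings_from_config(cfg, 10)
  dir <- withr::local_tempdir()
  wells <- c("A01", "B07", "H12")
  for (w in wells) {
    wc <- well_center_um(w)
    spec <- scene_spec("wildtype", wc, seed = 61L)
    job <- make_job_script(list(well = w, stage_um = wc), s10)
    mock_microscope_execute(job, spec, dir, settings = s10, well = w)
  }
  processed <- process_plate(dir, cfg)
  expect_length(processed, 3L)
  expect_setequal(names(processed), wells)
  expect_equal(dim(processed[["B07"]]$projection), c(96L, 96L))
  expect_error(process_plate(withr::local_tempdir(), cfg), "no rescan GFP470")
})

test_that("processed wells round-trip through their on-disk form", {
  q <- quick_processed_well("wildtype", seed = 55L)
  dir <- withr::local_tempdir()
  write_processed_well(q$pw, dir)
  back <- read_processed_well(dir, "A01")
  expect_identical(back$projection, q$pw$projection)
  expect_identical(back$recrop, q$pw$recrop)
  expect_identical(back$mask, q$pw$mask)
  expect_equal(back$focus_index, q$pw$focus_index)
})
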