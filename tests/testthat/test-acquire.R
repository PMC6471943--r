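test_that("pixel/stage affine map matches hand arithmetic and inverts", {
  cal <- stage_calibration(c(1000, 2000), 1.625)
  expect_equal(pixel_to_stage(c(0, 0), cal), c(1000, 2000))
  expect_equal(pixel_to_stage(c(100, 0), cal), c(1162.5, 2000))
  set.seed(5)
  px <- matrix(runif(2000, 0, 2047), ncol = 2)
  cal2 <- stage_calibration(c(-350.25, 8812.5), 0.65, flip = c(1, -1))
  back <- stage_to_pixel(pixel_to_stage(px, cal2), cal2)
  expect_lt(max(abs(back - px)), 1e-9)
  expect_error(stage_calibration(c(0, 0), -1))
})

test_that("centre-of-mass detection matches a brute-force double loop exactly", {
  cfg <- test_config(detect_min_area_px = 1L, detect_min_contrast = 1)
  set.seed(21)
  for (i in 1:10) {
    img <- matrix(0, 24, 32)
    blob <- matrix(sample(500:30000, 48, TRUE), 6, 8)
    r0 <- sample(1:18, 1); c0 <- sample(1:24, 1)
    img[r0:(r0 + 5), c0:(c0 + 7)] <- blob
    det <- detect_pronephros_center(img, cfg)
    mask <- li_threshold(img)$mask
    expect_equal(det$px, bf_center_of_mass(img, mask), tolerance = 1e-12)
  }
})

test_that("two equal blobs give the midpoint centre and degenerate inputs are blank", {
  cfg <- test_config(detect_min_area_px = 1L, detect_min_contrast = 1)
  img <- matrix(0, 200, 400)
  img[96:105, 96:105] <- 10000     # centred at x = 100 (0-based 95..104 -> 99.5)
  img[96:105, 296:305] <- 10000    # centred at x = 300
  det <- detect_pronephros_center(img, cfg)
  expect_equal(det$px[1], 199.5, tolerance = 1e-9)
  expect_null(detect_pronephros_center(matrix(0, 32, 32), cfg))
})

test_that("detection hits the generator's true centroid within a pixel", {
  cfg <- test_config()
  s4 <- settings_from_config(cfg, 4)
  for (seed in 1:5) {
    set.seed(seed + 100)
    off <- runif(2, -180, 180)
    spec <- scene_spec("wildtype", well_center_um("A01") + off,
                       orientation_deg = runif(1, -8, 8), seed = seed)
    ov <- render_overview(spec, "A01", s4)
    det <- detect_pronephros_center(ov$image, cfg)
    expect_lt(sqrt(sum((det$px - ov$truth$centroid_px)^2)), 1)
  }
})

test_that("job scripts follow the documented grammar byte for byte", {
  s <- acquisition_settings()
  roi <- list(well = "B05", stage_um = c(1500, 2250))
  job <- make_job_script(roi, s)
  expect_identical(job$lines, c(
    "GOTO 1500.0 2250.0",
    "AUTOFOCUS GFP470 700.0",
    "SET_CHANNEL BF 60 10",
    "STACK 30 4.0",
    "SET_CHANNEL GFP470 100 20",
    "STACK 30 4.0"))
  expect_length(job$lines, 6L)
  expect_match(job$lines[2], "700")

  s1 <- acquisition_settings(n_z = 1)
  expect_match(make_job_script(roi, s1)$lines[4], "^STACK 1 ")

  ## determinism
  expect_identical(make_job_script(roi, s)$lines, job$lines)
})

test_that("job scripts parse back and unknown verbs name their line", {
  roi <- list(well = "B05", stage_um = c(10.5, 20.25))
  job <- make_job_script(roi, acquisition_settings())
  cmds <- parse_job_script(job)
  expect_equal(cmds[[1]]$verb, "GOTO")
  expect_equal(cmds[[1]]$x, 10.5)
  expect_equal(cmds[[4]]$n_z, 30L)
  expect_error(parse_job_script(c("GOTO 1 2", "FOO 3")), "line 2.*FOO")
})

test_that("job files are written atomically under the job_<well>.txt name", {
  dir <- withr::local_tempdir()
  roi <- list(well = "C07", stage_um = c(1, 2))
  path <- write_job_script(make_job_script(roi, acquisition_settings()), dir)
  expect_equal(basename(path), "job_C07.txt")
  expect_length(list.files(dir), 1L)      # no stray temp files
})

test_that("watch_folder dispatches each stable file exactly once", {
  dir <- withr::local_tempdir()
  seen <- character(0)
  handler <- function(p) seen <<- c(seen, p)
  for (i in 1:5) writeLines("x", file.path(dir, sprintf("f%d.tif", i)))
  ledger <- file.path(dir, "ledger.txt")
  res <- watch_folder(dir, handler, poll_interval = 0, ledger_path = ledger)
  expect_length(res$processed, 5L)
  expect_length(seen, 5L)
  expect_length(unique(seen), 5L)
  expect_identical(sort(readLines(ledger)), sort(res$processed))

  ## idempotent re-run on the persisted ledger
  seen2 <- character(0)
  res2 <- watch_folder(dir, function(p) seen2 <<- c(seen2, p),
                       poll_interval = 0, ledger_path = ledger)
  expect_length(seen2, 0L)
})

test_that("watch_folder defers growing files and survives handler errors", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "grow.tif")
  writeLines("a", path)
  calls <- 0L
  polls <- 0L
  grow_then_count <- function(state) {
    polls <<- polls + 1L
    if (polls == 2L) cat("bbbb", file = path, append = TRUE)  # still growing
    FALSE
  }
  res <- watch_folder(dir, function(p) calls <<- calls + 1L,
                      poll_interval = 0, stop_condition = function(s) {
                        grow_then_count(s)
                        length(s$processed) == 1L
                      }, max_polls = 20L)
  expect_equal(calls, 1L)
  expect_length(res$processed, 1L)

  ## handler failure marks the file failed and the loop continues
  dir2 <- withr::local_tempdir()
  writeLines("a", file.path(dir2, "bad.tif"))
  writeLines("a", file.path(dir2, "good.tif"))
  ok <- character(0)
  expect_warning(
    res2 <- watch_folder(dir2, function(p) {
      if (grepl("bad", p)) stop("boom")
      ok <<- c(ok, p)
    }, poll_interval = 0),
    "handler failed")
  expect_length(res2$failed, 1L)
  expect_length(res2$processed, 1L)
  expect_match(res2$failed, "bad")
})

test_that("the mock microscope renders jobs at the commanded centre", {
  cfg <- test_config()
  s10 <- settings_from_config(cfg, 10)
  s10$n_z <- 3L
  wc <- well_center_um("D06")
  spec <- scene_spec("wildtype", wc + c(25, -35), seed = 31L)
  roi <- list(well = "D06", stage_um = spec$embryo_center_um)
  job <- make_job_script(roi, s10)
  dir <- withr::local_tempdir()
  res <- mock_microscope_execute(job, spec, dir, settings = s10, well = "D06")
  expect_length(res$files, 6L)                    # 2 channels x 3 planes
  expect_true(all(file.exists(res$files)))
  ## commanded centre equals the true embryo centre -> truth centroid at
  ## the field centre within 5 px
  centre <- (s10$camera_px - 1) / 2
  expect_lt(sqrt(sum((res$truth$centroid_px - centre)^2)), 5)

  expect_error(mock_microscope_execute(structure(list(well = "D06",
    lines = c("GOTO 1 2", "WOBBLE 9")), class = "job_script"), spec, dir,
    settings = s10), "line 2")
})

test_that("blank wells still produce full-length noise stacks", {
  cfg <- test_config()
  s10 <- settings_from_config(cfg, 10)
  s10$n_z <- 4L
  wc <- well_center_um("E01")
  spec <- scene_spec("blank", wc, seed = 33L)
  job <- make_job_script(list(well = "E01", stage_um = wc), s10)
  dir <- withr::local_tempdir()
  res <- mock_microscope_execute(job, spec, dir, settings = s10, well = "E01")
  recs <- list_plate_dir(dir)
  expect_equal(sum(recs$channel == "GFP470"), 4L)
  stk <- assemble_stack(recs, "E01", "GFP470", "rescan")
  expect_lt(max(vapply(stk$planes, max, numeric(1))), 50)   # noise only
})
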