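test_that("a simulated cohort round-trips through disk and analysis", {
  dir <- withr::local_tempdir()
  cfg <- synthetic_config(n_patients = 2, grid_px = 96, seed = 31)
  coh <- simulate_cohort_dir(dir, cfg, quiet = TRUE)
  ids <- coh$cohort$eye_id
  for (id in ids) {
    expect_true(file.exists(file.path(dir, paste0(id, "_flow.tif"))))
    expect_true(file.exists(file.path(dir, paste0(id, "_mask_t1.png"))))
  }
  expect_true(file.exists(file.path(dir, "geometry.json")))

  # images survive 16-bit storage exactly (the generator quantizes to the
  # same grid before writing)
  g <- coh$geometry
  back <- read_en_face(file.path(dir, paste0(ids[1], "_flow.tif")), g, "flow")
  expect_equal(back$pixels, coh$eyes[[1]]$flow$pixels, tolerance = 1e-7)
  m0 <- read_mask(file.path(dir, paste0(ids[1], "_mask_t0.png")), g)
  expect_identical(m0$pixels, coh$eyes[[1]]$mask_t0$pixels)

  res <- analyze_cohort_dir(dir, bin_params = binarization_params(2))
  expect_true(file.exists(file.path(dir, "results.csv")))
  expect_true(file.exists(file.path(dir, "run_manifest.json")))
  expect_equal(nrow(res), length(ids))
  expect_true(all(c("FV_OUT", "FV_500", "FV_1000", "dFV", "yGR",
                    "config_hash") %in% names(res)))

  # end-to-end determinism: a second run reproduces the records exactly
  res2 <- analyze_cohort_dir(dir, bin_params = binarization_params(2))
  expect_identical(res, res2)

  # in-memory and on-disk paths agree
  eye <- coh$eyes[[1]]
  rec <- analyze_eye(eye$flow, eye$structure, eye$mask_t0, eye$mask_t1,
                     eye$fu_years, eye_id = eye$eye_id,
                     bin_params = binarization_params(2))
  expect_equal(res$FV_500[res$eye_id == eye$eye_id], rec$FV_500,
               tolerance = 1e-9)
})

test_that("border-truncated eyes are excluded from cohort statistics", {
  rec <- simulate_cohort_records(n_patients = 20, seed = 5)
  rec$FV_OUT <- 42 + rnorm(nrow(rec))
  rec$excluded_border <- FALSE
  rec$excluded_border[1] <- TRUE
  st <- cohort_stats(rec, candidates = c("age", "dFV"))
  expect_equal(st$n_excluded, 1L)
  expect_equal(nrow(st$results), nrow(rec) - 1L)
})

test_that("the exclude-rings FV_OUT variant measures only beyond 1000 um", {
  coh <- tiny_cohort(n_patients = 1, grid_px = 128, seed = 61)
  eye <- coh$eyes[[1]]
  bp <- binarization_params(2)
  rec <- analyze_eye(eye$flow, eye$structure, eye$mask_t0, eye$mask_t1,
                     eye$fu_years, bin_params = bp,
                     fv_out_mode = "exclude-rings")
  comp <- compensate(eye$flow, eye$structure)
  bin <- phansalkar_binarize(comp, bp)
  reg <- build_regions(eye$mask_t0)
  expect_equal(rec$FV_OUT, fv_percentage(bin, reg$beyond), tolerance = 1e-12)
  expect_identical(rec$FV_OUT, rec$FV_OUT_beyond)
})

test_that("missing inputs fail with the path named", {
  dir <- withr::local_tempdir()
  expect_error(analyze_cohort_dir(dir), "geometry")
  g <- scan_geometry(64, 6)
  expect_error(read_en_face(file.path(dir, "nope.tif"), g), "nope.tif")
  expect_error(read_mask(file.path(dir, "nope.png"), g), "nope.png")
})

test_that("run configuration merges file values and overrides", {
  cfg <- run_config()
  expect_equal(cfg$ring_widths_um, c(500, 500))
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "bin:", "  radius_px: 7",
               "generator:", "  n_patients: 5"), path)
  cfg2 <- run_config(path)
  expect_equal(cfg2$seed, 9)
  expect_equal(cfg2$bin$radius_px, 7)
  expect_equal(cfg2$generator$n_patients, 5)
  cfg3 <- run_config(path, overrides = list(seed = 11))
  expect_equal(cfg3$seed, 11)
  expect_error(run_config(path, overrides = list(bogus = 1)), "bogus")
})

test_that("region label maps and QC overlays are written", {
  dir <- withr::local_tempdir()
  g <- scan_geometry(96, 6)
  mask <- circle_mask(g, 3, 3, 0.6)
  reg <- build_regions(mask)
  p1 <- file.path(dir, "regions.png")
  write_region_map(reg, p1)
  lab <- png::readPNG(p1)
  expect_equal(sum(lab == 0), sum(mask$pixels))
  coh <- tiny_cohort(n_patients = 1, grid_px = 96, seed = 2)
  dir2 <- withr::local_tempdir()
  write_cohort_dir(coh, dir2)
  analyze_cohort_dir(dir2, bin_params = binarization_params(2), qc = TRUE)
  expect_true(file.exists(file.path(
    dir2, paste0(coh$cohort$eye_id[1], "_qc.png"))))
})
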