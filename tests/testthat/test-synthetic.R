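test_that("the generator is deterministic given the seed", {
  a <- tiny_cohort(n_patients = 2, grid_px = 96, seed = 77)
  b <- tiny_cohort(n_patients = 2, grid_px = 96, seed = 77)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cohort, b$cohort)
  for (k in seq_along(a$eyes)) {
    expect_identical(a$eyes[[k]]$flow$pixels, b$eyes[[k]]$flow$pixels)
    expect_identical(a$eyes[[k]]$structure$pixels, b$eyes[[k]]$structure$pixels)
    expect_identical(a$eyes[[k]]$mask_t1$pixels, b$eyes[[k]]$mask_t1$pixels)
  }
  c2 <- tiny_cohort(n_patients = 2, grid_px = 96, seed = 78)
  expect_false(identical(a$eyes[[1]]$flow$pixels, c2$eyes[[1]]$flow$pixels))
})

test_that("grow_mask enlarges a disc by exactly speed * years", {
  g <- scan_geometry(512, 6)
  m0 <- circle_mask(g, 3, 3, 0.5)
  m1 <- grow_mask(m0, 0.1, 1)
  expect_equal(lesion_area(m1), pi * 0.36, tolerance = 0.02)
  expect_identical(grow_mask(m0, 0, 5)$pixels, m0$pixels)
  expect_identical(grow_mask(m0, 0.3, 0)$pixels, m0$pixels)
  # growth is monotone: the original lesion is contained
  expect_true(all(m1$pixels[m0$pixels]))
})

test_that("growing foci merge once the gap is covered", {
  g <- scan_geometry(256, 6)
  m <- lesion_mask(circle_mask(g, 2.3, 3, 0.3)$pixels |
                     circle_mask(g, 3.0, 3, 0.3)$pixels, g)
  expect_equal(nrow(lesion_foci(m)$foci), 2L)
  grown <- grow_mask(m, 0.1, 1)  # 2 x (0.3 + 0.1) = 0.8 > 0.7 centre gap
  expect_equal(nrow(lesion_foci(grown)$foci), 1L)
  # brute-force check of the dilation rule on a downsampled grid
  g2 <- scan_geometry(96, 6)
  m2 <- circle_mask(g2, 2.8, 3.1, 0.4)
  d <- edt_brute_um(m2)
  expect_identical(grow_mask(m2, 0.25, 1)$pixels, m2$pixels | (d <= 250))
})

test_that("truth void fractions equal the probability-field region means", {
  coh <- tiny_cohort(n_patients = 2, grid_px = 128, seed = 19)
  for (k in seq_along(coh$eyes)) {
    eye <- coh$eyes[[k]]
    tr <- coh$truth[k, ]
    cfg <- coh$config
    p <- ccfv:::void_probability_field(cfg, eye$flow$geometry, eye$mask_t0,
                                       tr$true_ring_excess)
    reg <- build_regions(eye$mask_t0)
    expect_equal(mean(p[reg$outside]), tr$true_void_frac_out, tolerance = 1e-9)
    expect_equal(mean(p[reg$para]), tr$true_void_frac_para, tolerance = 1e-9)
    expect_equal(mean(p[reg$peri]), tr$true_void_frac_peri, tolerance = 1e-9)
    # and the pipeline recovers them within a percentage point or two
    rec <- analyze_eye(eye$flow, eye$structure, eye$mask_t0, eye$mask_t1,
                       eye$fu_years, bin_params = binarization_params(2))
    expect_equal(rec$FV_OUT, 100 * tr$true_void_frac_out, tolerance = 0.05)
  }
})

test_that("a null configuration produces no ring contrast", {
  coh <- generate_cohort(synthetic_config(
    n_patients = 4, bilateral_prob = 0, grid_px = 128, seed = 23,
    ring_excess_range = c(0, 0), eccentricity_gradient = 0,
    growth_coupling = 0))
  dfv <- vapply(coh$eyes, function(eye) {
    analyze_eye(eye$flow, eye$structure, eye$mask_t0, eye$mask_t1,
                eye$fu_years, bin_params = binarization_params(2))$dFV
  }, 0.0)
  expect_lt(abs(mean(dfv)), 2)
  expect_equal(coh$truth$true_void_frac_para, coh$truth$true_void_frac_peri,
               tolerance = 1e-9)
})

test_that("a decoupled null leaves edge speed independent of ring excess", {
  rec <- simulate_cohort_records(n_patients = 36, growth_coupling = 0,
                                 seed = 1)  # ~50 eyes
  expect_gte(nrow(rec), 40)
  expect_lt(abs(cor(rec$true_edge_speed, rec$true_ring_excess)), 0.2)
})

test_that("oversized lesions are flagged as border-truncated", {
  coh <- generate_cohort(synthetic_config(
    n_patients = 1, bilateral_prob = 0, grid_px = 96, seed = 8,
    lesion_area_median_mm2 = 22, lesion_area_sdlog = 0.01,
    lesion_area_max_mm2 = 30))
  expect_true(coh$truth$border_truncated[1])
  expect_true(touches_border(coh$eyes[[1]]$mask_t0, coh$eyes[[1]]$mask_t1))
})

test_that("flow-void metrics are stable across grid resolution", {
  # same eye-level draws, finer raster + matched physical window radius:
  # each FV metric should move by well under a percentage point
  fv <- lapply(c(256, 512), function(n) {
    coh <- tiny_cohort(n_patients = 2, grid_px = n, seed = 55)
    do.call(rbind, lapply(coh$eyes, function(eye)
      analyze_eye(eye$flow, eye$structure, eye$mask_t0, eye$mask_t1,
                  eye$fu_years,
                  bin_params = binarization_params(scaled_radius(n)))[
        , c("FV_OUT", "FV_500", "FV_1000")]))
  })
  diffs <- abs(colMeans(fv[[1]]) - colMeans(fv[[2]]))
  expect_true(all(diffs < 1))
})
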