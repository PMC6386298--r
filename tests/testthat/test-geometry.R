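test_that("ring areas around a centred circular lesion match the analytic annuli", {
  g <- scan_geometry(512, 6)
  mask <- circle_mask(g, 3, 3, 0.5)
  reg <- build_regions(mask)
  px_area <- (g$um_per_px / 1000)^2
  expect_equal(sum(reg$para) * px_area, pi * (1.0^2 - 0.5^2), tolerance = 0.02)
  expect_equal(sum(reg$peri) * px_area, pi * (1.5^2 - 1.0^2), tolerance = 0.02)
})

test_that("region invariants hold and adjacent foci exclude each other", {
  g <- scan_geometry(256, 6)
  # two foci with a 600 um edge-to-edge gap: para rings abut between them
  m <- circle_mask(g, 2.0, 3, 0.4)$pixels | circle_mask(g, 3.4, 3, 0.4)$pixels
  mask <- lesion_mask(m, g)
  reg <- build_regions(mask)
  expect_false(any(reg$para & mask$pixels))
  expect_false(any(reg$peri & mask$pixels))
  expect_false(any(reg$para & reg$peri))
  expect_true(all(which(reg$para | reg$peri) %in% which(reg$outside)))
  # the midline between the foci is 300 um from each edge: para territory
  mid_col <- round(2.7 / 6 * 256)
  expect_true(any(reg$para[, mid_col]))
})

test_that("distance transform agrees with the all-pairs brute force", {
  set.seed(13)
  g <- scan_geometry(128, 6)
  m <- circle_mask(g, 2.2, 2.6, 0.45)$pixels |
    circle_mask(g, 4.0, 3.8, 0.3)$pixels
  mask <- lesion_mask(m, g)
  d_fast <- ccfv:::lesion_distance_map_um(mask)
  d_brute <- edt_brute_um(mask)
  expect_equal(d_fast, d_brute, tolerance = 1e-12)
  # region areas derived from either distance map are identical
  reg <- build_regions(mask)
  expect_identical(sum(reg$para), sum(!m & d_brute > 0 & d_brute <= 500))
  expect_identical(sum(reg$peri), sum(!m & d_brute > 500 & d_brute <= 1000))
})

test_that("empty masks are rejected by region construction", {
  g <- scan_geometry(64, 6)
  expect_error(build_regions(lesion_mask(matrix(FALSE, 64, 64), g)), "empty")
})

test_that("lesion area is pixel count times pixel area", {
  g <- scan_geometry(1024, 6)
  expect_equal(lesion_area(lesion_mask(matrix(TRUE, 1024, 1024), g)), 36.0)
  expect_equal(lesion_area(circle_mask(g, 3, 3, 1)), pi, tolerance = 0.02)
  expect_equal(lesion_area(lesion_mask(matrix(FALSE, 1024, 1024), g)), 0)
})

test_that("fovea distance averages over foci, unweighted", {
  g <- scan_geometry(512, 6)  # fovea at field centre (3, 3)
  expect_equal(fovea_distance(circle_mask(g, 4, 3, 0.2)), 1.0,
               tolerance = 0.01)
  m2 <- circle_mask(g, 3.5, 3, 0.15)$pixels | circle_mask(g, 4.5, 3, 0.3)$pixels
  expect_equal(fovea_distance(lesion_mask(m2, g)), 1.0, tolerance = 0.01)
  expect_equal(fovea_distance(circle_mask(g, 3, 3, 0.5)), 0.0,
               tolerance = 0.01)
})

test_that("border contact is detected at either visit", {
  g <- scan_geometry(128, 6)
  inner <- circle_mask(g, 3, 3, 0.5)
  clipped <- circle_mask(g, 0.2, 3, 0.5)
  expect_false(touches_border(inner, inner))
  expect_true(touches_border(clipped))
  expect_true(touches_border(inner, clipped))  # either-visit rule
})

test_that("regions are translation-equivariant and nested monotonically", {
  g <- scan_geometry(160, 6)
  base <- circle_mask(g, 2.2, 2.2, 0.3)
  shift_px <- 20L
  shifted <- lesion_mask(
    rbind(matrix(FALSE, shift_px, 160),
          base$pixels[1:(160 - shift_px), ]), g)
  ra <- build_regions(base)
  rb <- build_regions(shifted)
  expect_identical(rb$para[(shift_px + 1):160, ], ra$para[1:(160 - shift_px), ])
  expect_identical(rb$peri[(shift_px + 1):160, ], ra$peri[1:(160 - shift_px), ])

  # enlarging the lesion never increases the distance at any pixel
  bigger <- grow_mask(base, 0.2, 1)
  expect_true(all(ccfv:::lesion_distance_map_um(bigger) <=
                    ccfv:::lesion_distance_map_um(base) + 1e-9))

  # labeling is invariant under focus relabeling: areas and centroids are a
  # set, regardless of scan order
  two <- lesion_mask(base$pixels | circle_mask(g, 4, 4, 0.25)$pixels, g)
  f <- lesion_foci(two)$foci
  expect_equal(nrow(f), 2L)
  expect_equal(sum(f$area_mm2), lesion_area(two), tolerance = 1e-12)
})

test_that("focus labeling uses 8-connectivity", {
  g <- scan_geometry(16, 6)
  m <- matrix(FALSE, 16, 16)
  m[4, 4] <- TRUE
  m[5, 5] <- TRUE  # diagonal neighbour: one focus under 8-connectivity
  expect_equal(nrow(lesion_foci(lesion_mask(m, g))$foci), 1L)
})
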