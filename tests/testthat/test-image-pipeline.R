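test_that("compensation multiplies flow by the smoothed inverted structure", {
  g <- scan_geometry(64, 6)
  fl <- en_face_image(matrix(0.4, 64, 64), g, "flow")
  st <- en_face_image(matrix(0.3, 64, 64), g, "structure")
  comp <- compensate(fl, st, compensation_params(rescale = FALSE))
  expect_equal(comp$pixels, matrix(0.4 * 0.7, 64, 64))

  # constant product with rescale on: degenerate min-max guarded, flow
  # passes through unchanged
  comp2 <- compensate(fl, st, compensation_params(rescale = TRUE))
  expect_equal(comp2$pixels, fl$pixels)

  # shape / geometry mismatches are hard errors
  g2 <- scan_geometry(32, 6)
  st_small <- en_face_image(matrix(0.3, 32, 32), g2, "structure")
  expect_error(compensate(fl, st_small), "shape|geometry")
  g3 <- scan_geometry(64, 3)
  st_geo <- en_face_image(matrix(0.3, 64, 64), g3, "structure")
  expect_error(compensate(fl, st_geo), "geometry")
  expect_error(compensate(st, fl), "flow image and a structure image")
})

test_that("uniform structure leaves the binarization result unchanged", {
  # structure uniform at c < 1 makes compensation a positive scaling of the
  # flow image; after min-max rescale the Phansalkar map must be identical
  # to that of the raw flow image
  set.seed(101)
  g <- scan_geometry(64, 6)
  raw <- matrix(runif(64 * 64), 64, 64)
  fl <- en_face_image(raw, g, "flow")
  st <- en_face_image(matrix(0.45, 64, 64), g, "structure")
  comp <- compensate(fl, st, compensation_params(rescale = TRUE))
  bp <- binarization_params(radius_px = 7)
  rng <- range(raw)
  flow_mm <- en_face_image((raw - rng[1]) / diff(rng), g, "flow")
  expect_identical(phansalkar_binarize(comp, bp)$voids,
                   phansalkar_binarize(flow_mm, bp)$voids)
})

test_that("compensated intensity is strictly increasing in flow intensity", {
  set.seed(7)
  g <- scan_geometry(32, 6)
  st <- en_face_image(matrix(runif(32 * 32, 0.2, 0.9), 32), g, "structure")
  a <- matrix(runif(32 * 32, 0, 0.5), 32)
  b <- a + matrix(runif(32 * 32, 0.01, 0.4), 32)  # strictly larger flow
  pa <- compensate(en_face_image(a, g, "flow"), st,
                   compensation_params(rescale = FALSE))$pixels
  pb <- compensate(en_face_image(b, g, "flow"), st,
                   compensation_params(rescale = FALSE))$pixels
  expect_true(all(pb > pa))
})

test_that("a constant image has the closed-form threshold and no voids", {
  g <- scan_geometry(64, 6)
  img <- en_face_image(matrix(0.5, 64, 64), g, "flow")
  bp <- binarization_params(radius_px = 15)
  thr <- phansalkar_threshold(img$pixels, bp)
  # m = 0.5, s = 0: t = 0.5 * (1 + 2 exp(-5) - 0.25)
  expect_equal(max(abs(thr - 0.5 * (1 + 2 * exp(-5) - 0.25))), 0,
               tolerance = 1e-12)
  expect_equal(sum(phansalkar_binarize(img, bp)$voids), 0L)
})

test_that("binarization equals the brute-force windowed oracle", {
  g <- scan_geometry(32, 6)
  # half-black / half-white step image
  step <- cbind(matrix(0.1, 32, 16), matrix(0.9, 32, 16))
  bp <- binarization_params(radius_px = 5)
  got <- phansalkar_binarize(en_face_image(step, g, "flow"), bp)$voids
  expect_identical(got, phansalkar_oracle(step, 5))
  # the low side is void except near the boundary; the high side never is
  expect_true(all(got[, 1:11]))
  expect_true(!any(got[, 17:32]))

  # random images, several radii, pixel-exact agreement
  set.seed(31)
  for (r in c(3, 8, 15)) {
    px <- matrix(runif(64 * 64), 64, 64)
    got <- phansalkar_binarize(en_face_image(px, scan_geometry(64, 6), "flow"),
                               binarization_params(radius_px = r))$voids
    expect_identical(got, phansalkar_oracle(px, r))
  }
})

test_that("binarization absorbs affine intensity changes via min-max rescale", {
  set.seed(17)
  g <- scan_geometry(48, 6)
  px <- matrix(runif(48 * 48), 48, 48)
  affine <- 0.2 + 0.55 * px
  minmax <- function(x) (x - min(x)) / (max(x) - min(x))
  bp <- binarization_params(radius_px = 6)
  expect_identical(
    phansalkar_binarize(en_face_image(minmax(px), g, "flow"), bp)$voids,
    phansalkar_binarize(en_face_image(minmax(affine), g, "flow"), bp)$voids)
})

test_that("oversized binarization radius is rejected", {
  g <- scan_geometry(32, 6)
  img <- en_face_image(matrix(0.5, 32, 32), g, "flow")
  expect_error(phansalkar_binarize(img, binarization_params(radius_px = 17)),
               "radius")
})
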