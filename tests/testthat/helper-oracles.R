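# Independent oracles used by the tests: direct per-pixel computations that
# share no code with the package's fast paths.

# Brute-force Phansalkar map: for every pixel, gather the circular window
# (mirror boundary) and compute mean/SD by direct summation. The gather
# index table depends only on (n, m, radius) and can be reused across
# images of the same size.
phansalkar_oracle_indices <- function(n, m, radius) {
  off <- expand.grid(di = -radius:radius, dj = -radius:radius)
  off <- off[off$di^2 + off$dj^2 <= radius^2, ]
  reflect <- function(i, nn) {
    i <- ifelse(i < 0, -i - 1, i)
    ifelse(i >= nn, 2 * nn - 1 - i, i)
  }
  ii <- rep(0:(n - 1), times = m)
  jj <- rep(0:(m - 1), each = n)
  idx <- matrix(0L, n * m, nrow(off))
  for (t in seq_len(nrow(off))) {
    ri <- reflect(ii + off$di[t], n)
    rj <- reflect(jj + off$dj[t], m)
    idx[, t] <- ri + 1L + n * rj  # column-major linear index
  }
  idx
}

phansalkar_oracle <- function(px, radius, k = 0.25, r_norm = 0.5,
                              p = 2, q = 10, idx = NULL) {
  n <- nrow(px)
  m <- ncol(px)
  if (is.null(idx)) idx <- phansalkar_oracle_indices(n, m, radius)
  vals <- matrix(px[as.vector(idx)], nrow(idx), ncol(idx))
  mu <- rowMeans(vals)
  s <- sqrt(pmax(rowMeans(vals^2) - mu^2, 0))
  thr <- mu * (1 + p * exp(-q * mu) + k * (s / r_norm - 1))
  matrix(as.vector(px) < thr, n, m)
}

# All-pairs Euclidean distance from each background pixel to the nearest
# lesion pixel, in micrometres.
edt_brute_um <- function(mask) {
  px <- mask$pixels
  fg <- which(px, arr.ind = TRUE)
  d <- matrix(0, nrow(px), ncol(px))
  bg <- which(!px, arr.ind = TRUE)
  for (t in seq_len(nrow(bg))) {
    d[bg[t, 1], bg[t, 2]] <-
      sqrt(min((bg[t, 1] - fg[, 1])^2 + (bg[t, 2] - fg[, 2])^2))
  }
  d * mask$geometry$um_per_px
}

# Rasterize a circular lesion (centre and radius in mm, pixel-centre test).
circle_mask <- function(geometry, cx_mm, cy_mm, r_mm) {
  n <- geometry$grid_px
  px_mm <- geometry$field_mm / n
  cc <- (seq_len(n) - 0.5) * px_mm
  x <- matrix(cc, n, n, byrow = TRUE)
  y <- matrix(cc, n, n, byrow = FALSE)
  lesion_mask((x - cx_mm)^2 + (y - cy_mm)^2 <= r_mm^2, geometry)
}

# Binarization radius matched to the physical window of 15 px on the native
# 1024-px grid.
scaled_radius <- function(grid_px) max(2L, as.integer(round(15 * grid_px / 1024)))

# Small synthetic cohort for pipeline tests.
tiny_cohort <- function(n_patients = 2, grid_px = 128, seed = 42, ...) {
  generate_cohort(synthetic_config(n_patients = n_patients, grid_px = grid_px,
                                   seed = seed, ...))
}
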