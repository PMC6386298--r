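#' Scan geometry of an en-face acquisition
#'
#' Describes the physical grid of an en-face OCTA scan: a square raster of
#' `grid_px` pixels covering `field_mm` millimetres per side, fovea-centred
#' unless stated otherwise. Pixel indices are 0-based; physical coordinates
#' refer to pixel centres, so pixel `(i, j)` sits at
#' `((j + 0.5) * field_mm / grid_px, (i + 0.5) * field_mm / grid_px)` in mm
#' (x along columns, y along rows).
#'
#' @param grid_px integer, pixels per side (default 1024, the native en-face
#'   CC grid).
#' @param field_mm physical side length in mm (default 6, a 6 x 6 mm scan).
#' @param fovea_px numeric length-2, fovea position `(x, y)` in 0-based pixel
#'   coordinates. Defaults to the scan centre.
#' @return An object of class `scan_geometry` with fields `grid_px`,
#'   `field_mm`, `um_per_px` and `fovea_px`.
#' @examples
#' g <- scan_geometry(1024, 6)
#' g$um_per_px  # 5.859 um per pixel
#' @export
scan_geometry <- function(grid_px = 1024L, field_mm = 6,
                          fovea_px = c((grid_px - 1) / 2, (grid_px - 1) / 2)) {
  grid_px <- as.integer(grid_px)
  stopifnot(length(grid_px) == 1L, grid_px > 0L,
            length(field_mm) == 1L, is.finite(field_mm), field_mm > 0,
            length(fovea_px) == 2L, all(is.finite(fovea_px)))
  if (any(fovea_px < 0) || any(fovea_px > grid_px - 1))
    stop("fovea_px must lie inside the grid [0, grid_px - 1]")
  structure(list(
    grid_px   = grid_px,
    field_mm  = as.numeric(field_mm),
    um_per_px = field_mm * 1000 / grid_px,
    fovea_px  = as.numeric(fovea_px)
  ), class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %d px / %.2f mm (%.3f um/px), fovea at (%.1f, %.1f) px\n",
              x$grid_px, x$field_mm, x$um_per_px, x$fovea_px[1], x$fovea_px[2]))
  invisible(x)
}

same_geometry <- function(a, b) {
  isTRUE(all.equal(a$grid_px, b$grid_px)) &&
    isTRUE(all.equal(a$field_mm, b$field_mm)) &&
    isTRUE(all.equal(a$fovea_px, b$fovea_px))
}

#' Physical coordinates (mm) of every pixel centre
#'
#' @param geometry a [scan_geometry()].
#' @return list with matrices `x_mm`, `y_mm` of pixel-centre coordinates.
#' @keywords internal
pixel_coords_mm <- function(geometry) {
  n <- geometry$grid_px
  px_mm <- geometry$field_mm / n
  cc <- (seq_len(n) - 0.5) * px_mm       # centre of column j / row i
  list(x_mm = matrix(cc, n, n, byrow = TRUE),
       y_mm = matrix(cc, n, n, byrow = FALSE))
}

#' Map of distance from the fovea, in micrometres
#'
#' @param geometry a [scan_geometry()].
#' @return numeric matrix, per-pixel centre-to-fovea distance in um.
#' @keywords internal
fovea_distance_map_um <- function(geometry) {
  co <- pixel_coords_mm(geometry)
  fx <- (geometry$fovea_px[1] + 0.5) * geometry$field_mm / geometry$grid_px
  fy <- (geometry$fovea_px[2] + 0.5) * geometry$field_mm / geometry$grid_px
  sqrt((co$x_mm - fx)^2 + (co$y_mm - fy)^2) * 1000
}

#' En-face image container
#'
#' One grayscale en-face raster (structural or flow/angiogram channel) with
#' its scan geometry. Intensities are kept normalized to `[0, 1]`; 8- and
#' 16-bit sources are divided by their nominal maxima on load.
#'
#' @param pixels numeric matrix, square, all values finite and in `[0, 1]`.
#' @param geometry a [scan_geometry()] matching the matrix size.
#' @param modality `"structure"` or `"flow"`.
#' @return An object of class `en_face_image`.
#' @export
en_face_image <- function(pixels, geometry, modality = c("flow", "structure")) {
  modality <- match.arg(modality)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) != ncol(pixels)) stop("en-face image must be square")
  if (nrow(pixels) != geometry$grid_px)
    stop("image size does not match geometry$grid_px")
  if (!all(is.finite(pixels))) stop("image contains non-finite values")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image values must be normalized to [0, 1]")
  structure(list(pixels = pixels, geometry = geometry, modality = modality),
            class = "en_face_image")
}

#' @export
print.en_face_image <- function(x, ...) {
  cat(sprintf("<en_face_image> %s, %d x %d px, range [%.3f, %.3f]\n",
              x$modality, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' GA lesion mask
#'
#' Binary geographic-atrophy mask on the same grid as the en-face images.
#' Lesions may be multifocal; foci are labeled with 8-connectivity on demand
#' via [lesion_foci()].
#'
#' @param pixels logical (or 0/1 numeric) matrix, `TRUE` = atrophy.
#' @param geometry a [scan_geometry()] matching the matrix size.
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(pixels, geometry) {
  if (is.numeric(pixels)) pixels <- pixels > 0.5
  stopifnot(is.matrix(pixels), is.logical(pixels))
  if (nrow(pixels) != ncol(pixels)) stop("mask must be square")
  if (nrow(pixels) != geometry$grid_px)
    stop("mask size does not match geometry$grid_px")
  if (anyNA(pixels)) stop("mask contains NA")
  structure(list(pixels = pixels, geometry = geometry), class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf("<lesion_mask> %d x %d px, %d lesion px (%.3f mm^2)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), lesion_area(x)))
  invisible(x)
}

#' Label lesion foci and summarize them
#'
#' Connected components of the lesion mask under 8-connectivity (the ImageJ
#' particle convention), with per-focus area and centroid in physical
#' coordinates.
#'
#' @param mask a [lesion_mask()].
#' @return list with `labels` (integer matrix, 0 = background) and `foci`, a
#'   data.frame with columns `focus`, `area_mm2`, `cx_mm`, `cy_mm`.
#' @export
lesion_foci <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  lab <- cc_label8(mask$pixels)
  nf <- max(lab)
  px_mm <- mask$geometry$field_mm / mask$geometry$grid_px
  if (nf == 0L) {
    return(list(labels = lab,
                foci = data.frame(focus = integer(), area_mm2 = numeric(),
                                  cx_mm = numeric(), cy_mm = numeric())))
  }
  co <- pixel_coords_mm(mask$geometry)
  idx <- which(lab > 0L)
  f <- lab[idx]
  area <- tabulate(f, nbins = nf) * px_mm^2
  cx <- vapply(seq_len(nf), function(k) mean(co$x_mm[idx[f == k]]), 0.0)
  cy <- vapply(seq_len(nf), function(k) mean(co$y_mm[idx[f == k]]), 0.0)
  list(labels = lab,
       foci = data.frame(focus = seq_len(nf), area_mm2 = area,
                         cx_mm = cx, cy_mm = cy))
}
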