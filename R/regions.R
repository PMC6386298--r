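#' Euclidean distance from the lesion, in micrometres
#'
#' Exact Euclidean distance transform of the background measured from the
#' union of all lesion foci (pixel centre to pixel centre), scaled to um.
#' Lesion pixels have distance 0.
#'
#' @param mask a [lesion_mask()] (may not be empty).
#' @return numeric matrix of distances in um.
#' @keywords internal
lesion_distance_map_um <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  if (!any(mask$pixels)) stop("lesion mask is empty")
  bg <- matrix(as.numeric(!mask$pixels), nrow(mask$pixels))
  d_px <- EBImage::distmap(bg, metric = "euclidean")
  as.matrix(d_px) * mask$geometry$um_per_px
}

#' Build the analysis regions around a GA lesion
#'
#' Carves the three analysis regions from the lesion mask using the exact
#' Euclidean distance transform of the background from the union of all
#' lesion foci (so the rings automatically exclude, and stop at, adjacent
#' foci):
#' \itemize{
#'   \item `outside`: every non-lesion pixel (the default FV_OUT support,
#'     which subsumes the rings);
#'   \item `para`: non-lesion pixels with edge distance in `(0, 500]` um
#'     (the para-atrophy ring);
#'   \item `peri`: non-lesion pixels with edge distance in `(500, 1000]` um
#'     (the peri-atrophy ring);
#'   \item `beyond`: non-lesion pixels farther than 1000 um (the
#'     exclude-rings FV_OUT variant).
#' }
#' Ring membership uses half-open intervals so no pixel is counted twice.
#'
#' @param mask a [lesion_mask()]; must contain at least one lesion pixel.
#' @param ring_widths_um widths of the two rings in um (default `c(500, 500)`).
#' @return An object of class `region_set` with logical matrices `outside`,
#'   `para`, `peri`, `beyond`, the `distance_um` map and the geometry.
#' @export
build_regions <- function(mask, ring_widths_um = c(500, 500)) {
  stopifnot(inherits(mask, "lesion_mask"),
            length(ring_widths_um) == 2L, all(ring_widths_um > 0))
  if (!any(mask$pixels)) stop("cannot build regions around an empty lesion mask")
  d <- lesion_distance_map_um(mask)
  r1 <- ring_widths_um[1]
  r2 <- r1 + ring_widths_um[2]
  outside <- !mask$pixels
  structure(list(
    outside = outside,
    para    = outside & d > 0 & d <= r1,
    peri    = outside & d > r1 & d <= r2,
    beyond  = outside & d > r2,
    distance_um = d,
    ring_widths_um = ring_widths_um,
    geometry = mask$geometry
  ), class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  a <- (x$geometry$um_per_px / 1000)^2
  cat(sprintf("<region_set> outside %.2f mm^2 | para %.2f mm^2 | peri %.2f mm^2 | beyond %.2f mm^2\n",
              sum(x$outside) * a, sum(x$para) * a, sum(x$peri) * a,
              sum(x$beyond) * a))
  invisible(x)
}

#' Lesion area in mm^2
#'
#' Pixel count times physical pixel area, summed over all foci.
#'
#' @param mask a [lesion_mask()].
#' @return area in mm^2.
#' @examples
#' g <- scan_geometry(1024, 6)
#' lesion_area(lesion_mask(matrix(TRUE, 1024, 1024), g))  # 36 mm^2
#' @export
lesion_area <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  sum(mask$pixels) * (mask$geometry$um_per_px / 1000)^2
}

#' Mean centroid-to-fovea distance in mm
#'
#' Euclidean distance from each focus centroid to the fovea; for multifocal
#' lesions the unweighted mean over foci is returned.
#'
#' @param mask a [lesion_mask()] with at least one focus.
#' @return distance in mm.
#' @export
fovea_distance <- function(mask) {
  stopifnot(inherits(mask, "lesion_mask"))
  foci <- lesion_foci(mask)$foci
  if (nrow(foci) == 0L) stop("lesion mask has no foci")
  g <- mask$geometry
  fx <- (g$fovea_px[1] + 0.5) * g$field_mm / g$grid_px
  fy <- (g$fovea_px[2] + 0.5) * g$field_mm / g$grid_px
  mean(sqrt((foci$cx_mm - fx)^2 + (foci$cy_mm - fy)^2))
}

#' Does the lesion touch the scan border at either visit?
#'
#' Eyes whose atrophy extends beyond the scanned field at either visit have
#' no measurable growth rate and are excluded from yGR analyses.
#'
#' @param mask_t0 baseline [lesion_mask()].
#' @param mask_t1 follow-up [lesion_mask()]; omit to test a single visit.
#' @return logical flag.
#' @export
touches_border <- function(mask_t0, mask_t1 = NULL) {
  on_border <- function(m) {
    p <- m$pixels
    n <- nrow(p)
    any(p[1, ]) || any(p[n, ]) || any(p[, 1]) || any(p[, n])
  }
  stopifnot(inherits(mask_t0, "lesion_mask"))
  out <- on_border(mask_t0)
  if (!is.null(mask_t1)) {
    stopifnot(inherits(mask_t1, "lesion_mask"))
    out <- out || on_border(mask_t1)
  }
  out
}
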