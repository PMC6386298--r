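#' Parameters for structural shadow compensation
#'
#' The compensation multiplies the flow angiogram by the smoothed, inverted
#' structural image, so that CC signal attenuated under drusen (dark in the
#' structural channel) is boosted while normally transmitting regions are
#' left relatively unchanged.
#'
#' @param smooth_kernel_px odd kernel side for the Gaussian smoothing of the
#'   inverted structural image (default 3, i.e. a 3 x 3 kernel).
#' @param sigma_px Gaussian sigma in pixels. The default 0.85 gives the usual
#'   3 x 3 Gaussian approximation once truncated and renormalized.
#' @param rescale min-max rescale the product back to `[0, 1]` (default TRUE).
#' @return An object of class `compensation_params`.
#' @export
compensation_params <- function(smooth_kernel_px = 3L, sigma_px = 0.85,
                                rescale = TRUE) {
  smooth_kernel_px <- as.integer(smooth_kernel_px)
  stopifnot(smooth_kernel_px >= 1L, smooth_kernel_px %% 2L == 1L,
            is.finite(sigma_px), sigma_px > 0, is.logical(rescale))
  structure(list(smooth_kernel_px = smooth_kernel_px, sigma_px = sigma_px,
                 rescale = isTRUE(rescale)),
            class = "compensation_params")
}

#' Parameters for Phansalkar local thresholding
#'
#' Per-pixel threshold `t = m * (1 + p * exp(-q * m) + k * (s / r_norm - 1))`
#' where `m` and `s` are the local mean and (population) standard deviation
#' over a circular window. A pixel is a flow void iff its value is below `t`.
#' The constants default to the original Phansalkar values, which the ImageJ
#' "Auto Local Threshold" plugin also uses; only the radius is typically
#' tuned (15 px on the native 1024-px grid, about 88 um).
#'
#' @param radius_px circular window radius in pixels (default 15).
#' @param k,r_norm,p,q Phansalkar constants (defaults 0.25, 0.5, 2, 10).
#' @return An object of class `binarization_params`.
#' @export
binarization_params <- function(radius_px = 15L, k = 0.25, r_norm = 0.5,
                                p = 2.0, q = 10.0) {
  radius_px <- as.integer(radius_px)
  stopifnot(radius_px >= 1L,
            is.finite(k), is.finite(r_norm), r_norm > 0,
            is.finite(p), is.finite(q))
  structure(list(radius_px = radius_px, k = k, r_norm = r_norm, p = p, q = q),
            class = "binarization_params")
}

#' Separable Gaussian convolution with mirror padding
#'
#' Truncated, renormalized 1-D Gaussian applied along rows then columns,
#' with symmetric (mirror) boundary handling. Deterministic and exact for a
#' given kernel, unlike FFT-based convolution.
#'
#' @param x numeric matrix.
#' @param sigma_px Gaussian sigma in pixels.
#' @param kernel_px odd kernel length; default truncates at about 3 sigma.
#' @return numeric matrix, same size as `x`.
#' @keywords internal
gauss_blur <- function(x, sigma_px, kernel_px = 2L * ceiling(3 * sigma_px) + 1L) {
  stopifnot(kernel_px %% 2L == 1L)
  half <- (kernel_px - 1L) %/% 2L
  kk <- exp(-(seq(-half, half))^2 / (2 * sigma_px^2))
  kk <- kk / sum(kk)
  n <- nrow(x); m <- ncol(x)
  if (half == 0L) return(x)
  mirror <- function(i, n) {
    i <- ifelse(i < 1L, 1L - i, i)
    ifelse(i > n, 2L * n + 1L - i, i)
  }
  # rows (vertical pass)
  out <- matrix(0, n, m)
  for (t in seq_along(kk)) {
    rows <- mirror(seq_len(n) + (t - 1L - half), n)
    out <- out + kk[t] * x[rows, , drop = FALSE]
  }
  # columns (horizontal pass)
  res <- matrix(0, n, m)
  for (t in seq_along(kk)) {
    cols <- mirror(seq_len(m) + (t - 1L - half), m)
    res <- res + kk[t] * out[, cols, drop = FALSE]
  }
  res
}

#' Compensate the CC angiogram for structural shadowing
#'
#' Returns `flow * G(1 - structure)` where `G` is Gaussian smoothing with the
#' configured kernel: the structural channel is inverted on the normalized
#' scale, smoothed to suppress speckle, and multiplied into the flow channel.
#' Dark (shadowed) structural regions thereby receive a larger multiplier
#' than bright ones, compensating drusen shadow in the angiogram. With
#' `rescale = TRUE` the product is min-max rescaled to `[0, 1]`; if the
#' product is constant (degenerate rescale) the flow image is returned
#' unchanged.
#'
#' @param flow [en_face_image()] of modality `"flow"`.
#' @param structure [en_face_image()] of modality `"structure"`.
#' @param params a [compensation_params()].
#' @return An [en_face_image()] of modality `"flow"`.
#' @examples
#' g <- scan_geometry(64, 6)
#' fl <- en_face_image(matrix(0.4, 64, 64), g, "flow")
#' st <- en_face_image(matrix(0.3, 64, 64), g, "structure")
#' comp <- compensate(fl, st, compensation_params(rescale = FALSE))
#' comp$pixels[1, 1]  # 0.4 * (1 - 0.3) = 0.28
#' @export
compensate <- function(flow, structure, params = compensation_params()) {
  stopifnot(inherits(flow, "en_face_image"), inherits(structure, "en_face_image"),
            inherits(params, "compensation_params"))
  if (flow$modality != "flow" || structure$modality != "structure")
    stop("compensate() expects a flow image and a structure image, in that order")
  if (!identical(dim(flow$pixels), dim(structure$pixels)))
    stop("flow and structure images differ in shape")
  if (!same_geometry(flow$geometry, structure$geometry))
    stop("flow and structure images differ in scan geometry")
  inv <- gauss_blur(1 - structure$pixels, params$sigma_px,
                    kernel_px = params$smooth_kernel_px)
  comp <- flow$pixels * inv
  if (params$rescale) {
    rng <- range(comp)
    if (diff(rng) <= .Machine$double.eps) {
      # constant product: min-max rescale undefined; pass flow through
      return(en_face_image(flow$pixels, flow$geometry, "flow"))
    }
    comp <- (comp - rng[1]) / (rng[2] - rng[1])
  }
  comp[comp < 0] <- 0
  comp[comp > 1] <- 1
  en_face_image(comp, flow$geometry, "flow")
}

#' Phansalkar local threshold surface
#'
#' The per-pixel threshold `m * (1 + p * exp(-q * m) + k * (s / r_norm - 1))`
#' with `m`, `s` the local circular-window mean and standard deviation
#' (mirror padding at the border). Exposed separately from
#' [phansalkar_binarize()] for inspection and testing.
#'
#' @param pixels numeric matrix in `[0, 1]`.
#' @param params a [binarization_params()].
#' @return numeric matrix of thresholds.
#' @export
phansalkar_threshold <- function(pixels, params = binarization_params()) {
  stopifnot(is.matrix(pixels), inherits(params, "binarization_params"))
  if (params$radius_px > floor(min(dim(pixels)) / 2))
    stop("binarization radius exceeds half the image side")
  st <- cc_local_stats(pixels, params$radius_px)
  m <- st$mean
  s <- st$sd
  m * (1 + params$p * exp(-params$q * m) + params$k * (s / params$r_norm - 1))
}

#' Binarize a compensated angiogram into a flow-void map
#'
#' Applies Phansalkar local thresholding: a pixel is a flow void iff its
#' intensity is strictly below the local threshold (dark pixels = signal
#' voids in the CC flow).
#'
#' @param image an [en_face_image()] with values in `[0, 1]`.
#' @param params a [binarization_params()].
#' @return An object of class `binary_flow_map` with fields `voids` (logical
#'   matrix, `TRUE` = void), `geometry` and `params`.
#' @export
phansalkar_binarize <- function(image, params = binarization_params()) {
  stopifnot(inherits(image, "en_face_image"))
  thr <- phansalkar_threshold(image$pixels, params)
  structure(list(voids = image$pixels < thr,
                 geometry = image$geometry,
                 params = params),
            class = "binary_flow_map")
}

#' @export
print.binary_flow_map <- function(x, ...) {
  cat(sprintf("<binary_flow_map> %d x %d px, %.1f%% voids (Phansalkar r=%d)\n",
              nrow(x$voids), ncol(x$voids), 100 * mean(x$voids),
              x$params$radius_px))
  invisible(x)
}
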