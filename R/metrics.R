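#' Flow-void percentage inside a region
#'
#' `100 * (void pixels in region) / (region pixels)` — the binarized-map
#' equivalent of counting dark particles as a percentage of the analysed
#' area.
#'
#' @param voids a `binary_flow_map` from [phansalkar_binarize()].
#' @param region logical matrix selecting the region pixels.
#' @param region_name used in error messages (default deparsed argument).
#' @return percentage in `[0, 100]`.
#' @export
fv_percentage <- function(voids, region,
                          region_name = deparse(substitute(region))) {
  stopifnot(inherits(voids, "binary_flow_map"), is.matrix(region))
  if (is.numeric(region)) region <- region > 0.5
  if (!identical(dim(voids$voids), dim(region)))
    stop("void map and region mask differ in shape")
  n <- sum(region)
  if (n == 0L) stop(sprintf("region '%s' is empty", region_name))
  100 * sum(voids$voids & region) / n
}

#' Square-root-transformed yearly growth rate of GA
#'
#' `(sqrt(GA_II) - sqrt(GA_I)) / FU` in mm/yr, with areas in mm^2 and
#' follow-up in years. The square-root transform removes the dependence of
#' growth rates on baseline lesion size (a disc growing at constant edge
#' speed `v` has yGR = sqrt(pi) * v for any baseline radius). Negative
#' values (shrinking areas) are returned as-is, not clamped.
#'
#' @param ga_i baseline GA area, mm^2 (>= 0).
#' @param ga_ii follow-up GA area, mm^2 (>= 0).
#' @param fu follow-up time, years (> 0).
#' @return growth rate in mm/yr (vectorized).
#' @examples
#' compute_ygr(1, 4, 1)          # 1
#' compute_ygr(0.8, 1.63, 1.31)  # 0.2918
#' @export
compute_ygr <- function(ga_i, ga_ii, fu) {
  if (any(fu <= 0)) stop("follow-up time must be positive")
  if (any(ga_i < 0) || any(ga_ii < 0)) stop("areas must be non-negative")
  (sqrt(ga_ii) - sqrt(ga_i)) / fu
}

#' Analyse one eye end-to-end
#'
#' Runs the full per-eye pipeline on co-registered baseline inputs:
#' compensation of the baseline angiogram, Phansalkar binarization, ring
#' regions built on the baseline mask, the three flow-void percentages and
#' their difference, lesion areas at both visits, the square-root yearly
#' growth rate, the centroid-to-fovea distance, and the border-exclusion
#' flag (either visit). Flow-void metrics are baseline-visit quantities.
#'
#' @param flow,structure baseline [en_face_image()]s.
#' @param mask_t0,mask_t1 [lesion_mask()]s at baseline and follow-up.
#' @param fu_years follow-up time in years.
#' @param eye_id,patient_id identifiers carried into the record.
#' @param age patient age in years (optional covariate, `NA` if unknown).
#' @param comp_params a [compensation_params()].
#' @param bin_params a [binarization_params()].
#' @param ring_widths_um ring widths in um (default `c(500, 500)`).
#' @param fv_out_mode `"subsume-rings"` (default: FV_OUT over all non-lesion
#'   pixels) or `"exclude-rings"` (FV_OUT over pixels beyond 1000 um only).
#' @return one-row `data.frame` (an eye record) with columns `eye_id`,
#'   `patient_id`, `age`, `GA_I`, `GA_II`, `FU`, `yGR`, `FV_OUT`, `FV_500`,
#'   `FV_1000`, `dFV`, `FV_OUT_beyond`, `fovea_dist`, `excluded_border`.
#' @export
analyze_eye <- function(flow, structure, mask_t0, mask_t1, fu_years,
                        eye_id = "eye", patient_id = eye_id, age = NA_real_,
                        comp_params = compensation_params(),
                        bin_params = binarization_params(),
                        ring_widths_um = c(500, 500),
                        fv_out_mode = c("subsume-rings", "exclude-rings")) {
  fv_out_mode <- match.arg(fv_out_mode)
  rec <- try({
    comp <- compensate(flow, structure, comp_params)
    bin <- phansalkar_binarize(comp, bin_params)
    reg <- build_regions(mask_t0, ring_widths_um)
    fv_out_all <- fv_percentage(bin, reg$outside, "outside")
    fv_out_beyond <- if (any(reg$beyond))
      fv_percentage(bin, reg$beyond, "beyond-rings") else NA_real_
    fv_500 <- fv_percentage(bin, reg$para, "para-atrophy")
    fv_1000 <- fv_percentage(bin, reg$peri, "peri-atrophy")
    ga_i <- lesion_area(mask_t0)
    ga_ii <- lesion_area(mask_t1)
    data.frame(
      eye_id = eye_id, patient_id = patient_id, age = age,
      GA_I = ga_i, GA_II = ga_ii, FU = fu_years,
      yGR = compute_ygr(ga_i, ga_ii, fu_years),
      FV_OUT = if (fv_out_mode == "subsume-rings") fv_out_all else fv_out_beyond,
      FV_500 = fv_500, FV_1000 = fv_1000,
      dFV = fv_500 - fv_1000,
      FV_OUT_beyond = fv_out_beyond,
      fovea_dist = fovea_distance(mask_t0),
      excluded_border = touches_border(mask_t0, mask_t1),
      stringsAsFactors = FALSE
    )
  }, silent = TRUE)
  if (inherits(rec, "try-error"))
    stop(sprintf("eye '%s': %s", eye_id, attr(rec, "condition")$message))
  rec
}
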