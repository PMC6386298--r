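#' Read an en-face image from TIFF or PNG
#'
#' 8- and 16-bit grayscale sources are normalized to `[0, 1]` by their
#' nominal maxima (the tiff/png readers already return that scale); RGB(A)
#' sources are reduced to their first channel.
#'
#' @param path file path, `.tif`/`.tiff` or `.png`.
#' @param geometry a [scan_geometry()] describing the grid.
#' @param modality `"flow"` or `"structure"`.
#' @return an [en_face_image()].
#' @export
read_en_face <- function(path, geometry, modality = c("flow", "structure")) {
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("missing image file: ", path)
  px <- read_gray(path)
  en_face_image(px, geometry, modality)
}

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(px)) == 3L) px <- px[, , 1]
  px
}

#' Read a binary lesion mask from PNG
#'
#' @param path PNG path (white/255 = lesion).
#' @param geometry a [scan_geometry()].
#' @return a [lesion_mask()].
#' @export
read_mask <- function(path, geometry) {
  if (!file.exists(path)) stop("missing mask file: ", path)
  lesion_mask(read_gray(path) > 0.5, geometry)
}

#' Write a region set as an indexed label map for QC
#'
#' Grayscale PNG with levels 0 = lesion, 1/3 = para ring, 2/3 = peri ring,
#' 1 = beyond.
#'
#' @param regions a `region_set`.
#' @param path output PNG path.
#' @return the path, invisibly.
#' @export
write_region_map <- function(regions, path) {
  lab <- matrix(1, nrow(regions$outside), ncol(regions$outside))
  lab[!regions$outside] <- 0
  lab[regions$para] <- 1 / 3
  lab[regions$peri] <- 2 / 3
  png::writePNG(lab, path)
  invisible(path)
}

# QC overlay: binarized map as grayscale (voids black), lesion tinted green,
# para ring red, peri ring blue
write_qc_overlay <- function(voids, regions, path) {
  base <- 1 - voids$voids * 1
  r <- base; g <- base; b <- base
  g[!regions$outside] <- 0.2 + 0.8 * g[!regions$outside]
  r[regions$para] <- 0.5 + 0.5 * r[regions$para]
  b[regions$peri] <- 0.5 + 0.5 * b[regions$peri]
  png::writePNG(array(c(r, g, b), c(dim(base), 3L)), path)
  invisible(path)
}

# stable short fingerprint of a parameter list (provenance convenience;
# the manifest also stores the full parameters)
config_fingerprint <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10,
                                     force = TRUE))
  v <- utf8ToInt(s)
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Write a generated cohort to disk
#'
#' Per eye: `<eye>_struct.tif` and `<eye>_flow.tif` (16-bit grayscale TIFF),
#' `<eye>_mask_t0.png` and `<eye>_mask_t1.png` (binary PNG, white = lesion);
#' plus `cohort.csv`, `truth.csv` and a `geometry.json` sidecar with
#' `grid_px`, `field_mm`, `um_per_px` and the fovea position.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  for (eye in cohort$eyes) {
    id <- eye$eye_id
    tiff::writeTIFF(eye$structure$pixels,
                    file.path(dir, paste0(id, "_struct.tif")),
                    bits.per.sample = 16)
    tiff::writeTIFF(eye$flow$pixels,
                    file.path(dir, paste0(id, "_flow.tif")),
                    bits.per.sample = 16)
    png::writePNG(eye$mask_t0$pixels * 1,
                  file.path(dir, paste0(id, "_mask_t0.png")))
    png::writePNG(eye$mask_t1$pixels * 1,
                  file.path(dir, paste0(id, "_mask_t1.png")))
  }
  write.csv(cohort$cohort, file.path(dir, "cohort.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  g <- cohort$geometry
  jsonlite::write_json(list(grid_px = g$grid_px, field_mm = g$field_mm,
                            um_per_px = g$um_per_px,
                            fovea_x_px = g$fovea_px[1],
                            fovea_y_px = g$fovea_px[2]),
                       file.path(dir, "geometry.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Simulate a cohort straight to disk
#'
#' Thin wrapper over [generate_cohort()] + [write_cohort_dir()] that prints
#' a dataset summary.
#'
#' @param dir output directory.
#' @param config a [synthetic_config()].
#' @param quiet suppress the summary line.
#' @return the cohort object, invisibly.
#' @export
simulate_cohort_dir <- function(dir, config = synthetic_config(),
                                quiet = FALSE) {
  cohort <- generate_cohort(config, dir = dir)
  if (!quiet) {
    message(sprintf(
      "wrote %d eyes of %d patients to %s (grid %d px / %.1f mm, seed %d)",
      nrow(cohort$cohort), length(unique(cohort$cohort$patient_id)), dir,
      config$grid_px, config$field_mm, config$seed))
  }
  invisible(cohort)
}

#' Analyse a cohort directory end-to-end
#'
#' Reads `geometry.json` and `cohort.csv`, runs [analyze_eye()] for every
#' eye (baseline flow + structure TIFFs, masks at both visits), and writes
#' `results.csv` plus a JSON run manifest with all parameters and a config
#' fingerprint (every result row carries the fingerprint). Optional QC
#' overlay PNGs show the ring regions over the binarized void map.
#'
#' @param input_dir directory produced by [write_cohort_dir()] (or
#'   organized the same way).
#' @param output_dir where to write results (default `input_dir`).
#' @param comp_params a [compensation_params()].
#' @param bin_params a [binarization_params()].
#' @param ring_widths_um ring widths in um.
#' @param fv_out_mode `"subsume-rings"` or `"exclude-rings"` (see
#'   [analyze_eye()]).
#' @param skip_bad_eyes if `TRUE`, an eye-level hard error drops that eye
#'   with a warning instead of aborting the run.
#' @param qc write per-eye QC overlay PNGs.
#' @param quiet suppress per-eye progress messages.
#' @return data.frame of eye records (also written to
#'   `output_dir/results.csv`).
#' @export
analyze_cohort_dir <- function(input_dir, output_dir = input_dir,
                               comp_params = compensation_params(),
                               bin_params = binarization_params(),
                               ring_widths_um = c(500, 500),
                               fv_out_mode = "subsume-rings",
                               skip_bad_eyes = FALSE,
                               qc = FALSE, quiet = TRUE) {
  geo_path <- file.path(input_dir, "geometry.json")
  coh_path <- file.path(input_dir, "cohort.csv")
  if (!file.exists(geo_path)) stop("missing geometry sidecar: ", geo_path)
  if (!file.exists(coh_path)) stop("missing cohort table: ", coh_path)
  gj <- jsonlite::read_json(geo_path, simplifyVector = TRUE)
  geometry <- scan_geometry(gj$grid_px, gj$field_mm,
                            c(gj$fovea_x_px, gj$fovea_y_px))
  cohort <- read.csv(coh_path, stringsAsFactors = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  params <- list(comp = unclass(comp_params), bin = unclass(bin_params),
                 ring_widths_um = ring_widths_um, fv_out_mode = fv_out_mode)
  fp <- config_fingerprint(params)
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$eye_id[i]
    t_eye <- system.time({
      rec <- try({
        flow <- read_en_face(file.path(input_dir, paste0(id, "_flow.tif")),
                             geometry, "flow")
        struct <- read_en_face(file.path(input_dir, paste0(id, "_struct.tif")),
                               geometry, "structure")
        m0 <- read_mask(file.path(input_dir, paste0(id, "_mask_t0.png")),
                        geometry)
        m1 <- read_mask(file.path(input_dir, paste0(id, "_mask_t1.png")),
                        geometry)
        r <- analyze_eye(flow, struct, m0, m1, cohort$fu_years[i],
                         eye_id = id, patient_id = cohort$patient_id[i],
                         age = if ("age" %in% names(cohort))
                           cohort$age[i] else NA_real_,
                         comp_params = comp_params, bin_params = bin_params,
                         ring_widths_um = ring_widths_um,
                         fv_out_mode = fv_out_mode)
        if (qc) {
          comp <- compensate(flow, struct, comp_params)
          bin <- phansalkar_binarize(comp, bin_params)
          reg <- build_regions(m0, ring_widths_um)
          write_qc_overlay(bin, reg, file.path(output_dir,
                                               paste0(id, "_qc.png")))
        }
        r
      }, silent = TRUE)
    })
    if (inherits(rec, "try-error")) {
      if (!skip_bad_eyes) stop(attr(rec, "condition")$message)
      warning(sprintf("skipping eye '%s': %s", id,
                      attr(rec, "condition")$message))
      next
    }
    rec$config_hash <- fp
    rows[[i]] <- rec
    if (!quiet)
      message(sprintf("eye %s analysed in %.2f s", id, t_eye[["elapsed"]]))
  }
  results <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  write.csv(results, file.path(output_dir, "results.csv"), row.names = FALSE)
  jsonlite::write_json(
    c(params, list(config_hash = fp, n_eyes = nrow(results),
                   input_dir = input_dir)),
    file.path(output_dir, "run_manifest.json"), auto_unbox = TRUE,
    digits = NA)
  results
}

#' Cohort-level statistics on per-eye results
#'
#' Excludes border-truncated eyes, computes Pearson correlations between
#' yGR and each flow-void measure, then the univariable GEE screen and
#' multivariable model with patients as clusters. When `output_dir` is
#' given, writes `correlations.csv` and `table1.csv` (the screen-then-model
#' report layout).
#'
#' @param results data.frame of eye records (from [analyze_cohort_dir()] or
#'   [analyze_eye()]) or a path to `results.csv`.
#' @param candidates covariates for the GEE screen (default: the study's
#'   seven).
#' @param output_dir optional directory for the CSV reports.
#' @return list with `results` (post-exclusion), `correlations`, `gee`
#'   (a `gee_screen`), `table` (flattened report) and `n_excluded`.
#' @export
cohort_stats <- function(results,
                         candidates = c("age", "GA_I", "fovea_dist",
                                        "FV_500", "FV_1000", "FV_OUT", "dFV"),
                         output_dir = NULL) {
  if (is.character(results)) results <- read.csv(results,
                                                 stringsAsFactors = FALSE)
  stopifnot(is.data.frame(results))
  n0 <- nrow(results)
  if ("excluded_border" %in% names(results))
    results <- results[!results$excluded_border, , drop = FALSE]
  if (nrow(results) < 3) stop("fewer than 3 eyes after border exclusion")
  candidates <- intersect(candidates, names(results))
  candidates <- candidates[vapply(candidates, function(v)
    sd(results[[v]]) > 0, TRUE)]
  fvs <- intersect(c("FV_OUT", "FV_500", "FV_1000", "dFV"), names(results))
  correlations <- do.call(rbind, lapply(fvs, function(v) {
    pr <- pearson(results[[v]], results$yGR)
    data.frame(measure = v, r = pr$r, p = pr$p, n = pr$n,
               stringsAsFactors = FALSE)
  }))
  screen <- gee_screen_and_model(results, candidates)
  tab <- format_regression_table(screen)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(correlations, file.path(output_dir, "correlations.csv"),
              row.names = FALSE)
    write.csv(tab, file.path(output_dir, "table1.csv"), row.names = FALSE)
  }
  list(results = results, correlations = correlations, gee = screen,
       table = tab, n_excluded = n0 - nrow(results))
}

#' Load a run configuration from YAML with defaults
#'
#' Missing fields fall back to package defaults; unknown fields are an
#' error. The configuration mirrors the function arguments: geometry
#' defaults, compensation and binarization parameters, ring widths, the
#' FV_OUT variant, stats candidates and the generator seed.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides named list applied on top of the file (CLI-style).
#' @return list with elements `generator` (arguments for
#'   [synthetic_config()]), `comp`, `bin`, `ring_widths_um`, `fv_out_mode`,
#'   `candidates`, `seed`.
#' @export
run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(generator = list(), comp = list(), bin = list(),
              ring_widths_um = c(500, 500), fv_out_mode = "subsume-rings",
              candidates = c("age", "GA_I", "fovea_dist", "FV_500",
                             "FV_1000", "FV_OUT", "dFV"),
              seed = 1L)
  apply_over <- function(base, new, where) {
    for (nm in names(new)) {
      if (!nm %in% names(base))
        stop("unknown config field '", nm, "' in ", where)
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]]))
        utils::modifyList(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("missing config file: ", path)
    cfg <- apply_over(cfg, yaml::read_yaml(path), path)
  }
  cfg <- apply_over(cfg, overrides, "overrides")
  if (any(cfg$ring_widths_um <= 0)) stop("ring widths must be positive")
  cfg
}
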