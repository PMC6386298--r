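#' Configuration for the synthetic en-face OCTA cohort generator
#'
#' Defaults emulate the study conditions of a GA cohort imaged with 6 x 6 mm
#' fovea-centred scans: ~33 eyes of 23 patients (each patient bilateral with
#' probability 10/23), follow-up 1.31 +/- 0.2 years (floored at 1 year), a
#' baseline choriocapillaris void fraction of 0.42 with voids decreasing by
#' 0.8 percentage points per 500 um of distance from the fovea, lesion areas
#' log-normal around a 0.8 mm^2 median, and a peri-lesional void excess drawn
#' uniformly from `ring_excess_range` whose magnitude drives the lesion's
#' edge-growth speed through `growth_coupling`.
#'
#' @param n_patients number of patients (default 23).
#' @param bilateral_prob probability a patient contributes both eyes
#'   (default 10/23, giving 33 expected eyes from 23 patients).
#' @param grid_px pixels per side (default 1024).
#' @param field_mm physical side, mm (default 6).
#' @param seed RNG seed; each eye derives its own stream from
#'   `(seed, eye index)`.
#' @param base_void_frac void probability at the fovea absent any lesion
#'   effect (default 0.42).
#' @param eccentricity_gradient change in void fraction per 500 um of fovea
#'   distance (default -0.008: voids decrease away from the fovea).
#' @param ring_excess_range range of the extra void fraction in the
#'   para-atrophy band (default `c(0, 0.10)`). The excess holds its full
#'   value from the lesion edge to 500 um and tapers linearly to 0 at
#'   1000 um.
#' @param growth_coupling edge-growth speed per unit ring excess, mm/yr
#'   (default 4: an excess of 0.05 adds 0.2 mm/yr).
#' @param speed_noise_sd SD of the non-coupled component of edge speed,
#'   mm/yr (default 0.02).
#' @param drusen_density drusen per mm^2 (default 3).
#' @param drusen_shadow_depth fractional structural darkening under a druse
#'   (default 0.3).
#' @param drusen_radius_um druse radius range in um (default `c(30, 80)`).
#' @param followup_mean,followup_sd follow-up time distribution in years
#'   (default 1.31 +/- 0.2, floored at 1, matching a >= 12-month
#'   requirement).
#' @param speckle_grain_um grain size of the granular CC texture (default
#'   25 um, the scale of choriocapillaris lobules/intercapillary spacing).
#' @param lesion_area_median_mm2,lesion_area_sdlog,lesion_area_max_mm2
#'   log-normal baseline lesion area (median 0.8 mm^2, sdlog 1, capped at
#'   8 mm^2 so lesions rarely clip the field).
#' @param multifocal_probs probabilities of 1, 2 or 3 foci (default
#'   `c(0.7, 0.2, 0.1)`).
#' @param fovea_dist_mean,fovea_dist_sd lesion centroid placement: distance
#'   from the fovea is `|N(mean, sd)|` mm (default 0.86 +/- 0.54).
#' @param age_mean,age_sd patient age distribution (default 84.67 +/- 6.42).
#' @param void_level,signal_level flow intensity of void vs perfused pixels
#'   (defaults 0.30 and 0.85).
#' @param struct_level unshadowed structural intensity (default 0.85).
#' @param noise_sd per-pixel additive intensity noise SD (default 0.05).
#' @param illum_amp amplitude of the smooth illumination field (default
#'   0.05).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 23L,
                             bilateral_prob = 10 / 23,
                             grid_px = 1024L,
                             field_mm = 6,
                             seed = 1L,
                             base_void_frac = 0.42,
                             eccentricity_gradient = -0.008,
                             ring_excess_range = c(0, 0.10),
                             growth_coupling = 4,
                             speed_noise_sd = 0.02,
                             drusen_density = 3,
                             drusen_shadow_depth = 0.3,
                             drusen_radius_um = c(30, 80),
                             followup_mean = 1.31,
                             followup_sd = 0.2,
                             speckle_grain_um = 25,
                             lesion_area_median_mm2 = 0.8,
                             lesion_area_sdlog = 1.0,
                             lesion_area_max_mm2 = 8,
                             multifocal_probs = c(0.7, 0.2, 0.1),
                             fovea_dist_mean = 0.86,
                             fovea_dist_sd = 0.54,
                             age_mean = 84.67,
                             age_sd = 6.42,
                             void_level = 0.30,
                             signal_level = 0.85,
                             struct_level = 0.85,
                             noise_sd = 0.05,
                             illum_amp = 0.05) {
  cfg <- list(n_patients = as.integer(n_patients),
              bilateral_prob = bilateral_prob, grid_px = as.integer(grid_px),
              field_mm = field_mm, seed = as.integer(seed),
              base_void_frac = base_void_frac,
              eccentricity_gradient = eccentricity_gradient,
              ring_excess_range = ring_excess_range,
              growth_coupling = growth_coupling,
              speed_noise_sd = speed_noise_sd,
              drusen_density = drusen_density,
              drusen_shadow_depth = drusen_shadow_depth,
              drusen_radius_um = drusen_radius_um,
              followup_mean = followup_mean, followup_sd = followup_sd,
              speckle_grain_um = speckle_grain_um,
              lesion_area_median_mm2 = lesion_area_median_mm2,
              lesion_area_sdlog = lesion_area_sdlog,
              lesion_area_max_mm2 = lesion_area_max_mm2,
              multifocal_probs = multifocal_probs,
              fovea_dist_mean = fovea_dist_mean,
              fovea_dist_sd = fovea_dist_sd,
              age_mean = age_mean, age_sd = age_sd,
              void_level = void_level, signal_level = signal_level,
              struct_level = struct_level, noise_sd = noise_sd,
              illum_amp = illum_amp)
  with(cfg, {
    stopifnot(n_patients >= 1L, grid_px > 0L, field_mm > 0,
              bilateral_prob >= 0, bilateral_prob <= 1,
              base_void_frac >= 0, base_void_frac <= 1,
              drusen_shadow_depth >= 0, drusen_shadow_depth <= 1,
              all(ring_excess_range >= 0), all(ring_excess_range <= 1),
              diff(ring_excess_range) >= 0,
              followup_mean >= 1.0,
              void_level >= 0, signal_level <= 1, void_level < signal_level)
  })
  structure(cfg, class = "synthetic_config")
}

#' Grow a lesion mask isotropically
#'
#' Every background pixel whose exact Euclidean distance to the lesion is at
#' most `speed * years` (mm) becomes lesion: a disc of radius R grows to
#' radius `R + speed * years`, and nearby foci merge once their edge gap is
#' covered. For discs this gives `yGR = sqrt(pi) * speed` independent of
#' baseline radius.
#'
#' @param mask a [lesion_mask()].
#' @param speed edge speed in mm/yr (>= 0).
#' @param years elapsed time in years (>= 0).
#' @return a grown [lesion_mask()].
#' @export
grow_mask <- function(mask, speed, years) {
  stopifnot(inherits(mask, "lesion_mask"), speed >= 0, years >= 0)
  delta_um <- speed * years * 1000
  if (delta_um == 0 || !any(mask$pixels)) return(mask)
  d <- lesion_distance_map_um(mask)
  lesion_mask(mask$pixels | d <= delta_um, mask$geometry)
}

# rasterize one rotated ellipse (axes in mm, pixel-centre inclusion test)
ellipse_pixels <- function(geometry, cx_mm, cy_mm, a_mm, b_mm, theta) {
  co <- pixel_coords_mm(geometry)
  dx <- co$x_mm - cx_mm
  dy <- co$y_mm - cy_mm
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a_mm)^2 + (v / b_mm)^2 <= 1
}

# smooth low-order illumination field with unit mean and given amplitude
illumination_field <- function(n, amp) {
  x <- matrix(seq(-1, 1, length.out = n), n, n, byrow = TRUE)
  y <- matrix(seq(-1, 1, length.out = n), n, n, byrow = FALSE)
  cf <- rnorm(5)
  f <- cf[1] * x + cf[2] * y + cf[3] * x * y + cf[4] * (x^2 - 1 / 3) +
    cf[5] * (y^2 - 1 / 3)
  s <- stats::sd(f)
  if (s > 0) f <- f / s
  1 + amp * f
}

# drusen shadow weight field: 1 away from drusen, (1 - depth) under a druse,
# Gaussian-feathered edges; darkening acts multiplicatively on both channels
drusen_shadow_field <- function(geometry, density_per_mm2, depth,
                                radius_um_range) {
  n <- geometry$grid_px
  n_dr <- rpois(1, density_per_mm2 * geometry$field_mm^2)
  ind <- matrix(0, n, n)
  if (n_dr > 0) {
    px_um <- geometry$um_per_px
    cx <- runif(n_dr, 1, n)
    cy <- runif(n_dr, 1, n)
    r_px <- runif(n_dr, radius_um_range[1], radius_um_range[2]) / px_um
    for (i in seq_len(n_dr)) {
      lo_r <- max(1L, floor(cy[i] - r_px[i])); hi_r <- min(n, ceiling(cy[i] + r_px[i]))
      lo_c <- max(1L, floor(cx[i] - r_px[i])); hi_c <- min(n, ceiling(cx[i] + r_px[i]))
      if (lo_r > hi_r || lo_c > hi_c) next
      rr <- lo_r:hi_r; cc <- lo_c:hi_c
      d2 <- outer((rr - cy[i])^2, (cc - cx[i])^2, "+")
      blk <- ind[rr, cc]
      blk[d2 <= r_px[i]^2] <- 1
      ind[rr, cc] <- blk
    }
    feather_px <- max(0.75, 10 / px_um)  # ~10 um edge feather
    ind <- gauss_blur(ind, feather_px)
    ind[ind > 1] <- 1
    ind[ind < 0] <- 0
  }
  1 - depth * ind
}

# per-eye stream: deterministic small-integer seed from (cohort seed, index)
derive_eye_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + as.double(index) * 104729) %%
               2147483629)
}

# void-probability field: base + eccentricity gradient + peri-lesional
# excess (plateau to 500 um, linear taper to 0 at 1000 um); inside the
# lesion the CC is additionally impaired (not used by any outside metric)
void_probability_field <- function(cfg, geometry, mask_t0, excess) {
  d_fov <- fovea_distance_map_um(geometry)
  p <- cfg$base_void_frac + cfg$eccentricity_gradient * d_fov / 500
  if (any(mask_t0$pixels)) {
    d_les <- lesion_distance_map_um(mask_t0)
    prof <- ifelse(d_les <= 500, excess,
                   ifelse(d_les <= 1000, excess * (1000 - d_les) / 500, 0))
    p <- p + prof
    p[mask_t0$pixels] <- cfg$base_void_frac + 0.25
  }
  pmin(pmax(p, 0.02), 0.95)
}

# granular texture: rank-normalized band-pass (difference-of-Gaussians)
# white noise; thresholding it against the probability field plants voids
# with the requested local fraction and a controllable grain size
granular_uniform_field <- function(n, grain_px) {
  z <- matrix(rnorm(n * n), n, n)
  s_small <- max(0.5, grain_px / 3)
  s_large <- max(1.0, grain_px)
  g <- gauss_blur(z, s_small) - gauss_blur(z, s_large)
  matrix(rank(g, ties.method = "first") / (n * n + 1), n, n)
}

quantize16 <- function(x) round(x * 65535) / 65535

# generate one synthetic eye: images, masks at both visits, truth row
generate_eye <- function(cfg, eye_seed, eye_id, patient_id, age) {
  set.seed(eye_seed)
  g <- scan_geometry(cfg$grid_px, cfg$field_mm)
  n <- g$grid_px
  fx_mm <- (g$fovea_px[1] + 0.5) * g$field_mm / n
  fy_mm <- (g$fovea_px[2] + 0.5) * g$field_mm / n

  # --- baseline lesion: 1-3 elliptical foci near the fovea
  n_foci <- sample.int(3L, 1L, prob = cfg$multifocal_probs)
  total_area <- exp(rnorm(1, log(cfg$lesion_area_median_mm2),
                          cfg$lesion_area_sdlog))
  total_area <- min(max(total_area, 0.11), cfg$lesion_area_max_mm2)
  wts <- rgamma(n_foci, 2)
  areas <- total_area * wts / sum(wts)
  mpx <- matrix(FALSE, n, n)
  for (f in seq_len(n_foci)) {
    dist_mm <- min(abs(rnorm(1, cfg$fovea_dist_mean, cfg$fovea_dist_sd)),
                   g$field_mm / 2 - 0.6)
    ang <- runif(1, 0, 2 * pi)
    cx <- fx_mm + dist_mm * cos(ang)
    cy <- fy_mm + dist_mm * sin(ang)
    ratio <- runif(1, 0.6, 1)
    a_mm <- sqrt(areas[f] / (pi * ratio))
    b_mm <- a_mm * ratio
    mpx <- mpx | ellipse_pixels(g, cx, cy, a_mm, b_mm, runif(1, 0, pi))
  }
  mask_t0 <- lesion_mask(mpx, g)

  # --- growth coupled to the peri-lesional void excess
  excess <- runif(1, cfg$ring_excess_range[1], cfg$ring_excess_range[2])
  speed <- max(0, cfg$growth_coupling * excess + rnorm(1, 0, cfg$speed_noise_sd))
  fu <- max(1, rnorm(1, cfg$followup_mean, cfg$followup_sd))
  mask_t1 <- grow_mask(mask_t0, speed, fu)

  # --- void probability field and granular flow texture
  p_void <- void_probability_field(cfg, g, mask_t0, excess)
  grain_px <- cfg$speckle_grain_um / g$um_per_px
  u <- granular_uniform_field(n, grain_px)
  v <- u < p_void

  illum <- illumination_field(n, cfg$illum_amp)
  shadow <- drusen_shadow_field(g, cfg$drusen_density,
                                cfg$drusen_shadow_depth, cfg$drusen_radius_um)

  # illumination varies the angiogram only: the structural channel is bright
  # and uniform apart from drusen shadow (which hits both channels), so the
  # inverted-structure multiplier compensates shadow without inheriting an
  # amplified copy of the illumination field
  flow_px <- ifelse(v, cfg$void_level, cfg$signal_level) +
    rnorm(n * n, 0, cfg$noise_sd)
  flow_px <- flow_px * illum * shadow
  struct_px <- (cfg$struct_level + rnorm(n * n, 0, 0.02)) * shadow
  flow_px <- quantize16(pmin(pmax(flow_px, 0), 1))
  struct_px <- quantize16(pmin(pmax(struct_px, 0), 1))

  # --- ground truth on the noise-free probability field
  reg <- build_regions(mask_t0)
  foci <- lesion_foci(mask_t0)$foci
  truth <- data.frame(
    eye_id = eye_id, patient_id = patient_id, age = age,
    true_void_frac_out = mean(p_void[reg$outside]),
    true_void_frac_para = mean(p_void[reg$para]),
    true_void_frac_peri = mean(p_void[reg$peri]),
    true_ring_excess = excess,
    true_edge_speed = speed,
    baseline_area = lesion_area(mask_t0),
    followup_area = lesion_area(mask_t1),
    fu_years = fu,
    n_foci = nrow(foci),
    focus_centroids = as.character(jsonlite::toJSON(
      foci[, c("cx_mm", "cy_mm")], digits = NA)),
    border_truncated = touches_border(mask_t0, mask_t1),
    stringsAsFactors = FALSE
  )
  list(eye_id = eye_id, patient_id = patient_id, age = age, fu_years = fu,
       flow = en_face_image(flow_px, g, "flow"),
       structure = en_face_image(struct_px, g, "structure"),
       mask_t0 = mask_t0, mask_t1 = mask_t1,
       truth = truth)
}

#' Generate a synthetic cohort of en-face OCTA eyes with ground truth
#'
#' For every eye produces a granular flow angiogram (band-pass-filtered
#' white noise thresholded against a spatial void-probability field), a
#' bright structural image darkened under randomly placed drusen (with the
#' same darkening multiplied into the flow channel, to be undone by
#' compensation), GA masks at baseline and follow-up (the follow-up mask is
#' the baseline mask grown isotropically by `true_edge_speed * fu_years`),
#' a truth row per eye and a cohort table. Deterministic for a given seed;
#' each eye consumes its own RNG stream derived from `(seed, eye index)`.
#' Eyes whose lesion reaches the scan border at either visit are flagged
#' `border_truncated` in the truth table (the analysis stage excludes them
#' from growth statistics).
#'
#' @param config a [synthetic_config()].
#' @param dir optional directory; when given, images (16-bit TIFF), masks
#'   (PNG, 255 = lesion), `cohort.csv`, `truth.csv` and `geometry.json` are
#'   written there.
#' @return list with `eyes` (list of per-eye bundles: `flow`, `structure`,
#'   `mask_t0`, `mask_t1`, ids), `truth` (data.frame) and `cohort`
#'   (data.frame: `eye_id`, `patient_id`, `age`, `fu_years`, `fovea_x_px`,
#'   `fovea_y_px`).
#' @export
generate_cohort <- function(config = synthetic_config(), dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_eyes_per <- 1L + rbinom(config$n_patients, 1L, config$bilateral_prob)
  ages <- rnorm(config$n_patients, config$age_mean, config$age_sd)
  plan <- do.call(rbind, lapply(seq_len(config$n_patients), function(i) {
    sides <- c("OD", "OS")[seq_len(n_eyes_per[i])]
    data.frame(patient_id = sprintf("P%02d", i),
               eye_id = sprintf("P%02d_%s", i, sides),
               age = ages[i], stringsAsFactors = FALSE)
  }))
  eyes <- vector("list", nrow(plan))
  for (k in seq_len(nrow(plan))) {
    eyes[[k]] <- generate_eye(config, derive_eye_seed(config$seed, k),
                              plan$eye_id[k], plan$patient_id[k], plan$age[k])
  }
  truth <- do.call(rbind, lapply(eyes, `[[`, "truth"))
  g <- eyes[[1]]$flow$geometry
  cohort <- data.frame(
    eye_id = plan$eye_id, patient_id = plan$patient_id, age = plan$age,
    fu_years = vapply(eyes, `[[`, 0.0, "fu_years"),
    fovea_x_px = g$fovea_px[1], fovea_y_px = g$fovea_px[2],
    stringsAsFactors = FALSE
  )
  out <- list(eyes = eyes, truth = truth, cohort = cohort, geometry = g,
              config = config)
  if (!is.null(dir)) write_cohort_dir(out, dir)
  out
}

#' Fast record-level cohort simulator
#'
#' Simulates eye records directly at the measurement level (no images):
#' each eye receives a ring excess from `ring_excess_range`, an edge speed
#' `growth_coupling * excess` plus noise, a yGR of `sqrt(pi) * speed` (the
#' disc identity) plus a shared patient random effect and measurement
#' noise, and a measured dFV proportional to the excess plus measurement
#' noise. Used for statistical calibration studies (type-I error, power,
#' parameter recovery) where running the image pipeline for hundreds of
#' cohorts would add nothing: the quantities under test are properties of
#' the record-level statistics.
#'
#' @param n_patients,bilateral_prob cohort structure (defaults 23, 10/23).
#' @param ring_excess_range,growth_coupling,speed_noise_sd as in
#'   [synthetic_config()].
#' @param patient_sd SD of the shared per-patient yGR effect (default 0.05
#'   mm/yr).
#' @param ygr_noise_sd per-eye yGR measurement noise (default 0.03 mm/yr).
#' @param dfv_scale percentage points of measured dFV per unit ring excess
#'   (default 50: the taper's ring contrast is about half the excess).
#' @param dfv_noise_sd measurement noise on dFV, percentage points
#'   (default 1.5).
#' @param age_mean,age_sd patient age distribution.
#' @param seed RNG seed.
#' @return data.frame of eye records with `eye_id`, `patient_id`, `age`,
#'   `yGR`, `dFV`, `true_ring_excess`, `true_edge_speed`.
#' @export
simulate_cohort_records <- function(n_patients = 23L, bilateral_prob = 10 / 23,
                                    ring_excess_range = c(0, 0.10),
                                    growth_coupling = 4,
                                    speed_noise_sd = 0.02,
                                    patient_sd = 0.05, ygr_noise_sd = 0.03,
                                    dfv_scale = 50, dfv_noise_sd = 1.5,
                                    age_mean = 84.67, age_sd = 6.42,
                                    seed = 1L) {
  set.seed(seed)
  n_eyes_per <- 1L + rbinom(n_patients, 1L, bilateral_prob)
  pat_eff <- rnorm(n_patients, 0, patient_sd)
  ages <- rnorm(n_patients, age_mean, age_sd)
  rows <- lapply(seq_len(n_patients), function(i) {
    m <- n_eyes_per[i]
    e <- runif(m, ring_excess_range[1], ring_excess_range[2])
    speed <- pmax(0, growth_coupling * e + rnorm(m, 0, speed_noise_sd))
    data.frame(
      eye_id = sprintf("P%02d_%s", i, c("OD", "OS")[seq_len(m)]),
      patient_id = sprintf("P%02d", i),
      age = ages[i],
      yGR = sqrt(pi) * speed + pat_eff[i] + rnorm(m, 0, ygr_noise_sd),
      dFV = dfv_scale * e + rnorm(m, 0, dfv_noise_sd),
      true_ring_excess = e,
      true_edge_speed = speed,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
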