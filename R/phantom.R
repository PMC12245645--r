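#' Phantom generator configuration
#'
#' Parameters of the synthetic multispectral coronal head phantom. The
#' phantom emulates the anatomy the localizer is trained on: an "M"-shaped
#' brain curvature traced by minor cortical vessels converging onto a
#' midline dent, the superior sagittal sinus (SSS) as a blood-filled disc
#' at the dent at ~20 mm depth, a skin/skull surface band near the top of
#' the frame, wavelength-dependent exponential light attenuation with
#' depth, and large per-subject variation of anatomy and absolute
#' intensity scale.
#'
#' @param image_h,image_w image size in pixels (depth x width).
#' @param pixel_spacing_mm isotropic pixel spacing.
#' @param sss_depth_mm nominal SSS depth; jittered per subject by
#'   `sss_depth_jitter_mm` (uniform).
#' @param sss_diameter_mm nominal SSS diameter (fetal newborn median
#'   3.6 mm) with per-subject uniform jitter `sss_diameter_jitter_mm`.
#' @param curvature_amplitude_mm height of the curvature shoulders above
#'   the midline dent, jittered by `curvature_amplitude_jitter_mm`.
#' @param curvature_halfwidth_frac lateral distance from midline to the
#'   shoulders, as a fraction of image width.
#' @param midline_jitter_px per-subject lateral jitter of the midline.
#' @param n_cortical_vessels number of minor cortical vessels tracing the
#'   curvature.
#' @param skin_band_depth_mm,skin_band_thickness_mm skin/skull band
#'   geometry.
#' @param noise_sd additive Gaussian noise standard deviation, expressed
#'   as a fraction of the brightest noiseless intensity in the frame;
#'   0 gives the exact noiseless forward model.
#' @param intensity_range per-subject global intensity scale (AU), drawn
#'   log-uniformly; mirrors the raw-intensity span seen across real
#'   acquisitions (~1.75e3 to 2.3e6 AU).
#' @param mu_mm attenuation coefficients (mm^-1) at the band endpoints;
#'   linearly interpolated over wavelength.
#' @param o2sat_start_range,o2sat_floor,o2sat_noise_sd,o2sat_decay_power
#'   venous-trajectory model: O2Satss declines from a healthy start
#'   (45-60%) toward a floor (~5%) as FiO2 is reduced, with Gaussian
#'   reading noise; see [generate_study()].
#' @return object of class `pa_phantom_config`.
#' @export
phantom_config <- function(image_h = 96, image_w = 128,
                           pixel_spacing_mm = 0.3,
                           sss_depth_mm = 20, sss_depth_jitter_mm = 2,
                           sss_diameter_mm = 3.6, sss_diameter_jitter_mm = 0.6,
                           curvature_amplitude_mm = 6,
                           curvature_amplitude_jitter_mm = 1.5,
                           curvature_halfwidth_frac = 0.28,
                           midline_jitter_px = 4,
                           n_cortical_vessels = 14,
                           skin_band_depth_mm = 1.2,
                           skin_band_thickness_mm = 1.2,
                           noise_sd = 0.02,
                           intensity_range = c(1.75e3, 2.3e6),
                           mu_mm = c(0.08, 0.14),
                           o2sat_start_range = c(45, 60),
                           o2sat_floor = 5,
                           o2sat_noise_sd = 3,
                           o2sat_decay_power = 2) {
  cfg <- structure(as.list(environment()), class = "pa_phantom_config")
  stopifnot(cfg$image_h > 0, cfg$image_w > 0, cfg$pixel_spacing_mm > 0,
            cfg$noise_sd >= 0, all(cfg$intensity_range > 0),
            all(cfg$mu_mm > 0), cfg$sss_diameter_mm > 2 * cfg$sss_diameter_jitter_mm)
  max_depth_px <- (cfg$sss_depth_mm + cfg$sss_depth_jitter_mm +
                   (cfg$sss_diameter_mm + cfg$sss_diameter_jitter_mm) / 2) /
    cfg$pixel_spacing_mm
  if (max_depth_px >= cfg$image_h - 1)
    stop("config error: SSS geometry extends below the image frame")
  cfg
}

# Wavelength-dependent attenuation coefficient (mm^-1), linear ramp
# between the band endpoints.
attenuation_mu <- function(cfg, grid) {
  lam <- grid$values
  cfg$mu_mm[1] + (cfg$mu_mm[2] - cfg$mu_mm[1]) *
    (lam - min(lam)) / max(max(lam) - min(lam), 1)
}

#' Generate one subject's anatomy
#'
#' Draws a per-subject anatomical layout from the current RNG stream:
#' curvature amplitude, midline position, SSS depth/diameter jitter,
#' cortical vessel placement along the "M" curve, and the skin band.
#'
#' @param cfg a [phantom_config()].
#' @return object of class `pa_anatomy_map`: `labels` (0 background,
#'   1 skin band, 2 cortical vessel, 3 SSS), `blood_frac`, `o2sat`
#'   (percent; SSS pixels are `NA` until assigned per sample), `sss_xy`
#'   (0-based annotation `c(x, y)`), and the continuous subject geometry.
#' @export
generate_anatomy <- function(cfg = phantom_config()) {
  H <- cfg$image_h; W <- cfg$image_w; sp <- cfg$pixel_spacing_mm
  x_mid <- (W - 1) / 2 + runif(1, -cfg$midline_jitter_px, cfg$midline_jitter_px)
  y_dent <- (cfg$sss_depth_mm +
             runif(1, -cfg$sss_depth_jitter_mm, cfg$sss_depth_jitter_mm)) / sp
  amp <- (cfg$curvature_amplitude_mm +
          runif(1, -cfg$curvature_amplitude_jitter_mm,
                cfg$curvature_amplitude_jitter_mm)) / sp
  halfw <- cfg$curvature_halfwidth_frac * W
  curve_y <- function(x) {
    u <- pmin(pmax((x - x_mid) / (2 * halfw) * 2 * pi, -2 * pi), 2 * pi)
    y_dent - amp * (1 - cos(u)) / 2
  }
  radius <- (cfg$sss_diameter_mm +
             runif(1, -cfg$sss_diameter_jitter_mm, cfg$sss_diameter_jitter_mm)) /
    2 / sp

  labels <- matrix(0L, H, W)
  blood <- matrix(0, H, W)
  o2sat <- matrix(NA_real_, H, W)

  # skin/skull surface band
  y0 <- cfg$skin_band_depth_mm / sp
  y1 <- (cfg$skin_band_depth_mm + cfg$skin_band_thickness_mm) / sp
  band <- which(seq_len(H) - 1 >= y0 & seq_len(H) - 1 < y1)
  if (length(band)) {
    labels[band, ] <- 1L
    blood[band, ] <- 0.15
    o2sat[band, ] <- 90
  }

  # minor cortical vessels along the curvature (kept clear of the dent)
  n_v <- cfg$n_cortical_vessels
  if (n_v > 0) {
    off <- runif(n_v, radius + 2, 2 * halfw) * sample(c(-1, 1), n_v, TRUE)
    vx <- pmin(pmax(x_mid + off, 1), W - 2)
    vy <- curve_y(vx) + rnorm(n_v, 0, 1)
    vr <- runif(n_v, 1, 2)
    vo <- runif(n_v, 55, 95)
    vb <- runif(n_v, 0.4, 0.9)
    xs <- matrix(rep(0:(W - 1), each = H), H, W)
    ys <- matrix(rep(0:(H - 1), W), H, W)
    for (k in seq_len(n_v)) {
      m <- (xs - vx[k])^2 + (ys - vy[k])^2 <= vr[k]^2
      labels[m] <- 2L; blood[m] <- vb[k]; o2sat[m] <- vo[k]
    }
  }

  # SSS disc at the midline dent
  xs <- matrix(rep(0:(W - 1), each = H), H, W)
  ys <- matrix(rep(0:(H - 1), W), H, W)
  sss_mask <- (xs - x_mid)^2 + (ys - y_dent)^2 <= radius^2
  if (!any(sss_mask)) stop("config error: SSS disc contains no pixels")
  labels[sss_mask] <- 3L
  blood[sss_mask] <- 1
  o2sat[sss_mask] <- NA_real_  # assigned per sample

  sss_xy <- c(round(x_mid), round(y_dent))
  if (sss_xy[1] < 0 || sss_xy[1] > W - 1 || sss_xy[2] < 0 || sss_xy[2] > H - 1)
    stop("config error: SSS centre outside the image frame")

  structure(list(labels = labels, blood_frac = blood, o2sat = o2sat,
                 sss_mask = sss_mask, sss_xy = sss_xy,
                 sss_center = c(x_mid, y_dent), sss_radius_px = radius,
                 curve_y = curve_y, cfg = cfg),
            class = "pa_anatomy_map")
}

#' Assign the venous saturation of one time point to the SSS pixels
#'
#' @param anatomy a `pa_anatomy_map`.
#' @param o2satss venous O2Satss in percent.
#' @return the anatomy with SSS pixels carrying `o2satss`.
#' @export
set_sss_o2sat <- function(anatomy, o2satss) {
  stopifnot(inherits(anatomy, "pa_anatomy_map"),
            o2satss >= 0, o2satss <= 100)
  anatomy$o2sat[anatomy$sss_mask] <- o2satss
  anatomy
}

#' Render the multispectral image of an anatomy
#'
#' Forward model: the noiseless intensity at `(y, x)` and wavelength
#' `lambda` is `scale * blood_frac * S(lambda, O2Sat(y, x)) *
#' exp(-mu(lambda) * depth_mm(y))`, where `S` is the reference response
#' blend and `mu` the attenuation ramp. Additive Gaussian noise (clamped
#' at zero so intensities stay non-negative) is scaled by the brightest
#' noiseless pixel; `noise_sd = 0` gives the exact noiseless model.
#'
#' @param anatomy a `pa_anatomy_map` with O2Sat assigned on all perfused
#'   pixels (see [set_sss_o2sat()]).
#' @param ref a [build_reference_spectra()] object.
#' @param cfg the [phantom_config()].
#' @param intensity_scale global subject scale in AU; by default drawn
#'   log-uniformly over `cfg$intensity_range` from the current RNG.
#' @return a [spectral_image()].
#' @export
render_spectral_image <- function(anatomy, ref, cfg = anatomy$cfg,
                                  intensity_scale = NULL) {
  H <- cfg$image_h; W <- cfg$image_w
  grid <- ref$grid
  n_lam <- length(grid$values)
  if (is.null(intensity_scale))
    intensity_scale <- exp(runif(1, log(cfg$intensity_range[1]),
                                 log(cfg$intensity_range[2])))
  scale <- intensity_scale / max(ref$table)

  perf <- which(anatomy$blood_frac > 0)
  if (any(is.na(anatomy$o2sat[perf])))
    stop("perfused pixels without an O2Sat assignment; call set_sss_o2sat()")

  px <- array(0, dim = c(H, W, n_lam))
  if (length(perf)) {
    s_frac <- anatomy$o2sat[perf] / 100
    ext <- hb_extinction(grid)
    spec <- outer(ext[, "HbO2"], s_frac) + outer(ext[, "Hb"], 1 - s_frac)
    depth_mm <- ((perf - 1) %% H) * cfg$pixel_spacing_mm
    attn <- exp(-outer(attenuation_mu(cfg, grid), depth_mm))
    vals <- scale * spec * attn *
      rep(anatomy$blood_frac[perf], each = n_lam)
    for (l in seq_len(n_lam)) {
      plane <- matrix(0, H, W)
      plane[perf] <- vals[l, ]
      px[, , l] <- plane
    }
  }
  if (cfg$noise_sd > 0) {
    amp <- cfg$noise_sd * max(px)
    px <- px + array(rnorm(length(px), 0, amp), dim = dim(px))
    px[px < 0] <- 0
  }
  spectral_image(px, grid, cfg$pixel_spacing_mm)
}

# Venous O2Satss trajectory for one subject: decay from a healthy start
# toward the floor as FiO2 drops, with Gaussian reading noise. The first
# (highest-FiO2) sample is guaranteed healthy (> 30%), matching the
# curation assumption that every series starts at a normal oxygenation.
o2sat_trajectory <- function(fio2, cfg) {
  start <- runif(1, cfg$o2sat_start_range[1], cfg$o2sat_start_range[2])
  ratio <- pmax((fio2 - 0.08) / (1 - 0.08), 0)
  o2 <- cfg$o2sat_floor + (start - cfg$o2sat_floor) *
    ratio^cfg$o2sat_decay_power + rnorm(length(fio2), 0, cfg$o2sat_noise_sd)
  o2 <- pmin(pmax(o2, 0), 100)
  o2[1] <- max(o2[1], 30.5)
  o2
}

#' Generate a complete synthetic study
#'
#' Produces a multi-subject dataset mirroring the structure of the animal
#' experiments: per subject a fixed anatomy, a declining FiO2 schedule,
#' and an O2Satss trajectory that starts healthy (>= 30%) and decays with
#' FiO2 so that roughly 70% of all samples under the default schedule are
#' hypoxic (< 30%). The output is fully determined by `seed`.
#'
#' @param n_subjects number of subjects.
#' @param per_subject_counts samples per subject; defaults to the
#'   10-subject series `c(10, 5, 6, 9, 11, 9, 8, 11, 6, 9)` (84 samples)
#'   truncated/recycled to `n_subjects`.
#' @param fio2_schedule function `n -> fio2 vector` (monotone
#'   non-increasing); default linear 1.0 down to 0.08.
#' @param cfg a [phantom_config()].
#' @param seed integer master seed.
#' @return a [study_dataset()]; each sample also carries the rendering
#'   `intensity_scale` and true anatomy in attributes `anatomies`.
#' @export
generate_study <- function(n_subjects = 10,
                           per_subject_counts = NULL,
                           fio2_schedule = NULL,
                           cfg = phantom_config(),
                           seed = 1) {
  if (is.null(per_subject_counts)) {
    base_counts <- c(10, 5, 6, 9, 11, 9, 8, 11, 6, 9)
    per_subject_counts <- rep_len(base_counts, n_subjects)
  }
  stopifnot(length(per_subject_counts) == n_subjects,
            all(per_subject_counts >= 1))
  if (is.null(fio2_schedule))
    fio2_schedule <- function(n) seq(1, 0.08, length.out = max(n, 2))[seq_len(n)]

  ref <- build_reference_spectra(wavelength_grid())
  with_seed(derive_seed(seed, "phantom"), {
    samples <- list()
    anatomies <- list()
    for (s in seq_len(n_subjects)) {
      sid <- sprintf("S%02d", s)
      anatomy <- generate_anatomy(cfg)
      anatomies[[sid]] <- anatomy
      n <- per_subject_counts[s]
      fio2 <- fio2_schedule(n)
      if (any(diff(fio2) > 1e-9))
        stop("fio2_schedule must be monotone non-increasing")
      o2 <- o2sat_trajectory(fio2, cfg)
      scale <- exp(runif(1, log(cfg$intensity_range[1]),
                         log(cfg$intensity_range[2])))
      for (k in seq_len(n)) {
        an_k <- set_sss_o2sat(anatomy, o2[k])
        img <- render_spectral_image(an_k, ref, cfg, intensity_scale = scale)
        samples[[length(samples) + 1]] <-
          sample_record(img, sid, fio2[k], o2[k], anatomy$sss_xy)
      }
    }
    ds <- study_dataset(samples)
    attr(ds, "anatomies") <- anatomies
    attr(ds, "phantom_config") <- cfg
    ds
  })
}

#' Attenuation compensation matched to the phantom forward model
#'
#' Gains `exp(+mu(lambda) * sss_depth_mm)` that exactly undo the phantom's
#' exponential fluence decay at the nominal SSS depth; combined with the
#' unmixer's per-depth gain scaling this inverts the forward model at
#' every depth.
#'
#' @param cfg a [phantom_config()].
#' @param grid a [wavelength_grid()].
#' @return a [compensation_profile()].
#' @export
matched_compensation <- function(cfg = phantom_config(),
                                 grid = wavelength_grid()) {
  mu <- attenuation_mu(cfg, grid)
  compensation_profile(exp(mu * cfg$sss_depth_mm), cfg$sss_depth_mm)
}
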