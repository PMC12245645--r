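#' Spectral unmixing configuration
#'
#' @param ref a [build_reference_spectra()] table.
#' @param compensation a [compensation_profile()] undoing the per-
#'   wavelength attenuation at its reference depth.
#' @param fit_scale fit a free per-pixel amplitude jointly with the
#'   saturation (closed-form projection per candidate level). `FALSE`
#'   compares absolute amplitudes against the reference table directly.
#' @param region_h,region_w size (px) of the locally unmixed window
#'   around the SSS (default 50 x 80); unmixing the full frame is wasteful
#'   and the compensation is only calibrated near the SSS depth.
#' @param per_depth scale the compensation gains continuously with pixel
#'   depth (`gain^(depth/reference_depth)`, the exponential-fluence
#'   reading of the calibration); `FALSE` applies the reference-depth
#'   gains to every pixel.
#' @return object of class `pa_unmix_config`.
#' @export
unmix_config <- function(ref, compensation, fit_scale = TRUE,
                         region_h = 50, region_w = 80, per_depth = TRUE) {
  stopifnot(inherits(ref, "pa_reference_spectra"),
            inherits(compensation, "pa_compensation_profile"),
            length(compensation$gains) == nrow(ref$table),
            region_h >= 1, region_w >= 1)
  structure(list(ref = ref, compensation = compensation,
                 fit_scale = fit_scale, region_h = region_h,
                 region_w = region_w, per_depth = per_depth),
            class = "pa_unmix_config")
}

#' Apply attenuation compensation to a spectrum
#'
#' @param spectrum measured per-wavelength amplitudes.
#' @param compensation a [compensation_profile()].
#' @return the elementwise-compensated spectrum.
#' @export
compensate_spectrum <- function(spectrum, compensation) {
  if (length(spectrum) != length(compensation$gains))
    stop("spectrum length ", length(spectrum),
         " does not match the compensation profile (",
         length(compensation$gains), ")")
  spectrum * compensation$gains
}

# Residuals of every candidate saturation level for a matrix of spectra
# X (n_wavelengths x n_pixels). With fit_scale the amplitude is projected
# out per candidate: rss(s) = ||x||^2 - <x, S_s>^2 / ||S_s||^2.
unmix_residuals <- function(X, cfg) {
  S <- cfg$ref$table
  if (cfg$fit_scale) {
    cross <- crossprod(S, X)                      # n_levels x n_pixels
    ss <- colSums(S^2)
    sweep(-cross^2, 1, ss, "/") +
      matrix(colSums(X^2), nrow(cross), ncol(X), byrow = TRUE)
  } else {
    # ||x - S_s||^2 expanded
    matrix(colSums(X^2), ncol(S), ncol(X), byrow = TRUE) -
      2 * crossprod(S, X) + colSums(S^2)
  }
}

#' Unmix a single (compensated) spectrum
#'
#' Grid argmin of the mean squared residual between the measured spectrum
#' and the reference response over the candidate saturation levels. With
#' `fit_scale` the residual is minimized jointly over a free amplitude per
#' candidate (closed-form projection), making the estimate invariant to
#' overall signal scale. An all-zero spectrum carries no saturation
#' information and returns `NA`.
#'
#' @param spectrum compensated per-wavelength amplitudes (length equal to
#'   the reference grid).
#' @param cfg an [unmix_config()].
#' @return estimated oxygen saturation in percent (a grid level), or
#'   `NA_real_` for an all-zero spectrum.
#' @export
unmix_pixel <- function(spectrum, cfg) {
  if (length(spectrum) != nrow(cfg$ref$table))
    stop("spectrum length does not match the reference table")
  if (all(spectrum == 0)) return(NA_real_)
  r <- unmix_residuals(matrix(spectrum, ncol = 1), cfg)
  cfg$ref$o2sat_grid[which.min(r[, 1])]
}

# 0-based inclusive bounds of the window of size (h x w) centred at
# (cx, cy), clipped to the frame. Even edges bias toward the lower index.
window_bounds <- function(cx, cy, w, h, W, H) {
  x0 <- cx - floor(w / 2); x1 <- x0 + w - 1
  y0 <- cy - floor(h / 2); y1 <- y0 + h - 1
  c(x0 = max(x0, 0), x1 = min(x1, W - 1),
    y0 = max(y0, 0), y1 = min(y1, H - 1))
}

#' Unmix the region around a detected SSS location
#'
#' Spectrally unmixes the `region_h x region_w` window centred at
#' `center_xy` (clipped to the frame). Pixels outside the window, and
#' all-zero spectra inside it, are flagged invalid rather than set to a
#' saturation of zero.
#'
#' @param img a [spectral_image()].
#' @param center_xy 0-based `c(x, y)` window centre.
#' @param cfg an [unmix_config()].
#' @return object of class `pa_o2sat_map`: `values` (`H x W`, percent, NA
#'   where invalid), `valid` (logical mask of actually unmixed pixels).
#' @export
unmix_region <- function(img, center_xy, cfg) {
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  cx <- round(center_xy[1]); cy <- round(center_xy[2])
  if (cx < 0 || cx > W - 1 || cy < 0 || cy > H - 1)
    stop("window centre outside image bounds")
  b <- window_bounds(cx, cy, cfg$region_w, cfg$region_h, W, H)
  ys <- (b["y0"]:b["y1"]) + 1L
  xs <- (b["x0"]:b["x1"]) + 1L

  vals <- matrix(NA_real_, H, W)
  valid <- matrix(FALSE, H, W)

  sub <- img$pixels[ys, xs, , drop = FALSE]
  nh <- length(ys); nw <- length(xs); nl <- dim(sub)[3]
  X <- t(matrix(sub, nh * nw, nl))       # n_wavelengths x n_pixels

  gains <- cfg$compensation$gains
  if (cfg$per_depth) {
    depth_mm <- rep((ys - 1) * img$pixel_spacing_mm, times = nw)
    expo <- depth_mm / cfg$compensation$reference_depth_mm
    G <- exp(outer(log(gains), expo))    # n_wavelengths x n_pixels
    X <- X * G
  } else {
    X <- X * gains
  }

  nonzero <- colSums(abs(X)) > 0
  est <- rep(NA_real_, ncol(X))
  if (any(nonzero)) {
    r <- unmix_residuals(X[, nonzero, drop = FALSE], cfg)
    est[nonzero] <- cfg$ref$o2sat_grid[max.col(t(-r), ties.method = "first")]
  }
  vals[ys, xs] <- matrix(est, nh, nw)
  valid[ys, xs] <- matrix(nonzero, nh, nw)
  structure(list(values = vals, valid = valid, center_xy = c(cx, cy),
                 bounds = b),
            class = "pa_o2sat_map")
}

#' Gaussian smoothing of an O2Sat map
#'
#' Mask-normalized filtering: invalid pixels are excluded from the kernel
#' support (the blurred values are renormalized by the blurred validity
#' mask), so saturation estimates are never diluted by out-of-region
#' zeros. `sigma = 0` is the identity.
#'
#' @param map a `pa_o2sat_map` (or plain matrix, treated as all-valid).
#' @param sigma Gaussian standard deviation in pixels.
#' @return the smoothed map, same class and validity mask.
#' @export
smooth_o2sat_map <- function(map, sigma) {
  stopifnot(sigma >= 0)
  if (is.matrix(map))
    map <- structure(list(values = map, valid = !is.na(map)),
                     class = "pa_o2sat_map")
  if (sigma == 0) return(map)
  v <- map$values
  v[!map$valid] <- 0
  num <- gaussian_blur(v, sigma)
  den <- gaussian_blur(map$valid + 0, sigma)
  out <- map$values
  ok <- map$valid & den > 1e-12
  out[ok] <- num[ok] / den[ok]
  map$values <- out
  map
}

#' ROI parameters for O2Satss extraction
#'
#' The measurement ROI is an axis-aligned rectangle of `d x c` pixels
#' (x-edge `d`, y-edge `c`) whose centre is displaced from the detected
#' SSS point by `(b, a)` pixels (x, y); the O2Sat map is Gaussian-smoothed
#' with `sigma` before averaging. Defaults are the grid-search optimum
#' reported for the in vivo study (a = 1, b = -4, c = 4, d = 11,
#' sigma = 1).
#'
#' @param a,b centre displacement along y and x (px).
#' @param c_edge,d_edge edge lengths along y and x (px, >= 1).
#' @param sigma smoothing std (px, >= 0).
#' @return object of class `pa_roi_params`.
#' @export
roi_params <- function(a = 1, b = -4, c_edge = 4, d_edge = 11, sigma = 1) {
  stopifnot(c_edge >= 1, d_edge >= 1, sigma >= 0)
  structure(list(a = a, b = b, c = c_edge, d = d_edge, sigma = sigma),
            class = "pa_roi_params")
}

#' Average the smoothed O2Sat map over the measurement ROI
#'
#' Arithmetic mean of the valid pixels inside the displaced rectangle
#' (inclusive integer bounds, even edges biased toward the lower index,
#' clipped to the frame). The map should already be smoothed with the
#' ROI's sigma (see [measure_o2satss()] for the assembled step).
#'
#' @param map a `pa_o2sat_map`.
#' @param sss_xy 0-based detected/annotated SSS point `c(x, y)`.
#' @param roi a [roi_params()].
#' @return O2Satss in percent, or `NA_real_` when the ROI contains no
#'   valid pixel (measurement failure).
#' @export
extract_o2satss <- function(map, sss_xy, roi) {
  H <- nrow(map$values); W <- ncol(map$values)
  cx <- round(sss_xy[1]) + roi$b
  cy <- round(sss_xy[2]) + roi$a
  b <- window_bounds(cx, cy, roi$d, roi$c, W, H)
  if (b["x0"] > b["x1"] || b["y0"] > b["y1"]) return(NA_real_)
  ys <- (b["y0"]:b["y1"]) + 1L; xs <- (b["x0"]:b["x1"]) + 1L
  vals <- map$values[ys, xs]
  ok <- map$valid[ys, xs]
  if (!any(ok)) return(NA_real_)
  mean(vals[ok])
}

#' One-call O2Satss measurement (workflow step 2)
#'
#' Unmix the window around the SSS point, smooth with the ROI sigma, and
#' average over the displaced ROI rectangle.
#'
#' @param img a [spectral_image()].
#' @param sss_xy detected or annotated SSS point, 0-based `c(x, y)`.
#' @param ucfg an [unmix_config()].
#' @param roi a [roi_params()].
#' @return O2Satss in percent (`NA_real_` on measurement failure).
#' @export
measure_o2satss <- function(img, sss_xy, ucfg, roi = roi_params()) {
  map <- unmix_region(img, sss_xy, ucfg)
  map <- smooth_o2sat_map(map, roi$sigma)
  extract_o2satss(map, sss_xy, roi)
}

#' ROI grid-search space
#'
#' @param a_range,b_range centre displacements (px), default -5..5
#'   (+-1.5 mm at 0.3 mm spacing).
#' @param c_range,d_range edge lengths (px), default 2..20 (0.6-6 mm).
#' @param sigma_set smoothing levels (px), default 1..4.
#' @param min_sens,min_spec feasibility constraint on classifying hypoxia
#'   (< `threshold`) versus normoxia at the extracted readings.
#' @param threshold hypoxia boundary in percent.
#' @return object of class `pa_roi_space`.
#' @export
roi_search_space <- function(a_range = -5:5, b_range = -5:5,
                             c_range = 2:20, d_range = 2:20,
                             sigma_set = 1:4,
                             min_sens = 0.9, min_spec = 0.9,
                             threshold = 30) {
  stopifnot(length(a_range) > 0, length(b_range) > 0, length(c_range) > 0,
            length(d_range) > 0, length(sigma_set) > 0)
  structure(list(a_range = a_range, b_range = b_range, c_range = c_range,
                 d_range = d_range, sigma_set = sigma_set,
                 min_sens = min_sens, min_spec = min_spec,
                 threshold = threshold),
            class = "pa_roi_space")
}

#' Precompute unmixed maps for the ROI grid search
#'
#' @param samples list of [sample_record()]s (annotated).
#' @param ucfg an [unmix_config()].
#' @return list of entries `list(map, sss_xy, gt)` consumable by
#'   [grid_search_roi()].
#' @export
prepare_roi_entries <- function(samples, ucfg) {
  lapply(samples, function(s)
    list(map = unmix_region(s$image, s$sss_xy, ucfg),
         sss_xy = s$sss_xy, gt = s$o2satss_gt))
}

# Summed-area table with a zero top row / left column.
integral_image <- function(m) {
  H <- nrow(m); W <- ncol(m)
  a <- matrix(apply(m, 2, cumsum), H, W)
  b <- matrix(apply(a, 1, cumsum), W, H)
  out <- matrix(0, H + 1, W + 1)
  out[-1, -1] <- t(b)
  out
}

#' Exhaustive ROI parameter grid search
#'
#' Evaluates every `(a, b, c, d, sigma)` combination: for each sample the
#' (sigma-smoothed) O2Sat map is averaged over the displaced ROI and
#' compared to the ground-truth reading. Among combinations whose
#' hypoxia/normoxia classification reaches the sensitivity and specificity
#' floors, the mean-squared-error minimizer is returned; ties break
#' deterministically toward the smaller ROI area `c * d`, then smaller
#' `|a| + |b|`, then scan order. When no combination is feasible (or the
#' entries do not span both classes) the result is flagged infeasible and
#' carries the unconstrained optimum for diagnosis.
#'
#' @param entries list from [prepare_roi_entries()]: each
#'   `list(map, sss_xy, gt)`, `map` a `pa_o2sat_map` or plain matrix.
#' @param space a [roi_search_space()].
#' @return object of class `pa_roi_search`: `params` (best feasible
#'   [roi_params()] or NULL), `feasible`, `mse`, `sensitivity`,
#'   `specificity`, `best_unconstrained`, and `table` (per-sigma optimum,
#'   columns sigma / mse / sensitivity / specificity / d / c / b / a).
#' @export
grid_search_roi <- function(entries, space = roi_search_space()) {
  stopifnot(length(entries) >= 2)
  gt <- vapply(entries, `[[`, numeric(1), "gt")
  gt_pos <- gt < space$threshold
  both_classes <- any(gt_pos) && any(!gt_pos)

  n_ab <- length(space$a_range) * length(space$b_range)
  ab <- expand.grid(a = space$a_range, b = space$b_range,
                    KEEP.OUT.ATTRS = FALSE)
  best <- NULL; best_any <- NULL
  sigma_rows <- list()
  scan <- 0L

  consider <- function(slot, cand) {
    if (is.null(slot)) return(cand)
    key_new <- c(cand$mse, cand$area, cand$ab_l1, cand$scan)
    key_old <- c(slot$mse, slot$area, slot$ab_l1, slot$scan)
    for (i in seq_along(key_new)) {
      if (key_new[i] < key_old[i]) return(cand)
      if (key_new[i] > key_old[i]) return(slot)
    }
    slot
  }

  for (sg in space$sigma_set) {
    sm <- lapply(entries, function(e) smooth_o2sat_map(e$map, sg))
    ints <- lapply(sm, function(m) {
      v <- m$values; v[!m$valid] <- 0
      list(iv = integral_image(v), ic = integral_image(m$valid + 0),
           H = nrow(m$values), W = ncol(m$values))
    })
    cx0 <- vapply(entries, function(e) round(e$sss_xy[1]), numeric(1))
    cy0 <- vapply(entries, function(e) round(e$sss_xy[2]), numeric(1))
    best_sigma_feas <- NULL; best_sigma_any <- NULL

    for (cc in space$c_range) for (dd in space$d_range) {
      # predictions for all (a, b) x entries via summed-area lookups
      pred <- matrix(NA_real_, n_ab, length(entries))
      for (j in seq_along(entries)) {
        ii <- ints[[j]]
        x0 <- pmax(cx0[j] + ab$b - floor(dd / 2), 0)
        x1 <- pmin(cx0[j] + ab$b - floor(dd / 2) + dd - 1, ii$W - 1)
        y0 <- pmax(cy0[j] + ab$a - floor(cc / 2), 0)
        y1 <- pmin(cy0[j] + ab$a - floor(cc / 2) + cc - 1, ii$H - 1)
        ok <- x0 <= x1 & y0 <= y1
        sums <- cnts <- rep(NA_real_, n_ab)
        lut <- function(I, r0, c0, r1, c1)
          I[cbind(r1 + 2, c1 + 2)] - I[cbind(r0 + 1, c1 + 2)] -
          I[cbind(r1 + 2, c0 + 1)] + I[cbind(r0 + 1, c0 + 1)]
        sums[ok] <- lut(ii$iv, y0[ok], x0[ok], y1[ok], x1[ok])
        cnts[ok] <- lut(ii$ic, y0[ok], x0[ok], y1[ok], x1[ok])
        pred[, j] <- ifelse(!is.na(cnts) & cnts > 0, sums / cnts, NA_real_)
      }
      complete <- rowSums(is.na(pred)) == 0
      if (!any(complete)) { scan <- scan + n_ab; next }
      mse <- rowMeans((pred - matrix(gt, n_ab, length(gt), byrow = TRUE))^2)
      cls <- pred < space$threshold
      sens <- if (any(gt_pos))
        rowSums(cls[, gt_pos, drop = FALSE]) / sum(gt_pos) else NA_real_
      spec <- if (any(!gt_pos))
        rowSums(!cls[, !gt_pos, drop = FALSE]) / sum(!gt_pos) else NA_real_

      for (r in which(complete)) {
        scan_r <- scan + r
        cand <- list(params = roi_params(ab$a[r], ab$b[r], cc, dd, sg),
                     mse = mse[r], sensitivity = sens[r],
                     specificity = spec[r], area = cc * dd,
                     ab_l1 = abs(ab$a[r]) + abs(ab$b[r]), scan = scan_r)
        best_any <- consider(best_any, cand)
        best_sigma_any <- consider(best_sigma_any, cand)
        if (both_classes && sens[r] > space$min_sens &&
            spec[r] > space$min_spec) {
          best <- consider(best, cand)
          best_sigma_feas <- consider(best_sigma_feas, cand)
        }
      }
      scan <- scan + n_ab
    }
    best_sigma <- if (!is.null(best_sigma_feas)) best_sigma_feas
                  else best_sigma_any
    if (!is.null(best_sigma))
      sigma_rows[[as.character(sg)]] <- data.frame(
        sigma = sg, mse = best_sigma$mse,
        sensitivity = best_sigma$sensitivity,
        specificity = best_sigma$specificity,
        d = best_sigma$params$d, c = best_sigma$params$c,
        b = best_sigma$params$b, a = best_sigma$params$a)
  }

  structure(list(
    params = if (!is.null(best)) best$params else NULL,
    feasible = !is.null(best),
    mse = if (!is.null(best)) best$mse else NA_real_,
    sensitivity = if (!is.null(best)) best$sensitivity else NA_real_,
    specificity = if (!is.null(best)) best$specificity else NA_real_,
    both_classes = both_classes,
    best_unconstrained = best_any,
    table = do.call(rbind, sigma_rows),
    n_evaluated = scan), class = "pa_roi_search")
}
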