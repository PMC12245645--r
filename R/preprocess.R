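#' Dynamic-range rectification
#'
#' Clips image intensities at `T = mean + k * sd`, where the mean and the
#' (population) standard deviation are computed jointly over all
#' wavelength channels of the stack. Saturating the strongest reflectors
#' equalizes the visibility of micro- and macro-vessels so the structural
#' "M" curvature, rather than raw amplitude, drives landmark learning.
#'
#' @param img a [spectral_image()].
#' @param k saturation coefficient (>= 0); 0.5 at test time, drawn from
#'   `[0, 1]` as a training augmentation.
#' @return the rectified `pa_spectral_image` (elementwise `min(x, T)`).
#' @export
rectify_dynamic_range <- function(img, k = 0.5) {
  stopifnot(inherits(img, "pa_spectral_image"), k >= 0)
  x <- img$pixels
  mu <- mean(x)
  sd_pop <- sqrt(mean((x - mu)^2))
  thr <- mu + k * sd_pop
  img$pixels <- pmin(x, thr)
  img
}

#' Min-max normalization
#'
#' Affinely maps intensities to `[0, 1]`. In `joint` mode one affine map
#' is shared by all channels, so inter-channel ratios (the spectral shape)
#' are preserved up to the common offset; `per_channel` normalizes each
#' wavelength independently. A zero-range scope maps to all zeros.
#'
#' @param img a [spectral_image()].
#' @param mode `"joint"` (default) or `"per_channel"`.
#' @return the normalized `pa_spectral_image`.
#' @export
minmax_normalize <- function(img, mode = c("joint", "per_channel")) {
  mode <- match.arg(mode)
  x <- img$pixels
  norm01 <- function(v) {
    r <- range(v)
    if (r[2] - r[1] <= 0) return(v * 0)
    (v - r[1]) / (r[2] - r[1])
  }
  if (mode == "joint") {
    img$pixels <- array(norm01(x), dim = dim(x))
  } else {
    for (c in seq_len(dim(x)[3])) x[, , c] <- norm01(x[, , c])
    img$pixels <- x
  }
  img
}

# Plain Gaussian filtering of a matrix with zero padding outside the
# frame; sigma = 0 is the identity.
gaussian_blur <- function(m, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(m)
  # kernel must be odd-sized and no larger than the image
  radius <- min(2 * ceiling(3 * sigma) + 1,
                min(dim(m)) - (min(dim(m)) + 1) %% 2)
  out <- EBImage::gblur(m, sigma = sigma, radius = radius, boundary = 0)
  matrix(as.numeric(out), nrow(m), ncol(m))
}

#' Gaussian heatmap target for landmark regression
#'
#' Builds the training target for the localizer: a delta image at the
#' annotated SSS pixel is Gaussian-filtered and min-max normalized, giving
#' a single isotropic peak of value exactly 1 at the annotation that
#' decays radially.
#'
#' @param sss_xy 0-based annotation `c(x, y)`.
#' @param shape image shape `c(H, W)`.
#' @param sigma Gaussian standard deviation in pixels (default 3).
#' @return `H x W` matrix in `[0, 1]` with maximum 1 at `sss_xy`.
#' @export
make_heatmap_target <- function(sss_xy, shape, sigma = 3) {
  H <- shape[1]; W <- shape[2]
  x <- round(sss_xy[1]); y <- round(sss_xy[2])
  if (x < 0 || x > W - 1 || y < 0 || y > H - 1)
    stop("annotation outside image bounds")
  delta <- matrix(0, H, W)
  delta[y + 1, x + 1] <- 1
  hm <- gaussian_blur(delta, sigma)
  hm <- hm - min(hm)
  hm / max(hm)
}

#' Wavelength bins for input-channel augmentation
#'
#' The 21-wavelength band is partitioned into five bins
#' (700-730, 740-770, 780-820, 830-860, 870-900 nm; sizes 4, 4, 5, 4, 4)
#' so that a sparse channel subset still spans the whole spectrum.
#'
#' @return list of five `c(lo, hi)` inclusive nm ranges.
#' @export
wavelength_bins <- function() {
  list(c(700, 730), c(740, 770), c(780, 820), c(830, 860), c(870, 900))
}

#' Draw one wavelength per bin
#'
#' Samples the 5-channel subset used by the input-channel augmentation
#' (and by data-mode Monte Carlo dropout): exactly one wavelength from
#' each bin, drawn from the current RNG.
#'
#' @param grid a [wavelength_grid()].
#' @param bins bin list from [wavelength_bins()].
#' @return numeric vector of 5 distinct wavelengths (nm), in bin order.
#' @export
sample_channel_subset <- function(grid = wavelength_grid(),
                                  bins = wavelength_bins()) {
  vapply(bins, function(b) {
    members <- grid$values[grid$values >= b[1] & grid$values <= b[2]]
    if (length(members) == 0) stop("bin [", b[1], ", ", b[2],
                                   "] contains no grid wavelength")
    members[sample.int(length(members), 1)]
  }, numeric(1))
}

#' Mask all channels outside a kept wavelength subset
#'
#' @param img a [spectral_image()].
#' @param keep wavelengths (nm) to keep; all must be on the grid.
#' @return the image with non-kept channels set exactly to zero.
#' @export
mask_channels <- function(img, keep) {
  idx <- match(keep, img$grid$values)
  if (anyNA(idx)) stop("unknown wavelength(s): ",
                       paste(keep[is.na(idx)], collapse = ", "))
  drop_idx <- setdiff(seq_along(img$grid$values), idx)
  img$pixels[, , drop_idx] <- 0
  img
}

#' Geometric augmentation parameters
#'
#' @param p_flip horizontal-flip probability.
#' @param max_shift_frac maximum shift as a fraction of each frame edge.
#' @param max_rot_deg maximum absolute rotation.
#' @param scale_range multiplicative zoom range.
#' @param distort_amp_px control-point amplitude of the grid distortion
#'   (0 disables it).
#' @param distort_grid number of distortion control points per axis.
#' @return list of class `pa_augment_params`.
#' @export
augment_params <- function(p_flip = 0.5, max_shift_frac = 0.1,
                           max_rot_deg = 10, scale_range = c(0.9, 1.1),
                           distort_amp_px = 1.5, distort_grid = 5) {
  structure(list(p_flip = p_flip, max_shift_frac = max_shift_frac,
                 max_rot_deg = max_rot_deg, scale_range = scale_range,
                 distort_amp_px = distort_amp_px,
                 distort_grid = distort_grid),
            class = "pa_augment_params")
}

identity_augment_params <- function() {
  augment_params(p_flip = 0, max_shift_frac = 0, max_rot_deg = 0,
                 scale_range = c(1, 1), distort_amp_px = 0)
}

# Build the source-coordinate maps (0-based) of one random spatial
# transform: flip / rotation / scale / shift about the image centre plus a
# smooth grid distortion. Output-pixel (i, j) reads the input at
# (map_y[i, j], map_x[i, j]).
random_transform_maps <- function(shape, params) {
  H <- shape[1]; W <- shape[2]
  flip <- runif(1) < params$p_flip
  ang <- runif(1, -params$max_rot_deg, params$max_rot_deg) * pi / 180
  sc <- runif(1, params$scale_range[1], params$scale_range[2])
  tx <- runif(1, -1, 1) * params$max_shift_frac * W
  ty <- runif(1, -1, 1) * params$max_shift_frac * H

  cx <- (W - 1) / 2; cy <- (H - 1) / 2
  xo <- matrix(rep(0:(W - 1), each = H), H, W)
  yo <- matrix(rep(0:(H - 1), W), H, W)
  # inverse map: undo shift, then inverse rotation/scale about the centre
  xr <- xo - cx - tx
  yr <- yo - cy - ty
  map_x <- (cos(-ang) * xr - sin(-ang) * yr) / sc + cx
  map_y <- (sin(-ang) * xr + cos(-ang) * yr) / sc + cy
  if (flip) map_x <- (W - 1) - map_x

  if (params$distort_amp_px > 0) {
    g <- params$distort_grid
    up <- function(coarse) {
      cube <- array(coarse, dim = c(g, g, 1))
      my <- matrix(rep(seq(0, g - 1, length.out = H), W), H, W)
      mx <- matrix(rep(seq(0, g - 1, length.out = W), each = H), H, W)
      bilinear_warp(cube, my, mx)[, , 1]
    }
    map_x <- map_x + up(matrix(runif(g * g, -1, 1) * params$distort_amp_px, g, g))
    map_y <- map_y + up(matrix(runif(g * g, -1, 1) * params$distort_amp_px, g, g))
  }
  list(map_x = map_x, map_y = map_y)
}

#' Paired geometric augmentation of an image and its heatmap target
#'
#' Applies one random spatial transform (horizontal flip, rotation,
#' scaling, shifting, smooth grid distortion) identically to the image
#' stack and the heatmap, so the target peak moves with the anatomy. The
#' warped heatmap is re-normalized to peak 1. Draws mapping the peak
#' outside the frame are rejected and redrawn; after `max_tries` rejected
#' draws the untransformed pair is returned.
#'
#' @param pixels `H x W x C` image array.
#' @param heatmap `H x W` target matrix.
#' @param params an [augment_params()] list.
#' @param max_tries rejection budget.
#' @return list `pixels`, `heatmap` (same shapes).
#' @export
geometric_augment <- function(pixels, heatmap, params = augment_params(),
                              max_tries = 10) {
  stopifnot(all(dim(pixels)[1:2] == dim(heatmap)))
  H <- dim(heatmap)[1]; W <- dim(heatmap)[2]
  for (t in seq_len(max_tries)) {
    maps <- random_transform_maps(c(H, W), params)
    hm <- bilinear_warp(array(heatmap, dim = c(H, W, 1)),
                        maps$map_y, maps$map_x)[, , 1]
    if (max(hm) < 0.5) next  # peak left the frame; redraw
    px <- bilinear_warp(pixels, maps$map_y, maps$map_x)
    return(list(pixels = px, heatmap = hm / max(hm)))
  }
  list(pixels = pixels, heatmap = heatmap)
}

#' Test-time preprocessing for the localizer
#'
#' The inference contract of the landmark network: rectify the dynamic
#' range at `k` and jointly min-max normalize to `[0, 1]`.
#'
#' @param img a [spectral_image()].
#' @param k saturation coefficient (0.5 at test time).
#' @return `H x W x C` numeric array ready for [predict_heatmap()].
#' @export
preprocess_for_localizer <- function(img, k = 0.5) {
  minmax_normalize(rectify_dynamic_range(img, k))$pixels
}
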