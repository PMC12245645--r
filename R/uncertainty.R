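#' Monte Carlo dropout configuration
#'
#' Three sampling modes quantify where prediction variability comes from:
#' `model` re-runs the localizer with dropout active on the full
#' 21-channel input; `data` keeps dropout off but feeds a fresh binned
#' 5-wavelength subset each run (the training-time channel augmentation
#' kept at test time); `combined` crosses `n_model` dropout draws with
#' `n_data` channel subsets factorially.
#'
#' @param mode `"model"`, `"data"` or `"combined"`.
#' @param n_model dropout draws (default 400 in model mode, 20 combined).
#' @param n_data channel-subset draws (default 400 in data mode, 20
#'   combined).
#' @param seed RNG seed for all draws.
#' @return object of class `pa_mcd_config`.
#' @export
mcd_config <- function(mode = c("model", "data", "combined"),
                       n_model = NULL, n_data = NULL, seed = 1) {
  mode <- match.arg(mode)
  if (is.null(n_model)) n_model <- switch(mode, model = 400, data = 0,
                                          combined = 20)
  if (is.null(n_data)) n_data <- switch(mode, model = 0, data = 400,
                                        combined = 20)
  if (mode == "model" && n_model < 1) stop("model mode needs n_model >= 1")
  if (mode == "data" && n_data < 1) stop("data mode needs n_data >= 1")
  if (mode == "combined" && (n_model < 1 || n_data < 1))
    stop("combined mode needs n_model >= 1 and n_data >= 1")
  structure(list(mode = mode, n_model = n_model, n_data = n_data,
                 seed = seed),
            class = "pa_mcd_config")
}

#' Confidence score from an uncertainty value
#'
#' `beta = 1 - 2 * epsilon`, with `epsilon` the standard deviation of
#' repeated O2Satss predictions expressed as a fraction (0.20 = 20
#' percentage points). `beta` can go negative for epsilon > 0.5 and is
#' reported as-is (a very-low-confidence flag, not an error).
#'
#' @param epsilon uncertainty as a fraction (>= 0).
#' @return confidence score in `(-Inf, 1]`.
#' @examples
#' confidence_from_epsilon(0.20)    # 0.60
#' confidence_from_epsilon(0.0297)  # 0.9406
#' @export
confidence_from_epsilon <- function(epsilon) {
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  1 - 2 * epsilon
}

# Population standard deviation (n divisor); with hundreds of MCD runs
# the distinction from the n-1 form is negligible, but the contract
# epsilon = 0 for identical samples must hold exactly.
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Monte Carlo dropout sampling for one data point
#'
#' Repeatedly runs the full two-step measurement (localize, then unmix
#' and average over the ROI of the raw image) under the configured
#' stochasticity and summarizes the spread of the resulting O2Satss
#' readings and SSS coordinates. Deterministic for a fixed seed.
#'
#' @param model a trained `pa_localizer`.
#' @param img the [spectral_image()] of the data point.
#' @param ucfg an [unmix_config()].
#' @param roi a [roi_params()].
#' @param mcd an [mcd_config()].
#' @return object of class `pa_uncertainty_result`: `samples` (data frame
#'   run / x / y / o2satss), `epsilon` (percentage points), `beta`,
#'   `xy_std` (per-axis std, px), `n_failed` (runs with measurement
#'   failure, excluded from the spread).
#' @export
mcd_sample <- function(model, img, ucfg, roi = roi_params(),
                       mcd = mcd_config("model")) {
  stopifnot(inherits(model, "pa_localizer"),
            inherits(img, "pa_spectral_image"))
  x_full <- preprocess_for_localizer(img, k = 0.5)
  d <- dim(x_full)
  grid <- img$grid

  mask_input <- function(keep) {
    xm <- x_full
    xm[, , setdiff(seq_len(d[3]), match(keep, grid$values))] <- 0
    xm
  }

  runs <- with_seed(derive_seed(mcd$seed, "mcd"), {
    inputs_masks <- switch(mcd$mode,
      model = lapply(seq_len(mcd$n_model), function(i)
        list(x = x_full, masks = unet_draw_masks(model$cfg, d[1], d[2]))),
      data = lapply(seq_len(mcd$n_data), function(i)
        list(x = mask_input(sample_channel_subset(grid)), masks = NULL)),
      combined = {
        subsets <- lapply(seq_len(mcd$n_data), function(i)
          sample_channel_subset(grid))
        out <- list()
        for (m in seq_len(mcd$n_model)) {
          masks_m <- unet_draw_masks(model$cfg, d[1], d[2])
          for (dd in seq_len(mcd$n_data))
            out[[length(out) + 1]] <- list(x = mask_input(subsets[[dd]]),
                                           masks = masks_m)
        }
        out
      })
    lapply(inputs_masks, function(im) {
      hm <- unet_forward(model, im$x, im$masks)
      pt <- heatmap_to_point(hm)
      o2 <- measure_o2satss(img, pt, ucfg, roi)
      c(pt[1], pt[2], o2)
    })
  })

  mat <- do.call(rbind, runs)
  samples <- data.frame(run = seq_len(nrow(mat)), x = mat[, 1],
                        y = mat[, 2], o2satss = mat[, 3])
  ok <- !is.na(samples$o2satss)
  eps <- if (any(ok)) sd_pop(samples$o2satss[ok]) else NA_real_
  structure(list(
    samples = samples,
    epsilon = eps,
    beta = if (is.na(eps)) NA_real_ else confidence_from_epsilon(eps / 100),
    xy_std = c(x = sd_pop(samples$x), y = sd_pop(samples$y)),
    n_failed = sum(!ok), mode = mcd$mode, n_runs = nrow(mat)),
    class = "pa_uncertainty_result")
}

#' Aggregate uncertainty over a dataset
#'
#' Mean of the per-sample standard deviations (mSTD) of the O2Satss
#' predictions and of the per-axis coordinate spreads, plus the dataset
#' confidence `1 - 2 * mSTD`.
#'
#' @param results list of `pa_uncertainty_result`.
#' @return list `mstd` (percentage points), `mean_beta`, `xy_mstd` (px).
#' @export
aggregate_mstd <- function(results) {
  if (length(results) == 0) stop("no uncertainty results to aggregate")
  stopifnot(all(vapply(results, inherits, TRUE, "pa_uncertainty_result")))
  eps <- vapply(results, `[[`, numeric(1), "epsilon")
  xy <- t(vapply(results, `[[`, numeric(2), "xy_std"))
  mstd <- mean(eps)
  list(mstd = mstd,
       mean_beta = confidence_from_epsilon(mstd / 100),
       xy_mstd = colMeans(xy))
}
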