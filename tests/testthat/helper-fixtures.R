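# Shared fixtures, built once per test run. Small phantoms keep the
# networks and unmixing fast; geometry is scaled with the frame so the
# SSS stays inside the reduced field of view.

small_phantom_config <- function(noise_sd = 0.02, ...) {
  phantom_config(image_h = 48, image_w = 64, sss_depth_mm = 10,
                 sss_depth_jitter_mm = 1, curvature_amplitude_mm = 3,
                 midline_jitter_px = 3, noise_sd = noise_sd, ...)
}

# memoized fixtures
.fx <- new.env()

fx_ref <- function() {
  if (is.null(.fx$ref)) .fx$ref <- build_reference_spectra(wavelength_grid())
  .fx$ref
}

fx_small_study <- function() {
  if (is.null(.fx$small)) {
    .fx$small <- generate_study(n_subjects = 3,
                                per_subject_counts = c(4, 3, 5),
                                cfg = small_phantom_config(), seed = 7)
  }
  .fx$small
}

fx_small_noiseless <- function() {
  if (is.null(.fx$small0)) {
    .fx$small0 <- generate_study(n_subjects = 3,
                                 per_subject_counts = c(4, 3, 5),
                                 cfg = small_phantom_config(noise_sd = 0),
                                 seed = 7)
  }
  .fx$small0
}

fx_small_ucfg <- function(noiseless = FALSE, cfg = small_phantom_config()) {
  unmix_config(fx_ref(), matched_compensation(cfg))
}

# independent two-endpoint linear-unmixing oracle: non-negative least
# squares over (HbO2, Hb) weights solved by closed form with boundary
# checks; saturation = w_HbO2 / (w_HbO2 + w_Hb).
oracle_unmix <- function(spectrum, grid = wavelength_grid()) {
  ext <- hb_extinction(grid)
  A <- cbind(ext[, "HbO2"], ext[, "Hb"])
  w <- tryCatch(solve(crossprod(A), crossprod(A, spectrum)),
                error = function(e) NULL)
  if (is.null(w) || any(w < 0)) {
    # clamp to each axis and keep the better fit
    w1 <- sum(A[, 1] * spectrum) / sum(A[, 1]^2)
    w2 <- sum(A[, 2] * spectrum) / sum(A[, 2]^2)
    r1 <- sum((spectrum - A[, 1] * max(w1, 0))^2)
    r2 <- sum((spectrum - A[, 2] * max(w2, 0))^2)
    w <- if (r1 < r2) c(max(w1, 0), 0) else c(0, max(w2, 0))
  }
  if (sum(w) == 0) return(NA_real_)
  100 * w[1] / (w[1] + w[2])
}

# Default-scale study and the two LOSO-trained localizers used by the
# held-out-accuracy acceptance check and the workflow-ordering test
# (training is expensive, so the fits are shared across test files).
fx_default_study <- function() {
  if (is.null(.fx$default)) .fx$default <- generate_study(seed = 6)
  .fx$default
}

fx_loso_fit <- function(hold) {
  key <- paste0("fit_", hold)
  if (is.null(.fx[[key]])) {
    ds <- fx_default_study()
    .fx[[key]] <- train_localizer(
      build_localizer(unet_config(), seed = 6),
      ds$samples[subject_of(ds) != hold],
      train_config(epochs = 30, learning_rate = 3e-3, seed = 6,
                   augment = FALSE))$model
  }
  .fx[[key]]
}

tiny_unet_cfg <- function(dropout_p = 0.5)
  unet_config(in_channels = 21, levels = 2, base_features = 2,
              dropout_p = dropout_p)

planted_entries <- function(gts, H = 26, W = 34, sss = c(16, 12),
                            roi = roi_params(1, -2, 3, 5, 0)) {
  # Maps whose ROI mean equals the ground truth ONLY for the planted
  # window: all planted-rectangle cells carry gt + delta except one
  # corner carrying gt - (n-1) delta, so any other window mixes in either
  # the +25 background or an unbalanced subset of the pattern.
  lapply(gts, function(gt) {
    v <- matrix(gt + 25, H, W)
    cx <- sss[1] + roi$b; cy <- sss[2] + roi$a
    xs <- (cx - floor(roi$d / 2)):(cx - floor(roi$d / 2) + roi$d - 1) + 1
    ys <- (cy - floor(roi$c / 2)):(cy - floor(roi$c / 2) + roi$c - 1) + 1
    n <- length(xs) * length(ys)
    delta <- 2
    v[ys, xs] <- gt + delta
    v[ys[1], xs[1]] <- gt - (n - 1) * delta
    list(map = structure(list(values = v, valid = matrix(TRUE, H, W)),
                         class = "pa_o2sat_map"),
         sss_xy = sss, gt = gt)
  })
}

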