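#' U-Net configuration for SSS landmark localization
#'
#' Architecture of the heatmap-regression network: a standard U-Net with
#' `levels` resolution levels, two 3x3 convolution + ReLU blocks per
#' level, 2x2 max-pooling down, nearest-neighbour upsampling with skip
#' concatenation up, and a linear 1x1 output convolution. Feature widths
#' double per level from `base_features` (8, 16, 32, 64 at the default
#' four levels, 64 at the deepest). Dropout follows every pooling and
#' every upsampling operation and can be re-enabled at inference for
#' Monte Carlo dropout.
#'
#' @param in_channels input channels (21 wavelengths).
#' @param out_channels output channels (1 heatmap).
#' @param levels resolution levels (>= 2).
#' @param base_features features at the finest level.
#' @param dropout_p dropout probability at each pool/upsample junction.
#' @return object of class `pa_unet_config`.
#' @export
unet_config <- function(in_channels = 21, out_channels = 1, levels = 4,
                        base_features = 8, dropout_p = 0.5) {
  stopifnot(levels >= 2, base_features >= 1,
            dropout_p >= 0, dropout_p < 1)
  structure(list(in_channels = in_channels, out_channels = out_channels,
                 levels = levels, base_features = base_features,
                 features = base_features * 2^(seq_len(levels) - 1),
                 dropout_p = dropout_p),
            class = "pa_unet_config")
}

#' Training configuration for the localizer
#'
#' Full-budget defaults: batch size 4, learning rate 1e-4, MSE loss,
#' Adam, 2000 epochs; `epochs` and `learning_rate`
#' scale down together for desk-scale runs.
#'
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param epochs passes over the training set (0 = no training).
#' @param seed RNG seed controlling initialization, shuffling,
#'   augmentation and dropout.
#' @param heatmap_sigma Gaussian std (px) of the target peak.
#' @param augment apply the training augmentations (rectification-k,
#'   geometric, channel subsets).
#' @param k_range rectification coefficient range during training.
#' @param channel_aug_p probability of the 5-channel input augmentation.
#' @param geometric an [augment_params()] list (or NULL to disable).
#' @param clip_norm global L2 gradient-norm ceiling per step (Inf
#'   disables clipping).
#' @return object of class `pa_train_config`.
#' @export
train_config <- function(batch_size = 4, learning_rate = 1e-4, epochs = 2000,
                         seed = 1, heatmap_sigma = 3, augment = TRUE,
                         k_range = c(0, 1), channel_aug_p = 0.5,
                         geometric = augment_params(), clip_norm = 1) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 0, clip_norm > 0)
  structure(list(batch_size = batch_size, learning_rate = learning_rate,
                 epochs = epochs, seed = seed,
                 heatmap_sigma = heatmap_sigma, augment = augment,
                 k_range = k_range, channel_aug_p = channel_aug_p,
                 geometric = geometric, clip_norm = clip_norm),
            class = "pa_train_config")
}

#' Build an untrained localizer
#'
#' @param cfg a [unet_config()].
#' @param seed seed for the (He-normal) weight initialization.
#' @return object of class `pa_localizer` holding the config and the
#'   parameter list.
#' @export
build_localizer <- function(cfg = unet_config(), seed = 1) {
  with_seed(derive_seed(seed, "unet-init"), {
    L <- cfg$levels
    f <- cfg$features
    enc <- vector("list", L)
    c_in <- cfg$in_channels
    for (l in seq_len(L)) {
      enc[[l]] <- list(c1 = conv_param(c_in, f[l]), c2 = conv_param(f[l], f[l]))
      c_in <- f[l]
    }
    dec <- vector("list", L - 1)
    for (l in seq(L - 1, 1)) {
      c_cat <- f[l + 1] + f[l]  # upsampled deeper features + skip
      dec[[l]] <- list(c1 = conv_param(c_cat, f[l]), c2 = conv_param(f[l], f[l]))
    }
    # near-zero head: the initial heatmap starts at ~0 (the target's own
    # background level), which removes the early training blow-up that
    # a full-scale random head can trigger under MSE
    out <- conv_param(f[1], cfg$out_channels, k = 1)
    out$W <- out$W * 0.02
    structure(list(cfg = cfg, params = list(enc = enc, dec = dec, out = out),
                   trained_epochs = 0L),
              class = "pa_localizer")
  })
}

check_unet_input <- function(cfg, x) {
  d <- dim(x)
  if (length(d) != 3 || d[3] != cfg$in_channels)
    stop("input must be H x W x ", cfg$in_channels)
  div <- 2^(cfg$levels - 1)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop("spatial dims (", d[1], " x ", d[2],
         ") must be divisible by ", div)
  invisible(d)
}

# Dropout mask shapes for one forward pass (after each pool, then after
# each upsample).
unet_mask_dims <- function(cfg, h, w) {
  L <- cfg$levels; f <- cfg$features
  dims <- list()
  for (l in seq_len(L - 1))            # after pool l
    dims[[l]] <- c(h / 2^l, w / 2^l, f[l])
  for (l in seq(L - 1, 1))             # after upsample into level l
    dims[[length(dims) + 1]] <- c(h / 2^(l - 1), w / 2^(l - 1), f[l + 1])
  dims
}

unet_draw_masks <- function(cfg, h, w) {
  lapply(unet_mask_dims(cfg, h, w), dropout_mask, p = cfg$dropout_p)
}

# Forward pass (src/unet.cpp). masks = NULL disables dropout
# (deterministic inference). Returns the H x W heatmap matrix.
unet_forward <- function(model, x, masks = NULL) {
  check_unet_input(model$cfg, x)
  unet_run(model$params, x, if (is.null(masks)) list() else masks,
           matrix(0, 0, 0), FALSE)$y
}

# One training evaluation: forward, MSE loss against the target heatmap,
# and gradients with respect to every parameter.
unet_loss_grad <- function(model, x, target, masks = NULL) {
  check_unet_input(model$cfg, x)
  unet_run(model$params, x, if (is.null(masks)) list() else masks,
           target, TRUE)
}

# Assemble (input array, target heatmap) for one training sample,
# applying the configured augmentations from the current RNG.
prepare_training_pair <- function(sample, cfg) {
  k <- if (cfg$augment) runif(1, cfg$k_range[1], cfg$k_range[2]) else 0.5
  x <- preprocess_for_localizer(sample$image, k = k)
  hm <- make_heatmap_target(sample$sss_xy, dim(x)[1:2],
                            sigma = cfg$heatmap_sigma)
  if (cfg$augment && !is.null(cfg$geometric)) {
    aug <- geometric_augment(x, hm, cfg$geometric)
    x <- aug$pixels; hm <- aug$heatmap
  }
  if (cfg$augment && runif(1) < cfg$channel_aug_p) {
    keep <- sample_channel_subset(sample$image$grid)
    idx <- match(keep, sample$image$grid$values)
    drop_idx <- setdiff(seq_len(dim(x)[3]), idx)
    x[, , drop_idx] <- 0
  }
  list(x = x, target = hm)
}

#' Train the localizer
#'
#' Minimizes the mean squared error between the predicted and target
#' heatmaps with Adam, applying the three training augmentation families
#' (rectification-coefficient jitter, paired geometric transforms, binned
#' 5-channel subsets) when enabled. Training is deterministic for a fixed
#' seed and configuration.
#'
#' @param model a [build_localizer()] model.
#' @param samples list of [sample_record()]s.
#' @param cfg a [train_config()].
#' @return list `model` (trained) and `history` (per-epoch mean loss).
#' @export
train_localizer <- function(model, samples, cfg = train_config()) {
  stopifnot(inherits(model, "pa_localizer"), length(samples) >= 1)
  if (cfg$epochs == 0)
    return(list(model = model, history = numeric(0)))
  ucfg <- model$cfg
  d <- image_dims(samples[[1]]$image)
  params <- model$params
  opt <- adam_init(params)
  history <- numeric(cfg$epochs)
  with_seed(derive_seed(cfg$seed, "unet-train"), {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(samples))
      ep_loss <- 0; n_batches <- 0
      for (b0 in seq(1, length(ord), by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, length(ord))]
        gacc <- NULL; bloss <- 0
        for (i in idx) {
          pair <- prepare_training_pair(samples[[i]], cfg)
          masks <- if (ucfg$dropout_p > 0)
            unet_draw_masks(ucfg, d[1], d[2]) else NULL
          fw <- unet_run(params, pair$x,
                         if (is.null(masks)) list() else masks,
                         pair$target, TRUE)
          if (!is.finite(fw$loss))
            stop("training aborted: non-finite loss at epoch ", ep,
                 " (sample ", i, ")")
          bloss <- bloss + fw$loss
          gacc <- grad_add(gacc, fw$grads)
        }
        gacc <- grad_clip(grad_scale(gacc, 1 / length(idx)), cfg$clip_norm)
        st <- adam_step(params, gacc, opt, cfg$learning_rate)
        params <- st$params; opt <- st$state
        ep_loss <- ep_loss + bloss / length(idx); n_batches <- n_batches + 1
      }
      history[ep] <- ep_loss / n_batches
    }
  })
  model$params <- params
  model$trained_epochs <- model$trained_epochs + cfg$epochs
  list(model = model, history = history)
}

#' Predict the SSS localization heatmap
#'
#' @param model a trained (or untrained) `pa_localizer`.
#' @param img a [spectral_image()] (preprocessed internally with the
#'   test-time contract: rectification at `k`, joint min-max
#'   normalization) or an already-preprocessed `H x W x C` array.
#' @param stochastic enable dropout at inference (Monte Carlo dropout);
#'   masks are drawn from the current RNG. `FALSE` gives deterministic
#'   output.
#' @param k test-time rectification coefficient.
#' @return `H x W` heatmap matrix.
#' @export
predict_heatmap <- function(model, img, stochastic = FALSE, k = 0.5) {
  x <- if (inherits(img, "pa_spectral_image"))
    preprocess_for_localizer(img, k = k) else img
  check_unet_input(model$cfg, x)
  masks <- if (stochastic && model$cfg$dropout_p > 0)
    unet_draw_masks(model$cfg, dim(x)[1], dim(x)[2]) else NULL
  unet_forward(model, x, masks)
}

#' Extract the landmark coordinate from a heatmap
#'
#' Returns the 0-based `(x, y)` coordinate of the heatmap maximum. Ties
#' are broken toward the smallest row-major index (smallest y, then
#' smallest x), so a uniform map yields `(0, 0)`.
#'
#' @param heatmap numeric matrix.
#' @return numeric `c(x, y)`, 0-based.
#' @export
heatmap_to_point <- function(heatmap) {
  if (length(heatmap) == 0 || all(is.na(heatmap)))
    stop("heatmap is empty or all-NA")
  mx <- max(heatmap, na.rm = TRUE)
  hits <- which(heatmap == mx, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  c(x = unname(hits[1, 2] - 1), y = unname(hits[1, 1] - 1))
}

#' Save / load a localizer checkpoint
#'
#' The checkpoint stores the architecture config, the weights and the
#' training provenance; `load_localizer` refuses checkpoints whose
#' config does not match `expected_cfg` when one is supplied.
#'
#' @param model a `pa_localizer`.
#' @param path file path.
#' @param expected_cfg optional [unet_config()] the checkpoint must match.
#' @return `save_localizer` the path invisibly; `load_localizer` the model.
#' @export
save_localizer <- function(model, path) {
  stopifnot(inherits(model, "pa_localizer"))
  saveRDS(list(schema = "paoxi-localizer", version = 1L, model = model),
          path, version = 3)
  invisible(path)
}

#' @rdname save_localizer
#' @export
load_localizer <- function(path, expected_cfg = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$schema, "paoxi-localizer"))
    stop("not a localizer checkpoint: ", path)
  model <- obj$model
  if (!is.null(expected_cfg) && !identical(unclass(expected_cfg),
                                           unclass(model$cfg)))
    stop("checkpoint config does not match the expected architecture")
  model
}
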