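#' Leave-one-subject-out folds
#'
#' One fold per subject: all of that subject's samples form the test set
#' and the remaining subjects' samples the training set, so every model is
#' evaluated on anatomy it has never seen. The test sets partition the
#' dataset.
#'
#' @param ds a [study_dataset()] with at least two subjects.
#' @return list of folds `list(held_out, train_subjects, train_idx,
#'   test_idx)`.
#' @export
loso_folds <- function(ds) {
  if (length(ds$subjects) < 2)
    stop("leave-one-subject-out requires at least two subjects")
  subj <- subject_of(ds)
  lapply(ds$subjects, function(s) {
    list(held_out = s,
         train_subjects = setdiff(ds$subjects, s),
         train_idx = which(subj != s),
         test_idx = which(subj == s))
  })
}

#' Regression agreement metrics
#'
#' Ordinary least squares of the predicted O2Satss on the ground-truth
#' readings; the fit's R-squared is the headline goodness-of-fit measure.
#'
#' @param pred,gt numeric vectors of equal length (>= 3).
#' @return list `r_squared`, `slope`, `intercept`, `n`. All `NA` (flagged
#'   undefined) when the ground truth has zero variance.
#' @export
regression_metrics <- function(pred, gt) {
  stopifnot(length(pred) == length(gt), length(gt) >= 3)
  ok <- !is.na(pred) & !is.na(gt)
  pred <- pred[ok]; gt <- gt[ok]
  if (length(gt) < 3 || sd(gt) == 0)
    return(list(r_squared = NA_real_, slope = NA_real_,
                intercept = NA_real_, n = length(gt)))
  if (sd(pred) == 0)  # constant predictor explains nothing
    return(list(r_squared = 0, slope = 0, intercept = mean(pred),
                n = length(gt)))
  fit <- stats::lm(pred ~ gt)
  # suppress the benign perfect-fit note from summary.lm
  list(r_squared = suppressWarnings(summary(fit)$r.squared),
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n = length(gt))
}

#' Hypoxia classification metrics
#'
#' Hypoxia (`value < threshold`, strict) is the positive class;
#' `threshold = 30` percent is the clinical boundary between hypoxia and
#' normoxia. A metric whose class is absent from the ground truth is
#' returned as `NA` (undefined), not 0.
#'
#' @param preds,gts numeric vectors (percent).
#' @param threshold classification boundary (percent).
#' @return list `sensitivity`, `specificity`, and confusion counts
#'   `tp`, `fn`, `tn`, `fp`.
#' @export
classify_and_score <- function(preds, gts, threshold = 30) {
  stopifnot(length(preds) == length(gts))
  ok <- !is.na(preds) & !is.na(gts)
  pc <- preds[ok] < threshold
  gc <- gts[ok] < threshold
  tp <- sum(pc & gc); fn <- sum(!pc & gc)
  tn <- sum(!pc & !gc); fp <- sum(pc & !gc)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fn = fn, tn = tn, fp = fp)
}

#' Curation check: series must start healthy
#'
#' Every acquisition series starts at the highest FiO2, so the first
#' sample's ground-truth O2Satss is expected to be normoxic
#' (>= threshold); a hypoxic first reading indicates a corrupted series
#' (catheter displacement, blood-gas contamination) and flags the subject
#' for exclusion. Report-only.
#'
#' @param ds a [study_dataset()] with samples in acquisition order.
#' @param threshold hypoxia boundary (percent).
#' @return data.frame `subject`, `pass`, `reason`.
#' @export
curation_check <- function(ds, threshold = 30) {
  subj <- subject_of(ds)
  rows <- lapply(ds$subjects, function(s) {
    idx <- which(subj == s)
    if (length(idx) == 0)
      return(data.frame(subject = s, pass = FALSE, reason = "no samples"))
    first <- ds$samples[[idx[1]]]$o2satss_gt
    if (first < threshold)
      data.frame(subject = s, pass = FALSE,
                 reason = sprintf("first sample hypoxic (%.1f%% < %g%%)",
                                  first, threshold))
    else data.frame(subject = s, pass = TRUE, reason = "")
  })
  do.call(rbind, rows)
}

#' End-to-end baseline input assembly
#'
#' Builds the network input of the four end-to-end regression baselines:
#' `M1` the jointly min-max-normalized 21-channel raw stack (no
#' rectification, so the spectral ratios the regressor needs are kept);
#' `M2` the 1-channel O2Sat map unmixed only in the window around the SSS
#' and zero elsewhere (scaled to `[0, 1]`); `M3` the 22-channel
#' concatenation of both; `M4` a 20 x 20 crop of the M3 stack centred on
#' the SSS (zero-padded with a warning if the crop leaves the frame).
#'
#' @param sample a [sample_record()].
#' @param variant `"M1"`, `"M2"`, `"M3"` or `"M4"`.
#' @param sss_xy SSS location for M2-M4 (defaults to the annotation).
#' @param ucfg an [unmix_config()] (required for M2-M4).
#' @param patch_px M4 crop edge (px).
#' @return numeric array `H x W x C` (or `patch_px x patch_px x 22`).
#' @export
assemble_baseline_input <- function(sample, variant = c("M1", "M2", "M3", "M4"),
                                    sss_xy = NULL, ucfg = NULL,
                                    patch_px = 20) {
  variant <- match.arg(variant)
  raw <- function() minmax_normalize(sample$image, "joint")$pixels
  o2map <- function() {
    if (is.null(ucfg)) stop(variant, " requires an unmix_config")
    xy <- if (is.null(sss_xy)) sample$sss_xy else sss_xy
    m <- unmix_region(sample$image, xy, ucfg)
    v <- m$values / 100
    v[!m$valid] <- 0
    v
  }
  if (variant == "M1") return(raw())
  if (variant == "M2") {
    v <- o2map()
    return(array(v, dim = c(dim(v), 1)))
  }
  stack <- array(c(raw(), o2map()),
                 dim = c(dim(raw())[1:2], dim(raw())[3] + 1))
  if (variant == "M3") return(stack)
  # M4: patch crop around the SSS
  xy <- round(if (is.null(sss_xy)) sample$sss_xy else sss_xy)
  H <- dim(stack)[1]; W <- dim(stack)[2]
  b <- c(x0 = xy[1] - floor(patch_px / 2), y0 = xy[2] - floor(patch_px / 2))
  out <- array(0, dim = c(patch_px, patch_px, dim(stack)[3]))
  xs <- b["x0"]:(b["x0"] + patch_px - 1)
  ys <- b["y0"]:(b["y0"] + patch_px - 1)
  in_x <- xs >= 0 & xs <= W - 1
  in_y <- ys >= 0 & ys <= H - 1
  if (!all(in_x) || !all(in_y))
    warning("M4 patch extends beyond the frame; zero-padded")
  out[which(in_y), which(in_x), ] <-
    stack[ys[in_y] + 1, xs[in_x] + 1, , drop = FALSE]
  out
}

# ---- LeNet-type O2Sat regressor (PredNet) ----------------------------------

#' Build the end-to-end O2Sat regressor
#'
#' A small LeNet-type CNN: two 3x3 conv + ReLU + 2x2 max-pool blocks
#' followed by two dense layers for the full-frame variants, and a single
#' conv + pool block with one hidden dense layer for the 20 x 20 patch
#' variant (`small = TRUE`). Output is a single linear unit predicting
#' O2Satss in percent.
#'
#' @param in_channels input channels.
#' @param input_hw spatial input shape `c(H, W)`.
#' @param small use the reduced patch architecture.
#' @param seed weight-initialization seed.
#' @return object of class `pa_prednet`.
#' @export
build_prednet <- function(in_channels, input_hw, small = FALSE, seed = 1) {
  H <- input_hw[1]; W <- input_hw[2]
  div <- if (small) 2 else 4
  if (H %% div != 0 || W %% div != 0)
    stop("input dims must be divisible by ", div)
  with_seed(derive_seed(seed, "prednet-init"), {
    if (small) {
      flat <- (H / 2) * (W / 2) * 8
      params <- list(conv1 = conv_param(in_channels, 8),
                     fc1 = dense_param(flat, 32),
                     fc2 = dense_param(32, 1))
    } else {
      flat <- (H / 4) * (W / 4) * 16
      params <- list(conv1 = conv_param(in_channels, 8),
                     conv2 = conv_param(8, 16),
                     fc1 = dense_param(flat, 64),
                     fc2 = dense_param(64, 1))
    }
    structure(list(params = params, small = small,
                   in_channels = in_channels, input_hw = c(H, W)),
              class = "pa_prednet")
  })
}

prednet_forward <- function(net, x, keep_cache = FALSE) {
  p <- net$params
  a1 <- relu(conv3_fwd(x, p$conv1$W, p$conv1$b))
  p1 <- maxpool2_fwd(a1)
  if (net$small) {
    flat <- as.numeric(p1$y)
    h <- relu(dense_fwd(flat, p$fc1))
    y <- dense_fwd(h, p$fc2)
    cache <- if (keep_cache) list(x = x, a1 = a1, p1 = p1, flat = flat, h = h)
  } else {
    a2 <- relu(conv3_fwd(p1$y, p$conv2$W, p$conv2$b))
    p2 <- maxpool2_fwd(a2)
    flat <- as.numeric(p2$y)
    h <- relu(dense_fwd(flat, p$fc1))
    y <- dense_fwd(h, p$fc2)
    cache <- if (keep_cache)
      list(x = x, a1 = a1, p1 = p1, a2 = a2, p2 = p2, flat = flat, h = h)
  }
  list(y = y, cache = cache)
}

prednet_backward <- function(net, cache, dy) {
  p <- net$params
  g <- list()
  b2 <- dense_bwd(cache$h, p$fc2, dy)
  g$fc2 <- list(W = b2$dW, b = b2$db)
  dh <- relu_bwd(b2$dx, cache$h)
  b1 <- dense_bwd(cache$flat, p$fc1, dh)
  g$fc1 <- list(W = b1$dW, b = b1$db)
  if (net$small) {
    dp1 <- array(b1$dx, dim = dim(cache$p1$y))
    da1 <- maxpool2_bwd(cache$p1$idx, dp1,
                        dim(cache$a1)[1], dim(cache$a1)[2])
    da1 <- relu_bwd(da1, cache$a1)
    c1 <- conv3_bwd(cache$x, p$conv1$W, da1)
    g$conv1 <- list(W = c1$dw, b = c1$db)
  } else {
    dp2 <- array(b1$dx, dim = dim(cache$p2$y))
    da2 <- maxpool2_bwd(cache$p2$idx, dp2,
                        dim(cache$a2)[1], dim(cache$a2)[2])
    da2 <- relu_bwd(da2, cache$a2)
    c2 <- conv3_bwd(cache$p1$y, p$conv2$W, da2)
    g$conv2 <- list(W = c2$dw, b = c2$db)
    dp1 <- maxpool2_bwd(cache$p1$idx, c2$dx,
                        dim(cache$a1)[1], dim(cache$a1)[2])
    dp1 <- relu_bwd(dp1, cache$a1)
    c1 <- conv3_bwd(cache$x, p$conv1$W, dp1)
    g$conv1 <- list(W = c1$dw, b = c1$db)
  }
  g[names(net$params)]
}

# One balanced minibatch: each slot picks the hypoxia or the normoxia
# group with probability 1/2, then a uniform member (with replacement),
# so a ~70%-hypoxic dataset still trains on a ~50/50 stream.
balanced_batch_idx <- function(grp_h, grp_n, batch_size) {
  pick_h <- runif(batch_size) < 0.5
  from_h <- grp_h[sample.int(length(grp_h), batch_size, replace = TRUE)]
  from_n <- grp_n[sample.int(length(grp_n), batch_size, replace = TRUE)]
  ifelse(pick_h, from_h, from_n)
}

#' Training configuration for the end-to-end regressor
#'
#' Full-budget defaults for the O2Sat regressor: batch size 8, learning
#' rate 1e-6, MSE loss, Adam, 10000 epochs; `epochs`
#' scales down for desk-scale runs.
#'
#' @param batch_size,learning_rate,epochs,seed as in [train_config()].
#' @param augment apply geometric augmentation to the input stacks.
#' @param geometric an [augment_params()] list.
#' @return object of class `pa_prednet_train_config`.
#' @export
prednet_train_config <- function(batch_size = 8, learning_rate = 1e-6,
                                 epochs = 10000, seed = 1, augment = TRUE,
                                 geometric = augment_params()) {
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 0)
  structure(list(batch_size = batch_size, learning_rate = learning_rate,
                 epochs = epochs, seed = seed, augment = augment,
                 geometric = geometric),
            class = "pa_prednet_train_config")
}

#' Train an end-to-end baseline regressor
#'
#' Minimizes the squared error of the scalar O2Satss prediction with
#' Adam. Because ~70% of samples are hypoxic under the declining-FiO2
#' protocol, minibatches draw from the hypoxia and normoxia groups with
#' equal probability (with replacement) to counter the class imbalance;
#' both groups must be represented.
#'
#' @param variant `"M1"`..`"M4"`.
#' @param samples training [sample_record()]s.
#' @param ucfg an [unmix_config()] (needed for M2-M4 inputs).
#' @param cfg a [prednet_train_config()].
#' @param threshold hypoxia boundary used for the balanced sampler.
#' @return list `model` (a `pa_prednet`), `history` (per-epoch mean
#'   loss), `variant`.
#' @export
train_baseline <- function(variant, samples, ucfg = NULL,
                           cfg = prednet_train_config(), threshold = 30) {
  gts <- vapply(samples, `[[`, numeric(1), "o2satss_gt")
  grp_h <- which(gts < threshold)
  grp_n <- which(gts >= threshold)
  if (cfg$epochs > 0 && (length(grp_h) == 0 || length(grp_n) == 0))
    stop("balanced sampling needs both hypoxic and normoxic samples")

  inputs <- lapply(samples, assemble_baseline_input, variant = variant,
                   ucfg = ucfg)
  hw <- dim(inputs[[1]])[1:2]
  net <- build_prednet(dim(inputs[[1]])[3], hw,
                       small = identical(variant, "M4"), seed = cfg$seed)
  if (cfg$epochs == 0)
    return(list(model = net, history = numeric(0), variant = variant))

  params <- net$params
  opt <- adam_init(params)
  steps_per_epoch <- max(1L, ceiling(length(samples) / cfg$batch_size))
  history <- numeric(cfg$epochs)
  with_seed(derive_seed(cfg$seed, "prednet-train"), {
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0
      for (st in seq_len(steps_per_epoch)) {
        idx <- balanced_batch_idx(grp_h, grp_n, cfg$batch_size)
        gacc <- NULL; bloss <- 0
        for (i in idx) {
          x <- inputs[[i]]
          if (cfg$augment && !is.null(cfg$geometric)) {
            maps <- random_transform_maps(hw, cfg$geometric)
            x <- bilinear_warp(x, maps$map_y, maps$map_x)
          }
          net$params <- params
          fw <- prednet_forward(net, x, keep_cache = TRUE)
          resid <- fw$y - gts[i]
          if (!is.finite(resid))
            stop("training aborted: non-finite loss at epoch ", ep)
          bloss <- bloss + resid^2
          gacc <- grad_add(gacc,
                           prednet_backward(net, fw$cache, 2 * resid))
        }
        gacc <- grad_scale(gacc, 1 / length(idx))
        stp <- adam_step(params, gacc, opt, cfg$learning_rate)
        params <- stp$params; opt <- stp$state
        ep_loss <- ep_loss + bloss / length(idx)
      }
      history[ep] <- ep_loss / steps_per_epoch
    }
  })
  net$params <- params
  list(model = net, history = history, variant = variant)
}

#' Predict O2Satss with a trained baseline regressor
#'
#' @param fit result of [train_baseline()].
#' @param sample a [sample_record()].
#' @param ucfg an [unmix_config()] (M2-M4).
#' @param sss_xy SSS location override for M2-M4 (default: annotation).
#' @return predicted O2Satss (percent).
#' @export
predict_baseline <- function(fit, sample, ucfg = NULL, sss_xy = NULL) {
  x <- assemble_baseline_input(sample, fit$variant, sss_xy = sss_xy,
                               ucfg = ucfg)
  prednet_forward(fit$model, x)$y
}

#' Cross-validated end-to-end evaluation of a measurement workflow
#'
#' Runs leave-one-subject-out evaluation of one of the O2Satss estimation
#' workflows and pools the held-out predictions: `two_step` trains the
#' landmark localizer per fold, localizes the SSS on the held-out
#' subject, and measures O2Satss by ROI-averaged spectral unmixing;
#' `gt` is the same measurement at the expert/true annotation (no
#' training); `M1`-`M4` train the end-to-end CNN regressors (`M4` uses
#' the annotation for its patch crop by default). Measurement failures
#' are reported and excluded from the regression.
#'
#' @param ds a [study_dataset()].
#' @param mode workflow to evaluate.
#' @param ucfg an [unmix_config()].
#' @param roi a [roi_params()].
#' @param loc_cfg a [train_config()] (two_step).
#' @param prednet_cfg a [prednet_train_config()] (M1-M4).
#' @param folds optionally a subset of [loso_folds()] to run.
#' @param threshold hypoxia boundary (percent).
#' @return object of class `pa_eval_report`: `metrics` (regression +
#'   classification + localization error when applicable), `per_sample`
#'   data frame, `mode`, `n_failed`.
#' @export
run_full_pipeline <- function(ds, mode = c("two_step", "gt", "M1", "M2",
                                           "M3", "M4"),
                              ucfg, roi = roi_params(),
                              loc_cfg = train_config(),
                              prednet_cfg = prednet_train_config(),
                              folds = NULL, threshold = 30) {
  mode <- match.arg(mode)
  if (is.null(folds)) folds <- loso_folds(ds)
  subj <- subject_of(ds)
  rows <- list()

  for (f in folds) {
    stopifnot(!f$held_out %in% subj[f$train_idx])  # no leakage
    train_samples <- ds$samples[f$train_idx]
    predictor <- switch(mode,
      gt = function(s) list(pred = measure_o2satss(s$image, s$sss_xy,
                                                   ucfg, roi),
                            loc = s$sss_xy),
      two_step = {
        model <- build_localizer(unet_config(
          in_channels = length(ds$samples[[1]]$image$grid$values)),
          seed = loc_cfg$seed)
        model <- train_localizer(model, train_samples, loc_cfg)$model
        function(s) {
          pt <- heatmap_to_point(predict_heatmap(model, s$image))
          list(pred = measure_o2satss(s$image, pt, ucfg, roi), loc = pt)
        }
      },
      {
        fit <- train_baseline(mode, train_samples, ucfg, prednet_cfg,
                              threshold)
        function(s) list(pred = predict_baseline(fit, s, ucfg), loc = NULL)
      })
    for (i in f$test_idx) {
      s <- ds$samples[[i]]
      out <- predictor(s)
      rows[[length(rows) + 1]] <- data.frame(
        subject = s$subject_id, fold = f$held_out, sample_idx = i,
        gt = s$o2satss_gt, pred = out$pred,
        loc_x = if (is.null(out$loc)) NA_real_ else out$loc[1],
        loc_y = if (is.null(out$loc)) NA_real_ else out$loc[2],
        ann_x = s$sss_xy[1], ann_y = s$sss_xy[2])
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$pred)
  reg <- regression_metrics(tab$pred[ok], tab$gt[ok])
  cls <- classify_and_score(tab$pred[ok], tab$gt[ok], threshold)
  loc_err <- if (mode == "two_step")
    mean(sqrt((tab$loc_x - tab$ann_x)^2 + (tab$loc_y - tab$ann_y)^2),
         na.rm = TRUE) else NA_real_
  structure(list(
    metrics = c(reg, cls, list(mean_loc_error_px = loc_err)),
    per_sample = tab, mode = mode, n_failed = sum(!ok)),
    class = "pa_eval_report")
}
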