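test_that("LOSO folds partition the dataset by subject", {
  ds <- fx_small_study()
  folds <- loso_folds(ds)
  expect_length(folds, 3)
  test_idx <- sort(unlist(lapply(folds, `[[`, "test_idx")))
  expect_equal(test_idx, seq_along(ds$samples))  # partition, no overlap
  for (f in folds) {
    expect_false(f$held_out %in% f$train_subjects)
    expect_setequal(c(f$held_out, f$train_subjects), ds$subjects)
    expect_length(intersect(f$train_idx, f$test_idx), 0)
  }
  two <- study_dataset(ds$samples[subject_of(ds) %in% c("S01", "S02")])
  expect_length(loso_folds(two), 2)
  one <- study_dataset(ds$samples[subject_of(ds) == "S01"])
  expect_error(loso_folds(one), "at least two subjects")
})

test_that("regression metrics reproduce hand-computed OLS fits", {
  m <- regression_metrics(c(0, 10, 20), c(0, 10, 20))
  expect_equal(c(m$r_squared, m$slope, m$intercept), c(1, 1, 0))
  m2 <- regression_metrics(c(2, 12, 22), c(0, 10, 20))
  expect_equal(c(m2$r_squared, m2$slope, m2$intercept), c(1, 1, 2))
  m3 <- regression_metrics(c(10, 10, 10), c(0, 10, 20))
  expect_equal(m3$slope, 0)
  expect_equal(m3$r_squared, 0)
  m4 <- regression_metrics(c(1, 2, 3), c(5, 5, 5))
  expect_true(is.na(m4$r_squared))  # zero-variance ground truth flagged
  expect_error(regression_metrics(1:2, 1:2), "length")
})

test_that("hypoxia classification uses the strict 30% boundary", {
  cs <- classify_and_score(c(29.9, 30.0), c(10, 50))
  expect_equal(cs$tp, 1)  # 29.9 is hypoxia
  expect_equal(cs$tn, 1)  # 30.0 is normoxia
  # confusion counts consistent with the reference classification rates
  preds <- c(rep(10, 46), rep(40, 8), rep(50, 28), rep(20, 2))
  gts <- c(rep(15, 54), rep(60, 30))
  cs2 <- classify_and_score(preds, gts)
  expect_equal(c(cs2$tp, cs2$fn, cs2$tn, cs2$fp), c(46, 8, 28, 2))
  expect_equal(cs2$sensitivity, 46 / 54, tolerance = 1e-12)
  expect_equal(cs2$specificity, 28 / 30, tolerance = 1e-12)
  expect_equal(round(cs2$sensitivity, 3), 0.852)
  expect_equal(round(cs2$specificity, 3), 0.933)
  perfect <- classify_and_score(c(10, 50), c(20, 70))
  expect_equal(c(perfect$sensitivity, perfect$specificity), c(1, 1))
  onesided <- classify_and_score(c(10, 20), c(10, 20))
  expect_true(is.na(onesided$specificity))
  expect_equal(onesided$sensitivity, 1)
})

test_that("curation check flags series that start hypoxic", {
  ds <- fx_small_study()
  rep <- curation_check(ds)
  expect_true(all(rep$pass))  # generator guarantees healthy starts

  bad <- ds
  first_s2 <- which(subject_of(ds) == "S02")[1]
  bad$samples[[first_s2]]$o2satss_gt <- 22
  rep2 <- curation_check(bad)
  expect_false(rep2$pass[rep2$subject == "S02"])
  expect_match(rep2$reason[rep2$subject == "S02"], "first sample hypoxic")

  ghost <- ds
  ghost$subjects <- c(ghost$subjects, "SX")
  rep3 <- curation_check(ghost)
  expect_match(rep3$reason[rep3$subject == "SX"], "no samples")
})

test_that("baseline inputs have the documented channels and masking", {
  ds <- fx_small_study()
  s <- ds$samples[[1]]
  ucfg <- fx_small_ucfg()
  m1 <- assemble_baseline_input(s, "M1")
  expect_equal(dim(m1)[3], 21)
  expect_equal(range(m1), c(0, 1))
  m2 <- assemble_baseline_input(s, "M2", ucfg = ucfg)
  expect_equal(dim(m2)[3], 1)
  # pixels outside the unmixing window are exactly zero
  b <- unmix_region(s$image, s$sss_xy, ucfg)
  expect_true(all(m2[, , 1][!b$valid] == 0))
  m3 <- assemble_baseline_input(s, "M3", ucfg = ucfg)
  expect_equal(dim(m3)[3], 22)
  expect_equal(m3[, , 1:21], m1)
  m4 <- assemble_baseline_input(s, "M4", ucfg = ucfg)
  expect_equal(dim(m4), c(20, 20, 22))
  # crop centred near a corner pads with zeros and warns
  expect_warning(m4c <- assemble_baseline_input(s, "M4", sss_xy = c(2, 2),
                                                ucfg = ucfg),
                 "zero-padded")
  expect_equal(dim(m4c), c(20, 20, 22))
  expect_true(all(m4c[, 1:8, ] == 0))  # out-of-frame columns zero-padded
})

test_that("balanced sampler draws both classes with equal probability", {
  grp_h <- 1:70; grp_n <- 71:100
  draws <- with_seed(8, balanced_batch_idx(grp_h, grp_n, 10000))
  expect_equal(mean(draws <= 70), 0.5, tolerance = 0.02)
  expect_true(all(draws %in% 1:100))
})

test_that("the end-to-end regressor trains, and degenerates gracefully", {
  ds <- fx_small_study()
  samples <- ds$samples
  ucfg <- fx_small_ucfg()
  cfg <- prednet_train_config(epochs = 15, learning_rate = 1e-3,
                              seed = 3, augment = FALSE)
  fit <- train_baseline("M1", samples, ucfg, cfg)
  expect_length(fit$history, 15)
  expect_lt(mean(tail(fit$history, 3)), fit$history[1])
  pred <- predict_baseline(fit, samples[[1]], ucfg)
  expect_true(is.finite(pred))

  fit0 <- train_baseline("M4", samples, ucfg,
                         prednet_train_config(epochs = 0))
  expect_length(fit0$history, 0)
  expect_true(fit0$model$small)

  allhyp <- samples[vapply(samples, function(s) s$o2satss_gt < 30,
                           logical(1))]
  expect_error(train_baseline("M1", allhyp, ucfg, cfg), "both hypoxic")
})

test_that("two-step workflow outperforms the full-frame regressor", {
  # the anatomical-landmark route concentrates the training signal, so at
  # an equal (desk-scale) epoch budget it dominates end-to-end regression
  # from the full 21-channel frame; pooled over two held-out subjects of
  # the default study, reusing the LOSO localizers trained for the
  # held-out-accuracy check
  ds <- fx_default_study()
  subj <- subject_of(ds)
  ucfg <- unmix_config(fx_ref(), matched_compensation(phantom_config()))
  roi <- roi_params(0, 0, 4, 4, 1)
  rows <- list()
  for (hold in c("S01", "S02")) {
    model <- fx_loso_fit(hold)
    m1 <- train_baseline("M1", ds$samples[subj != hold], ucfg,
                         prednet_train_config(epochs = 30, seed = 6,
                                              augment = FALSE))
    for (s in ds$samples[subj == hold]) {
      pt <- heatmap_to_point(predict_heatmap(model, s$image))
      rows[[length(rows) + 1]] <- data.frame(
        gt = s$o2satss_gt,
        two_step = measure_o2satss(s$image, pt, ucfg, roi),
        m1 = predict_baseline(m1, s, ucfg))
    }
  }
  tab <- do.call(rbind, rows)
  r2_ts <- regression_metrics(tab$two_step, tab$gt)$r_squared
  r2_m1 <- regression_metrics(tab$m1, tab$gt)$r_squared
  expect_gt(r2_ts, r2_m1)
})

test_that("GT-annotation pipeline is near-exact on noiseless phantoms", {
  ds <- fx_small_noiseless()
  ucfg <- unmix_config(fx_ref(),
                       matched_compensation(small_phantom_config(noise_sd = 0)))
  rep <- run_full_pipeline(ds, "gt", ucfg, roi_params(a = 0, b = 0,
                                                      c_edge = 4, d_edge = 4,
                                                      sigma = 0))
  expect_equal(rep$n_failed, 0)
  expect_equal(nrow(rep$per_sample), length(ds$samples))
  expect_gt(rep$metrics$r_squared, 0.99)
  expect_true(all(abs(rep$per_sample$pred - rep$per_sample$gt) <= 1))
  # fold count equals subject count; each sample used exactly once
  expect_setequal(rep$per_sample$sample_idx, seq_along(ds$samples))
})
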