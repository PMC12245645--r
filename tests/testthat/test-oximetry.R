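test_that("attenuation compensation is an exact elementwise gain", {
  comp <- compensation_profile(rep(1, 21), 20)
  x <- runif(21)
  expect_equal(compensate_spectrum(x, comp), x)
  expect_equal(compensate_spectrum(rep(0, 21), comp), rep(0, 21))
  comp2 <- compensation_profile(exp(seq(0.1, 2, length.out = 21)), 20)
  expect_equal(compensate_spectrum(x, comp2), x * comp2$gains)
  expect_error(compensate_spectrum(runif(20), comp), "does not match")
})

test_that("matched compensation undoes the phantom attenuation exactly", {
  cfg <- small_phantom_config(noise_sd = 0)
  ref <- fx_ref()
  an <- with_seed(3, generate_anatomy(cfg))
  an <- set_sss_o2sat(an, 62)
  img <- with_seed(4, render_spectral_image(an, ref, cfg, intensity_scale = 5e4))
  comp <- matched_compensation(cfg)
  xy <- an$sss_xy
  depth_mm <- xy[2] * cfg$pixel_spacing_mm
  spec <- img$pixels[xy[2] + 1, xy[1] + 1, ]
  gains <- comp$gains ^ (depth_mm / comp$reference_depth_mm)
  recovered <- spec * gains
  # pre-attenuation spectrum is proportional to the reference blend
  blend <- reference_spectrum(ref, 62)
  ratio <- recovered / blend
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-9)
})

test_that("pixel unmixing recovers pure and scaled reference rows", {
  ref <- fx_ref()
  ucfg <- unmix_config(ref, compensation_profile(rep(1, 21), 20))
  expect_equal(unmix_pixel(reference_spectrum(ref, 70), ucfg), 70)
  expect_equal(unmix_pixel(0.5 * reference_spectrum(ref, 40), ucfg), 40)
  expect_true(is.na(unmix_pixel(rep(0, 21), ucfg)))
  # scale invariance with the free-amplitude fit
  sp <- reference_spectrum(ref, 23) + 0.02 * mean(reference_spectrum(ref, 23))
  for (alpha in c(1e-4, 0.1, 7, 1e5))
    expect_equal(unmix_pixel(alpha * sp, ucfg), unmix_pixel(sp, ucfg))
  # the literal fixed-amplitude fit is sensitive to scale by design
  lit <- unmix_config(ref, compensation_profile(rep(1, 21), 20),
                      fit_scale = FALSE)
  expect_equal(unmix_pixel(reference_spectrum(ref, 70), lit), 70)
})

test_that("grid unmixing agrees with the two-endpoint closed-form oracle", {
  ref <- fx_ref()
  ucfg <- unmix_config(ref, compensation_profile(rep(1, 21), 20))
  blends <- with_seed(31, {
    s_true <- runif(300, 0, 100)
    amp <- 10^runif(300, -2, 2)
    list(s = s_true, amp = amp)
  })
  for (i in seq_len(300)) {
    sp <- blends$amp[i] * reference_spectrum(ref, blends$s[i])
    est <- unmix_pixel(sp, ucfg)
    orc <- oracle_unmix(sp)
    expect_lt(abs(est - orc), 1 + 1e-9)  # within one grid step
    expect_lt(abs(est - blends$s[i]), 0.5 + 1e-9)
  }
})

test_that("region unmixing handles windows, clipping and invalid pixels", {
  ref <- fx_ref()
  grid <- wavelength_grid()
  H <- 20; W <- 30
  px <- array(0, c(H, W, 21))
  blend <- reference_spectrum(ref, 55)
  for (l in 1:21) px[5:16, 4:25, l] <- blend[l]
  img <- spectral_image(px, grid)
  ucfg <- unmix_config(ref, compensation_profile(rep(1, 21), 20),
                       region_h = 8, region_w = 10, per_depth = FALSE)
  m <- unmix_region(img, c(14, 10), ucfg)
  expect_true(all(m$values[m$valid] == 55))
  expect_equal(sum(m$valid), 8 * 10)
  expect_true(all(is.na(m$values[!m$valid])))
  # corner centre clips without out-of-bounds access
  m2 <- unmix_region(img, c(0, 0), ucfg)
  expect_lte(sum(m2$valid | !m2$valid & FALSE, na.rm = TRUE), H * W)
  expect_true(all(which(m2$valid, arr.ind = TRUE)[, "col"] <= 6))
  # all-zero image yields no valid pixels
  zero <- spectral_image(array(0, c(H, W, 21)), grid)
  expect_equal(sum(unmix_region(zero, c(14, 10), ucfg)$valid), 0)
  expect_error(unmix_region(img, c(40, 10), ucfg), "outside")
})

test_that("map smoothing is mask-normalized and sigma = 0 is the identity", {
  v <- matrix(NA_real_, 9, 9)
  v[3:7, 3:7] <- 50
  map <- structure(list(values = v, valid = !is.na(v)),
                   class = "pa_o2sat_map")
  expect_equal(smooth_o2sat_map(map, 0)$values, v)
  # constant maps are fixed points for any sigma
  for (sg in c(1, 2.5))
    expect_equal(smooth_o2sat_map(map, sg)$values[3:7, 3:7],
                 v[3:7, 3:7], tolerance = 1e-9)
  # single spike: centre value equals the mask-normalized kernel weight
  sp <- matrix(0, 9, 9); sp[5, 5] <- 80
  spike <- structure(list(values = sp, valid = matrix(TRUE, 9, 9)),
                     class = "pa_o2sat_map")
  sm <- smooth_o2sat_map(spike, 1)
  # direct 2-D Gaussian convolution oracle (kernel truncated at 3 sigma,
  # matching the implementation's support)
  g1 <- function(d, s) exp(-d^2 / (2 * s^2))
  ker <- outer(g1(-3:3, 1), g1(-3:3, 1))
  num <- 0; den <- 0
  for (dy in -3:3) for (dx in -3:3) {
    yy <- 5 + dy; xx <- 5 + dx
    if (yy < 1 || yy > 9 || xx < 1 || xx > 9) next
    w <- ker[dy + 4, dx + 4]
    num <- num + w * sp[yy, xx]; den <- den + w
  }
  expect_equal(sm$values[5, 5], num / den, tolerance = 1e-4)
  # invalid pixels never dilute the valid ones
  half <- structure(list(values = cbind(matrix(60, 6, 3),
                                        matrix(NA_real_, 6, 3)),
                         valid = cbind(matrix(TRUE, 6, 3),
                                       matrix(FALSE, 6, 3))),
                    class = "pa_o2sat_map")
  sm2 <- smooth_o2sat_map(half, 2)
  expect_equal(sm2$values[, 1:3], matrix(60, 6, 3), tolerance = 1e-9)
  expect_true(all(is.na(sm2$values[, 4:6])))
})

test_that("ROI extraction averages valid pixels in the displaced rectangle", {
  uni <- structure(list(values = matrix(42, 30, 40),
                        valid = matrix(TRUE, 30, 40)),
                   class = "pa_o2sat_map")
  for (r in list(roi_params(), roi_params(0, 0, 2, 2, 0),
                 roi_params(-3, 5, 7, 3, 1)))
    expect_equal(extract_o2satss(uni, c(20, 15), r), 42)
  # 2 x 2 ROI over {10, 20, 30, 40} -> 25
  v <- matrix(NA_real_, 10, 10)
  v[5:6, 5:6] <- c(10, 20, 30, 40)
  m <- structure(list(values = v, valid = !is.na(v)),
                 class = "pa_o2sat_map")
  # centre (5, 5) 0-based with even edges biases to the lower index:
  # rows 5:6, cols 5:6 in 1-based terms
  expect_equal(extract_o2satss(m, c(5, 5), roi_params(0, 0, 2, 2, 0)), 25)
  # reported optimum for the in vivo study parses into valid params
  tbl <- roi_params(a = 1, b = -4, c_edge = 4, d_edge = 11, sigma = 1)
  expect_s3_class(tbl, "pa_roi_params")
  expect_identical(unclass(roi_params())[c("a", "b", "c", "d", "sigma")],
                   list(a = 1, b = -4, c = 4, d = 11, sigma = 1))
  # ROI with no valid pixel flags a measurement failure
  expect_true(is.na(extract_o2satss(m, c(1, 1), roi_params(0, 0, 2, 2, 0))))
})

test_that("grid search recovers a planted ROI with zero error", {
  gts <- c(12, 18, 25, 41, 55, 68)  # spans both classes
  entries <- planted_entries(gts)
  space <- roi_search_space(a_range = 0:2, b_range = -3:0, c_range = 2:4,
                            d_range = 4:6, sigma_set = c(0, 1))
  res <- grid_search_roi(entries, space)
  expect_true(res$feasible)
  expect_equal(res$mse, 0)
  expect_equal(unclass(res$params)[c("a", "b", "c", "d", "sigma")],
               list(a = 1, b = -2, c = 3, d = 5, sigma = 0))
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
  # per-sigma table has one row per smoothing level, Table-2 layout
  expect_named(res$table, c("sigma", "mse", "sensitivity", "specificity",
                            "d", "c", "b", "a"))
  expect_equal(res$table$sigma, c(0, 1))
})

test_that("grid search equals full enumeration on a small space", {
  set.seed(42)
  gts <- c(15, 22, 35, 50)
  entries <- lapply(gts, function(gt) {
    v <- matrix(gt + rnorm(20 * 24, 0, 6), 20, 24)
    list(map = structure(list(values = v, valid = matrix(TRUE, 20, 24)),
                         class = "pa_o2sat_map"),
         sss_xy = c(12, 10), gt = gt)
  })
  space <- roi_search_space(a_range = -1:1, b_range = -1:1, c_range = 2:3,
                            d_range = 2:3, sigma_set = 1:2)
  res <- grid_search_roi(entries, space)
  # brute force with the public per-sample operations
  best <- Inf
  for (sg in space$sigma_set) {
    sm <- lapply(entries, function(e) smooth_o2sat_map(e$map, sg))
    for (a in space$a_range) for (b in space$b_range)
      for (cc in space$c_range) for (dd in space$d_range) {
        pred <- mapply(function(m, e)
          extract_o2satss(m, e$sss_xy, roi_params(a, b, cc, dd, sg)),
          sm, entries)
        mse <- mean((pred - gts)^2)
        sens <- mean(pred[gts < 30] < 30)
        spec <- mean(pred[gts >= 30] >= 30)
        if (sens > 0.9 && spec > 0.9) best <- min(best, mse)
      }
  }
  expect_equal(res$mse, best)
})

test_that("grid search signals infeasibility without both classes", {
  gts <- c(55, 60, 70, 80)  # all normoxic
  entries <- planted_entries(gts)
  res <- grid_search_roi(entries, roi_search_space(
    a_range = 0:1, b_range = -2:-1, c_range = 2:3, d_range = 4:5,
    sigma_set = 0))
  expect_false(res$feasible)
  expect_false(res$both_classes)
  expect_null(res$params)
  # the unconstrained optimum is still reported for diagnosis
  expect_false(is.null(res$best_unconstrained))
  expect_lte(res$best_unconstrained$mse, 1e-9)
})
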