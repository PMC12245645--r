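test_that("anatomy places the SSS at the midline dent", {
  cfg <- small_phantom_config()
  an <- with_seed(1, generate_anatomy(cfg))
  H <- cfg$image_h; W <- cfg$image_w
  # annotation inside the frame and at the curve's global minimum (dent)
  expect_true(an$sss_xy[1] >= 0 && an$sss_xy[1] <= W - 1)
  expect_true(an$sss_xy[2] >= 0 && an$sss_xy[2] <= H - 1)
  xs <- seq(0, W - 1, by = 0.25)
  dent_x <- xs[which.max(an$curve_y(xs))]  # y grows with depth
  expect_lt(abs(dent_x - an$sss_center[1]), 1)
  # SSS near the configured depth (within jitter + rounding)
  expect_lt(abs(an$sss_xy[2] * cfg$pixel_spacing_mm - cfg$sss_depth_mm),
            cfg$sss_depth_jitter_mm + cfg$pixel_spacing_mm)
  # SSS pixels labelled and fully perfused
  expect_true(any(an$labels == 3L))
  expect_true(all(an$blood_frac[an$sss_mask] == 1))
})

test_that("anatomy degenerates gracefully and varies across seeds", {
  bare <- small_phantom_config()
  bare$n_cortical_vessels <- 0
  bare$skin_band_thickness_mm <- 0
  an <- with_seed(2, generate_anatomy(bare))
  expect_setequal(unique(as.vector(an$labels)), c(0L, 3L))

  a1 <- with_seed(10, generate_anatomy(small_phantom_config()))
  a2 <- with_seed(11, generate_anatomy(small_phantom_config()))
  expect_false(identical(a1$labels, a2$labels))
  expect_true(any(a1$labels == 3L) && any(a2$labels == 3L))

  deep <- small_phantom_config()
  deep$sss_depth_mm <- 20  # 67 px in a 48-px-tall frame
  expect_error(with_seed(1, generate_anatomy(deep)), "config error")
})

test_that("the forward model renders the documented physics", {
  cfg <- small_phantom_config(noise_sd = 0)
  ref <- fx_ref()
  an <- with_seed(3, generate_anatomy(cfg))
  an <- set_sss_o2sat(an, 55)
  img <- with_seed(4, render_spectral_image(an, ref, cfg,
                                            intensity_scale = 1e5))
  # background (no blood) pixels are exactly zero without noise
  bg <- which(an$blood_frac == 0)
  for (l in c(1, 11, 21))
    expect_true(all(img$pixels[, , l][bg] == 0))
  # deeper pixel of equal composition is strictly dimmer at every lambda
  sx <- an$sss_xy[1] + 1
  ys <- which(an$sss_mask[, sx])
  expect_true(all(img$pixels[max(ys), sx, ] < img$pixels[min(ys), sx, ]))
  # noise clamping keeps intensities non-negative
  noisy_cfg <- small_phantom_config(noise_sd = 0.3)
  img2 <- with_seed(5, render_spectral_image(an, ref, noisy_cfg,
                                             intensity_scale = 1e5))
  expect_true(all(img2$pixels >= 0))
})

test_that("noiseless forward model inverts exactly through the unmixer", {
  ds <- fx_small_noiseless()
  cfg0 <- small_phantom_config(noise_sd = 0)
  ucfg <- unmix_config(fx_ref(), matched_compensation(cfg0))
  for (s in ds$samples) {
    px <- s$image$pixels[s$sss_xy[2] + 1, s$sss_xy[1] + 1, ]
    depth_mm <- s$sss_xy[2] * s$image$pixel_spacing_mm
    gains <- ucfg$compensation$gains ^
      (depth_mm / ucfg$compensation$reference_depth_mm)
    est <- unmix_pixel(px * gains, ucfg)
    expect_lt(abs(est - s$o2satss_gt), 1 + 1e-9)
  }
})

test_that("study generation matches the protocol structure", {
  ds <- fx_small_study()
  expect_equal(as.vector(table(factor(subject_of(ds),
                                      levels = ds$subjects))),
               c(4, 3, 5))
  # every subject's first sample is healthy, FiO2 monotone declining
  for (s in ds$subjects) {
    idx <- which(subject_of(ds) == s)
    expect_gte(ds$samples[[idx[1]]]$o2satss_gt, 30)
    fio2 <- vapply(ds$samples[idx], `[[`, numeric(1), "fio2")
    expect_true(all(diff(fio2) <= 1e-9))
  }
  # seed determinism is bit-exact
  ds2 <- generate_study(n_subjects = 3, per_subject_counts = c(4, 3, 5),
                        cfg = small_phantom_config(), seed = 7)
  for (i in seq_along(ds$samples))
    expect_identical(ds$samples[[i]]$image$pixels,
                     ds2$samples[[i]]$image$pixels)
  expect_error(generate_study(n_subjects = 2, per_subject_counts = c(3, 4),
                              fio2_schedule = function(n) seq(0.5, 1, length.out = n),
                              cfg = small_phantom_config(), seed = 1),
               "monotone")
})

test_that("default schedule produces a predominantly hypoxic dataset", {
  gts <- with_seed(99, o2sat_trajectory(seq(1, 0.08, length.out = 9),
                                        phantom_config()))
  expect_gte(gts[1], 30)
  # over many subjects the hypoxic fraction settles near 70%
  fracs <- with_seed(123, {
    replicate(40, mean(o2sat_trajectory(seq(1, 0.08, length.out = 9),
                                        phantom_config()) < 30))
  })
  expect_lt(abs(mean(fracs) - 0.7), 0.12)
})
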