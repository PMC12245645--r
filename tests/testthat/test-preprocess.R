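mini_image <- function(values, h = 2, w = 2, grid = wavelength_grid(700, 700, 10)) {
  spectral_image(array(values, dim = c(h, w, length(grid$values))), grid)
}

test_that("dynamic-range rectification clips at mean + k * population sd", {
  # hand-computed: {0, 0, 0, 100}, k = 0.5 -> T = 25 + 0.5 * 43.3013
  img <- mini_image(c(0, 0, 0, 100))
  out <- rectify_dynamic_range(img, k = 0.5)
  expect_equal(sort(unique(as.vector(out$pixels))), c(0, 46.65063509),
               tolerance = 1e-8)
  # constant image unchanged (sd = 0)
  const <- mini_image(rep(7, 4))
  expect_equal(rectify_dynamic_range(const, 0.5)$pixels, const$pixels)
  # large k is the identity; output never exceeds input
  expect_equal(rectify_dynamic_range(img, 10)$pixels, img$pixels)
  noisy <- fx_small_study()$samples[[1]]$image
  for (k in c(0, 0.5, 1))
    expect_true(all(rectify_dynamic_range(noisy, k)$pixels <= noisy$pixels))
})

test_that("min-max normalization maps to [0, 1] and keeps spectral shape", {
  img <- mini_image(c(2, 4, 6, 4))
  out <- minmax_normalize(img)
  expect_equal(sort(unique(as.vector(out$pixels))), c(0, 0.5, 1))
  # joint mode preserves inter-channel ratios when the minimum is 0
  g2 <- wavelength_grid(700, 710, 10)
  two <- spectral_image(array(c(0, 2, 4, 8, 0, 1, 2, 4), c(2, 2, 2)), g2)
  n2 <- minmax_normalize(two, "joint")
  expect_equal(n2$pixels[2, 1, 1] / n2$pixels[2, 1, 2],
               two$pixels[2, 1, 1] / two$pixels[2, 1, 2])
  # degenerate range convention
  expect_true(all(minmax_normalize(mini_image(rep(3, 4)))$pixels == 0))
  # per-channel mode normalizes each wavelength separately
  pc <- minmax_normalize(two, "per_channel")
  expect_equal(max(pc$pixels[, , 1]), 1)
  expect_equal(max(pc$pixels[, , 2]), 1)
})

test_that("heatmap targets peak exactly at the annotation and are isotropic", {
  hm <- make_heatmap_target(c(10, 7), c(24, 32))
  expect_equal(dim(hm), c(24, 32))
  expect_equal(max(hm), 1)
  expect_equal(unname(heatmap_to_point(hm)), c(10, 7))
  expect_equal(hm[8, 11], 1)
  # symmetric off-peak pixels are equal
  expect_equal(hm[8, 11 + 3], hm[8, 11 - 3])
  expect_equal(hm[8 + 2, 11], hm[8 - 2, 11])
  expect_true(all(hm >= 0 & hm <= 1))
  # composition identity over interior points
  for (p in list(c(3, 3), c(20, 15), c(28, 5))) {
    hm <- make_heatmap_target(p, c(24, 32))
    expect_equal(unname(heatmap_to_point(hm)), p)
  }
  expect_error(make_heatmap_target(c(-1, 5), c(24, 32)), "outside")
  expect_error(make_heatmap_target(c(32, 5), c(24, 32)), "outside")
})

test_that("channel subsets draw exactly one wavelength per bin", {
  grid <- wavelength_grid()
  bins <- wavelength_bins()
  sizes <- vapply(bins, function(b)
    sum(grid$values >= b[1] & grid$values <= b[2]), numeric(1))
  expect_equal(sizes, c(4, 4, 5, 4, 4))
  draws <- with_seed(5, replicate(500, sample_channel_subset(grid, bins)))
  expect_equal(dim(draws), c(5, 500))
  for (i in 1:5)
    expect_true(all(draws[i, ] >= bins[[i]][1] & draws[i, ] <= bins[[i]][2]))
  expect_equal(length(unique(apply(draws, 2, paste, collapse = ","))) > 100,
               TRUE)  # many of the 1280 combinations realized
  expect_identical(with_seed(9, sample_channel_subset(grid)),
                   with_seed(9, sample_channel_subset(grid)))
})

test_that("channel masking zeroes exactly the non-kept wavelengths", {
  img <- fx_small_study()$samples[[1]]$image
  keep <- c(700, 750, 800, 840, 900)
  out <- mask_channels(img, keep)
  kept_idx <- match(keep, img$grid$values)
  nonzero <- vapply(seq_len(21), function(c) any(out$pixels[, , c] != 0),
                    logical(1))
  expect_equal(which(nonzero), kept_idx)
  expect_equal(out$pixels[, , kept_idx], img$pixels[, , kept_idx])
  # full grid is the identity; empty set zeroes everything
  expect_equal(mask_channels(img, img$grid$values)$pixels, img$pixels)
  expect_true(all(mask_channels(img, numeric(0))$pixels == 0))
  expect_error(mask_channels(img, 715), "unknown wavelength")
})

test_that("geometric augmentation moves image and target together", {
  H <- 24; W <- 32
  hm <- make_heatmap_target(c(20, 9), c(H, W))
  px <- array(runif(H * W * 3), c(H, W, 3))
  # identity parameters leave the pair untouched
  id <- with_seed(1, geometric_augment(px, hm, identity_augment_params()))
  expect_equal(id$pixels, px)
  expect_equal(id$heatmap, hm)
  # pure horizontal flip reflects the peak: x' = W - 1 - x
  flip_only <- augment_params(p_flip = 1, max_shift_frac = 0,
                              max_rot_deg = 0, scale_range = c(1, 1),
                              distort_amp_px = 0)
  fl <- with_seed(2, geometric_augment(px, hm, flip_only))
  expect_equal(unname(heatmap_to_point(fl$heatmap)), c(W - 1 - 20, 9))
  expect_equal(fl$pixels[, W:1, ], px)
  # under random transforms, a channel carrying a copy of the target
  # stays aligned with the warped target (within interpolation tolerance)
  px2 <- px; px2[, , 2] <- hm
  for (seed in 1:15) {
    aug <- with_seed(seed, geometric_augment(px2, hm, augment_params()))
    p_target <- heatmap_to_point(aug$heatmap)
    p_channel <- heatmap_to_point(aug$pixels[, , 2])
    expect_lte(sqrt(sum((p_target - p_channel)^2)), 1.5)
    expect_equal(max(aug$heatmap), 1)  # renormalized peak, in frame
  }
})
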