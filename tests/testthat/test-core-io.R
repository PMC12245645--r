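test_that("wavelength grid enumerates the acquisition band", {
  g <- wavelength_grid(700, 900, 10)
  expect_length(g$values, 21)
  expect_equal(g$values[1], 700)
  expect_equal(tail(g$values, 1), 900)

  expect_equal(wavelength_grid(700, 700, 10)$values, 700)
  expect_equal(wavelength_grid(700, 900, 50)$values,
               c(700, 750, 800, 850, 900))
  # count formula matches explicit enumeration
  for (step in c(5, 10, 20, 25, 50)) {
    g <- wavelength_grid(700, 900, step)
    expect_equal(length(g$values), (900 - 700) / step + 1)
    expect_true(all(diff(g$values) == step))
  }
  expect_error(wavelength_grid(700, 900, 15), "invalid wavelength grid")
})

test_that("reference spectra are convex blends of the extinction endpoints", {
  ref <- fx_ref()
  expect_equal(ref$o2sat_grid, 0:100)
  ext <- hb_extinction(wavelength_grid())
  # s = 100 row is pure HbO2, s = 0 pure Hb
  expect_equal(unname(ref$table[, "100"]), unname(ext[, "HbO2"]))
  expect_equal(unname(ref$table[, "0"]), unname(ext[, "Hb"]))
  # s = 50 is the arithmetic mean of the endpoints
  expect_equal(ref$table[, "50"], (ref$table[, "0"] + ref$table[, "100"]) / 2)
  # blend linearity at arbitrary s, to machine precision
  for (s in c(13, 37.5, 81)) {
    direct <- reference_spectrum(ref, s)
    expect_equal(direct,
                 (s / 100) * ref$table[, "100"] +
                   (1 - s / 100) * ref$table[, "0"],
                 tolerance = 1e-12)
  }
  # near the isosbestic point the rows barely depend on s
  i800 <- which(wavelength_grid()$values == 800)
  spread <- diff(range(ref$table[i800, ])) / mean(ref$table[i800, ])
  expect_lt(spread, 0.1)
  expect_gt(min(ref$table), 0)
  expect_error(build_reference_spectra(wavelength_grid(600, 900, 10)),
               "extinction table range")
  expect_error(build_reference_spectra(wavelength_grid(), o2sat_step = 3),
               "divide")
})

test_that("dataset container round-trips losslessly and is versioned", {
  ds <- fx_small_study()
  path <- withr::local_tempfile(fileext = ".rds")
  save_dataset(ds, path)
  back <- load_dataset(path)
  expect_identical(back$subjects, ds$subjects)
  expect_length(back$samples, length(ds$samples))
  # per-subject counts preserved
  expect_identical(table(subject_of(back)), table(subject_of(ds)))
  # arrays and metadata numerically exact
  i <- length(ds$samples)
  expect_identical(back$samples[[i]]$image$pixels, ds$samples[[i]]$image$pixels)
  expect_identical(back$samples[[i]]$sss_xy, ds$samples[[i]]$sss_xy)
  expect_identical(back$samples[[i]]$o2satss_gt, ds$samples[[i]]$o2satss_gt)

  # empty dataset round-trips
  empty <- study_dataset(list())
  save_dataset(empty, path)
  expect_length(load_dataset(path)$samples, 0)

  # schema-version guard
  payload <- readRDS(path)
  payload$version <- 99L
  saveRDS(payload, path)
  expect_error(load_dataset(path), "schema version")
  saveRDS(list(foo = 1), path)
  expect_error(load_dataset(path), "not a paoxi dataset")
})

test_that("validate_dataset reports violations and passes clean data", {
  ds <- fx_small_study()
  expect_equal(nrow(validate_dataset(ds)), 0)

  bad <- ds
  bad$samples[[1]]$sss_xy <- c(-1, 5)
  rep <- validate_dataset(bad)
  expect_true(any(rep$field == "sss_xy"))

  bad2 <- ds
  bad2$samples[[2]]$image$pixels <- bad2$samples[[2]]$image$pixels[, , 1:20]
  rep2 <- validate_dataset(bad2)
  expect_true(any(grepl("channel count", rep2$problem)))

  bad3 <- ds
  bad3$samples[[1]]$image$pixels[1] <- NaN
  expect_true(any(grepl("non-finite", validate_dataset(bad3)$problem)))
})

test_that("annotation sidecar and reference spectra export as CSV", {
  ds <- fx_small_study()
  path <- withr::local_tempfile(fileext = ".csv")
  export_annotations(ds, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), length(ds$samples))
  expect_named(tab, c("subject_id", "sample_idx", "sss_x", "sss_y",
                      "o2satss_gt", "fio2"))
  export_reference_spectra(fx_ref(), path)
  tab2 <- read.csv(path, check.names = FALSE)
  expect_equal(nrow(tab2), 21)
  expect_equal(ncol(tab2), 102)  # wavelength + 101 saturation levels
})
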