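#' Acquisition wavelength grid
#'
#' The multiwavelength protocol images the near-infrared band from
#' `start_nm` to `stop_nm` in `step_nm` increments; the default
#' 700-900 nm / 10 nm protocol yields 21 channels.
#'
#' @param start_nm,stop_nm,step_nm grid endpoints and increment in nm;
#'   `step_nm` must divide `stop_nm - start_nm` exactly.
#' @return an object of class `pa_wavelength_grid` with fields `start_nm`,
#'   `stop_nm`, `step_nm` and the ordered `values`.
#' @examples
#' length(wavelength_grid(700, 900, 10)$values)  # 21
#' @export
wavelength_grid <- function(start_nm = 700, stop_nm = 900, step_nm = 10) {
  stopifnot(is.numeric(start_nm), is.numeric(stop_nm), is.numeric(step_nm),
            step_nm > 0, stop_nm >= start_nm)
  n_steps <- (stop_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("invalid wavelength grid: step ", step_nm,
         " nm does not divide the span ", stop_nm - start_nm, " nm")
  values <- start_nm + step_nm * seq.int(0L, round(n_steps))
  structure(list(start_nm = start_nm, stop_nm = stop_nm, step_nm = step_nm,
                 values = values),
            class = "pa_wavelength_grid")
}

#' @export
print.pa_wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength grid: %g-%g nm, step %g nm, %d channels>\n",
              x$start_nm, x$stop_nm, x$step_nm, length(x$values)))
  invisible(x)
}

#' Multiwavelength photoacoustic image
#'
#' A coronal PA image stack. Pixels are stored as an array with
#' `dim = c(H, W, n_channels)` indexed `[y, x, channel]`; y increases with
#' imaging depth. Intensities are in arbitrary units (AU) and must be
#' finite and non-negative.
#'
#' @param pixels numeric array `H x W x C`.
#' @param grid the [wavelength_grid()]; `C` must equal its channel count.
#' @param pixel_spacing_mm isotropic pixel spacing (default 0.3 mm).
#' @return object of class `pa_spectral_image`.
#' @export
spectral_image <- function(pixels, grid = wavelength_grid(),
                           pixel_spacing_mm = 0.3) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3)
  if (dim(pixels)[3] != length(grid$values))
    stop("channel count ", dim(pixels)[3], " does not match the ",
         length(grid$values), "-wavelength grid")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and >= 0")
  structure(list(pixels = pixels, grid = grid,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "pa_spectral_image")
}

image_dims <- function(img) dim(img$pixels)[1:2]

#' One experimental data point
#'
#' Couples a [spectral_image()] with its acquisition metadata: subject id,
#' inspired-oxygen fraction (FiO2), the ground-truth venous oxygen
#' saturation at the superior sagittal sinus (O2Satss, percent) and the
#' expert point annotation of the SSS centre.
#'
#' @param image a `pa_spectral_image`.
#' @param subject_id scalar identifier.
#' @param fio2 fraction of inspired oxygen in `[0.08, 1]`.
#' @param o2satss_gt ground-truth O2Satss in percent, `[0, 100]`.
#' @param sss_xy 0-based pixel coordinate `c(x, y)` of the SSS centre.
#' @return object of class `pa_sample_record`.
#' @export
sample_record <- function(image, subject_id, fio2, o2satss_gt, sss_xy) {
  stopifnot(inherits(image, "pa_spectral_image"),
            length(sss_xy) == 2, is.numeric(sss_xy))
  if (fio2 < 0.08 - 1e-9 || fio2 > 1 + 1e-9)
    stop("fio2 must lie in [0.08, 1]")
  if (o2satss_gt < 0 || o2satss_gt > 100)
    stop("o2satss_gt must lie in [0, 100] percent")
  hw <- image_dims(image)
  if (sss_xy[1] < 0 || sss_xy[1] > hw[2] - 1 ||
      sss_xy[2] < 0 || sss_xy[2] > hw[1] - 1)
    stop("sss_xy outside image bounds")
  structure(list(image = image, subject_id = as.character(subject_id),
                 fio2 = fio2, o2satss_gt = o2satss_gt,
                 sss_xy = as.numeric(sss_xy)),
            class = "pa_sample_record")
}

#' Study dataset
#'
#' Ordered collection of [sample_record()]s across subjects; per-subject
#' sample counts may differ (subjects reach terminal hypoxia at different
#' rates).
#'
#' @param samples list of `pa_sample_record`.
#' @return object of class `pa_study_dataset` with fields `samples` and
#'   `subjects`.
#' @export
study_dataset <- function(samples) {
  stopifnot(is.list(samples),
            all(vapply(samples, inherits, TRUE, "pa_sample_record")))
  subjects <- unique(vapply(samples, function(s) s$subject_id, ""))
  structure(list(samples = samples, subjects = subjects),
            class = "pa_study_dataset")
}

#' @export
print.pa_study_dataset <- function(x, ...) {
  cat(sprintf("<study dataset: %d samples, %d subjects>\n",
              length(x$samples), length(x$subjects)))
  invisible(x)
}

subject_of <- function(ds) vapply(ds$samples, function(s) s$subject_id, "")

#' Reference response table for spectral unmixing
#'
#' Builds the table `S(lambda, s)` of expected photoacoustic response at
#' each wavelength for each candidate oxygen saturation level `s`, as the
#' convex blend `s/100 * HbO2 + (1 - s/100) * Hb` of the embedded
#' extinction endpoints.
#'
#' @param grid a [wavelength_grid()] within 700-900 nm.
#' @param o2sat_step grid resolution in percent; must divide 100.
#' @return object of class `pa_reference_spectra`: `o2sat_grid` (percent
#'   levels) and `table` (`n_wavelengths x n_levels` matrix, AU).
#' @export
build_reference_spectra <- function(grid = wavelength_grid(), o2sat_step = 1) {
  stopifnot(o2sat_step > 0)
  if (abs(100 / o2sat_step - round(100 / o2sat_step)) > 1e-9)
    stop("o2sat_step must divide 100")
  ext <- hb_extinction(grid)
  s_grid <- seq(0, 100, by = o2sat_step)
  tab <- vapply(s_grid, function(s)
    (s / 100) * ext[, "HbO2"] + (1 - s / 100) * ext[, "Hb"],
    numeric(nrow(ext)))
  dimnames(tab) <- list(grid$values, s_grid)
  structure(list(o2sat_grid = s_grid, table = tab, grid = grid),
            class = "pa_reference_spectra")
}

#' Look up (or blend) the reference spectrum at a saturation level
#'
#' @param ref a [build_reference_spectra()] object.
#' @param s oxygen saturation in percent (need not be on the grid).
#' @return numeric vector of length `n_wavelengths`.
#' @export
reference_spectrum <- function(ref, s) {
  stopifnot(inherits(ref, "pa_reference_spectra"), s >= 0, s <= 100)
  n <- ncol(ref$table)
  (s / 100) * ref$table[, n] + (1 - s / 100) * ref$table[, 1]
}

#' Per-wavelength attenuation compensation profile
#'
#' Multiplicative gains that undo the depth-dependent optical attenuation
#' of the excitation light, calibrated at a reference depth (the typical
#' skin-to-SSS distance).
#'
#' @param gains positive numeric vector, one gain per wavelength.
#' @param reference_depth_mm depth at which the calibration holds.
#' @return object of class `pa_compensation_profile`.
#' @export
compensation_profile <- function(gains, reference_depth_mm) {
  stopifnot(is.numeric(gains), all(gains > 0), reference_depth_mm > 0)
  structure(list(gains = as.numeric(gains),
                 reference_depth_mm = reference_depth_mm),
            class = "pa_compensation_profile")
}

.dataset_schema_version <- 1L

#' Save / load a study dataset container
#'
#' The container is a single versioned serialized file holding the image
#' arrays and all per-sample metadata; `load_dataset(save_dataset(ds))` is
#' an identity on every field. A schema-version field guards against
#' reading containers written by an incompatible package revision.
#'
#' @param ds a [study_dataset()].
#' @param path file path.
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the
#'   reconstructed `pa_study_dataset`.
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "pa_study_dataset"))
  payload <- list(schema = "paoxi-dataset",
                  version = .dataset_schema_version, dataset = ds)
  saveRDS(payload, path, version = 3, compress = "gzip")
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || !identical(payload$schema, "paoxi-dataset"))
    stop("not a paoxi dataset container: ", path)
  if (!identical(payload$version, .dataset_schema_version))
    stop("incompatible dataset schema version ", payload$version,
         " (this package reads version ", .dataset_schema_version, ")")
  payload$dataset
}

#' Export the annotation sidecar
#'
#' Writes the per-sample metadata (subject, index, SSS annotation, FiO2,
#' ground truth O2Satss) as a CSV for inspection outside R.
#'
#' @param ds a [study_dataset()].
#' @param path CSV path.
#' @export
export_annotations <- function(ds, path) {
  rows <- lapply(seq_along(ds$samples), function(i) {
    s <- ds$samples[[i]]
    data.frame(subject_id = s$subject_id, sample_idx = i,
               sss_x = s$sss_xy[1], sss_y = s$sss_xy[2],
               o2satss_gt = s$o2satss_gt, fio2 = s$fio2)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Export the reference spectra as CSV
#'
#' @param ref a [build_reference_spectra()] object.
#' @param path CSV path.
#' @export
export_reference_spectra <- function(ref, path) {
  df <- data.frame(wavelength_nm = ref$grid$values, ref$table,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Validate a study dataset
#'
#' Report-only integrity check: annotation bounds, non-finite or negative
#' intensities, channel-count mismatches, metadata ranges. An empty report
#' means all invariants hold.
#'
#' @param ds a `pa_study_dataset` (fields may have been altered externally).
#' @return data.frame with columns `sample_idx`, `field`, `problem`;
#'   zero rows when the dataset is valid.
#' @export
validate_dataset <- function(ds) {
  bad <- list()
  note <- function(i, field, problem)
    bad[[length(bad) + 1]] <<- data.frame(sample_idx = i, field = field,
                                          problem = problem)
  for (i in seq_along(ds$samples)) {
    s <- ds$samples[[i]]
    px <- s$image$pixels
    hw <- dim(px)[1:2]
    if (dim(px)[3] != length(s$image$grid$values))
      note(i, "image", "channel count does not match wavelength grid")
    if (!all(is.finite(px)))
      note(i, "image", "non-finite intensities")
    else if (any(px < 0))
      note(i, "image", "negative intensities")
    if (s$sss_xy[1] < 0 || s$sss_xy[1] > hw[2] - 1 ||
        s$sss_xy[2] < 0 || s$sss_xy[2] > hw[1] - 1)
      note(i, "sss_xy", "annotation outside image bounds")
    if (s$o2satss_gt < 0 || s$o2satss_gt > 100)
      note(i, "o2satss_gt", "outside [0, 100] percent")
    if (s$fio2 < 0.08 - 1e-9 || s$fio2 > 1 + 1e-9)
      note(i, "fio2", "outside [0.08, 1]")
    if (!s$subject_id %in% ds$subjects)
      note(i, "subject_id", "subject missing from dataset subject list")
  }
  if (length(bad) == 0)
    data.frame(sample_idx = integer(), field = character(),
               problem = character())
  else do.call(rbind, bad)
}
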