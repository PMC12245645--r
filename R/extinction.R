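#' Hemoglobin molar extinction endpoints in the NIR window
#'
#' Molar extinction coefficients (cm^-1 / (mol/L)) of oxyhemoglobin (HbO2)
#' and deoxyhemoglobin (Hb) from 700 to 900 nm at 10 nm steps, rounded from
#' published spectrophotometric compilations. These two endpoint spectra
#' define the reference response table used by the spectral unmixer: the
#' response at a fractional saturation s is the convex blend
#' `s * HbO2 + (1 - s) * Hb`. The curves cross near 800 nm (isosbestic
#' point), which is why single-wavelength imaging cannot resolve oxygen
#' saturation in this band.
#'
#' @param grid a [wavelength_grid()]; must lie within 700-900 nm.
#' @return numeric matrix with one row per grid wavelength and columns
#'   `HbO2` and `Hb`; values interpolated linearly where the grid falls
#'   between the tabulated 10 nm samples.
#' @export
hb_extinction <- function(grid = wavelength_grid(700, 900, 10)) {
  stopifnot(inherits(grid, "pa_wavelength_grid"))
  tab <- .hb_extinction_table
  if (min(grid$values) < min(tab$nm) || max(grid$values) > max(tab$nm)) {
    stop("wavelength grid outside the embedded extinction table range (",
         min(tab$nm), "-", max(tab$nm), " nm)")
  }
  out <- cbind(
    HbO2 = approx(tab$nm, tab$HbO2, xout = grid$values)$y,
    Hb   = approx(tab$nm, tab$Hb,   xout = grid$values)$y
  )
  rownames(out) <- grid$values
  out
}

# Static compilation sampled at the 21 acquisition wavelengths.
.hb_extinction_table <- data.frame(
  nm   = seq(700, 900, 10),
  HbO2 = c(290, 334, 370, 390, 446, 518, 586, 650, 710, 766, 816,
           864, 910, 952, 1014, 1058, 1087, 1110, 1130, 1178, 1198),
  Hb   = c(1794, 1640, 1325, 1102, 1116, 1405, 1549, 1312, 1075, 904, 762,
           717, 693, 691, 694, 691, 702, 714, 726, 739, 752)
)
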