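#' Resample spectra onto a target wavelength grid
#'
#' Linear interpolation of one or more spectra onto a target grid, the
#' standard preprocessing step that brings field-spectrometer output to the
#' 1 nm working resolution.  Values at wavelengths coinciding with input
#' nodes are preserved exactly.
#'
#' @param spectra Tibble with a `wavelength` column plus one numeric column
#'   per spectrum.
#' @param grid Target wavelengths (nm), default [spectral_grid()].  Must lie
#'   within the input wavelength range (no extrapolation).
#' @return Tibble on the target grid with the same value columns.
#' @export
resample_spectra <- function(spectra, grid = spectral_grid()) {
  spectra <- as_tibble(spectra)
  stopifnot("wavelength" %in% names(spectra))
  wl <- spectra$wavelength
  validate_grid(wl)
  if (min(grid) < min(wl) - 1e-9 || max(grid) > max(wl) + 1e-9) {
    abort("target grid extends beyond the input wavelength range",
          class = "leafplates_extrapolation_error")
  }
  cols <- setdiff(names(spectra), "wavelength")
  out <- tibble(wavelength = as.numeric(grid))
  for (cl in cols) {
    out[[cl]] <- approx(wl, spectra[[cl]], xout = grid, ties = "ordered")$y
  }
  out
}

#' Savitzky-Golay smoothing of spectra
#'
#' Applies a Savitzky-Golay filter to every value column of a spectra table
#' on a uniform grid.  Defaults (window 11, order 3) give mild smoothing at
#' 1 nm resolution.  Low-degree polynomials (degree <= `order`) pass through
#' unchanged, which is the defining property of the filter.
#'
#' @param spectra Tibble with `wavelength` plus value columns, uniform grid.
#' @param window Odd window length (bands).
#' @param order Polynomial order, `< window`.
#' @param clip If `TRUE` (default), clip smoothed reflectance to `[0, 1]`
#'   (physical bound).
#' @return Smoothed tibble on the same grid.
#' @export
sg_smooth <- function(spectra, window = 11, order = 3, clip = TRUE) {
  spectra <- as_tibble(spectra)
  stopifnot("wavelength" %in% names(spectra))
  if (window %% 2 != 1 || window < 3) {
    abort("window must be an odd integer >= 3", class = "leafplates_parameter_error")
  }
  if (order >= window) {
    abort("order must be smaller than window", class = "leafplates_parameter_error")
  }
  steps <- diff(spectra$wavelength)
  if (max(steps) - min(steps) > 1e-8) {
    abort("Savitzky-Golay smoothing requires a uniform grid",
          class = "leafplates_parameter_error")
  }
  out <- spectra
  for (cl in setdiff(names(spectra), "wavelength")) {
    y <- signal::sgolayfilt(spectra[[cl]], p = order, n = window)
    if (clip) y <- pmin(pmax(y, 0), 1)
    out[[cl]] <- y
  }
  out
}

#' Construct a leaf spectrum table
#'
#' @param wavelength Wavelengths in nm.
#' @param reflectance Reflectance fraction per band.
#' @param transmittance Optional transmittance fraction per band.
#' @return A `leaf_spectrum` tibble.
#' @export
leaf_spectrum <- function(wavelength, reflectance, transmittance = NULL) {
  validate_grid(wavelength)
  out <- tibble(wavelength = as.numeric(wavelength), reflectance = reflectance)
  if (!is.null(transmittance)) out$transmittance <- transmittance
  class(out) <- c("leaf_spectrum", class(out))
  out
}

#' @export
autoplot.leaf_spectrum <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), -"wavelength",
                              names_to = "quantity", values_to = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$fraction,
                                     colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "fraction", colour = NULL) +
    ggplot2::theme_minimal()
}
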