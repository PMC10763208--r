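#' Spectral band definitions
#'
#' The three-band segmentation used for reporting: blue-green
#' (400-560 nm), yellow-red (560-780 nm) and near-infrared (780-1000 nm).
#' Interior edges belong to the band on their left (560 nm to blue-green,
#' 780 nm to yellow-red), giving a deterministic partition of the 601
#' bands; `full` covers the whole grid.
#'
#' @return Tibble with columns `band`, `lo`, `hi`.
#' @export
band_definitions <- function() {
  tibble(band = c("full", "blue_green", "yellow_red", "near_infrared"),
         lo = c(400, 400, 560, 780),
         hi = c(1000, 560, 780, 1000))
}

band_mask <- function(wavelength, lo, hi) {
  if (lo <= 400) wavelength >= lo & wavelength <= hi else wavelength > lo & wavelength <= hi
}

#' Band-wise RMSE between measured and modelled spectra
#'
#' Root-mean-square difference over the wavelengths of a band, by default
#' normalized by the band-mean measured reflectance (relative RMSE), which
#' is the per-sample accuracy statistic reported by the package.  Set
#' `relative = FALSE` for the plain unnormalized RMSE.
#'
#' @param measured,modelled Reflectance vectors, or [leaf_spectrum()]
#'   tibbles, on a common grid.
#' @param wavelength Wavelength vector (taken from `measured` when it is a
#'   spectrum tibble).
#' @param lo,hi Band limits in nm (default: full grid).
#' @param relative Normalize by the band-mean measured reflectance.
#' @return Nonnegative scalar; `0` iff identical over the band.
#' @export
rmse_spectral <- function(measured, modelled, wavelength = NULL,
                          lo = 400, hi = 1000, relative = TRUE) {
  if (is.data.frame(measured)) {
    wavelength <- measured$wavelength
    measured <- measured$reflectance
  }
  if (is.data.frame(modelled)) modelled <- modelled$reflectance
  if (is.null(wavelength)) wavelength <- seq(400, length.out = length(measured))
  keep <- band_mask(wavelength, lo, hi)
  if (!any(keep)) abort("band contains no wavelengths", class = "leafplates_value_error")
  m <- measured[keep]
  s <- modelled[keep]
  rms <- sqrt(mean((m - s)^2))
  if (!relative) return(rms)
  mbar <- mean(m)
  if (mbar == 0) abort("band-mean measured reflectance is zero", class = "leafplates_value_error")
  rms / mbar
}

#' Min/max/mean/variance summary of inverted parameters
#'
#' Summarizes the retrieved layer parameters of a cohort inversion, one row
#' per parameter, with the population variance (denominator n).
#'
#' @param results Tibble with columns `N1`, `N2`, `Cab12`, `Cm12` (e.g. the
#'   `$results` of [invert_cohort()]), or a list of single-sample inversion
#'   results.
#' @return Tibble with `parameter`, `min`, `max`, `mean`, `variance`.
#' @export
summarize_parameters <- function(results) {
  if (!is.data.frame(results)) {
    if (length(results) == 0) abort("no results to summarize", class = "leafplates_value_error")
    results <- purrr::map_dfr(results, tidy)
  }
  if (nrow(results) == 0) abort("no results to summarize", class = "leafplates_value_error")
  pars <- c("N1", "N2", "Cab12", "Cm12")
  purrr::map_dfr(pars, function(p) {
    x <- results[[p]]
    tibble(parameter = p, min = min(x), max = max(x), mean = mean(x),
           variance = mean((x - mean(x))^2))
  })
}

#' Pearson correlations between retrieved and measured leaf parameters
#'
#' Correlates the retrieved layer parameters {N1, N2, Cab12, Cm12} with the
#' measured biochemistry {Cab, Cw, Cm, N} across samples.  Zero-variance
#' columns yield `NA` with a warning.
#'
#' @param results Cohort results tibble (with `sample_id`, `N1`, `N2`,
#'   `Cab12`, `Cm12`).
#' @param biochem Biochemistry tibble (with `sample_id`, `Cab`, `Cw`, `Cm`,
#'   `N`).
#' @return 4 x 4 correlation matrix (rows: retrieved, cols: measured).
#' @export
parameter_correlations <- function(results, biochem) {
  stopifnot(nrow(results) >= 3)
  joined <- left_join(results, biochem, by = "sample_id")
  ret <- as.matrix(joined[c("N1", "N2", "Cab12", "Cm12")])
  meas <- as.matrix(joined[c("Cab", "Cw", "Cm", "N")])
  degenerate <- c(apply(ret, 2, var), apply(meas, 2, var)) < 1e-30
  if (any(degenerate)) warn("zero-variance parameter: correlations reported as NA")
  suppressWarnings(cor(ret, meas))
}
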