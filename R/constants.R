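#' Default 1 nm spectral grid
#'
#' The working grid of the package: wavelengths from 400 to 1000 nm in 1 nm
#' steps, 601 bands.  All forward models and fitness evaluations operate on
#' this grid (or a user-supplied strictly increasing subset of it).
#'
#' @param from,to Grid limits in nm.
#' @param by Step in nm.
#' @return Integer vector of wavelengths (nm), strictly increasing.
#' @export
#' @examples
#' length(spectral_grid())  # 601
spectral_grid <- function(from = 400, to = 1000, by = 1) {
  if (from < 400 - 1e-9 || to > 1000 + 1e-9) {
    abort("spectral grid must lie within 400-1000 nm", class = "leafplates_grid_error")
  }
  wl <- seq(from, to, by = by)
  validate_grid(wl)
  wl
}

validate_grid <- function(wavelengths) {
  if (length(wavelengths) < 2 || any(diff(wavelengths) <= 0)) {
    abort("wavelengths must be strictly increasing", class = "leafplates_grid_error")
  }
  invisible(wavelengths)
}

constants_cols <- c("wavelength", "n", "Kcab", "Kcw", "Kcm")

validate_constants <- function(constants) {
  missing <- setdiff(constants_cols, names(constants))
  if (length(missing) > 0) {
    abort(paste0("constants table is missing column(s): ", paste(missing, collapse = ", ")),
          class = "leafplates_format_error")
  }
  constants <- arrange(as_tibble(constants), .data$wavelength)
  if (anyDuplicated(constants$wavelength) || any(diff(constants$wavelength) <= 0)) {
    abort("constants wavelengths must be unique and monotone", class = "leafplates_grid_error")
  }
  for (k in c("Kcab", "Kcw", "Kcm")) {
    if (any(constants[[k]] < 0)) {
      abort(paste0("negative specific absorption coefficient in ", k),
            class = "leafplates_value_error")
    }
  }
  if (any(constants$n <= 1)) {
    abort("refractive index must exceed 1 at every wavelength", class = "leafplates_value_error")
  }
  constants
}

#' Read and write optical-constants tables
#'
#' The constants table holds, per wavelength, the leaf refractive index `n`
#' and the specific absorption coefficients of chlorophyll (`Kcab`,
#' cm^2 ug^-1), water (`Kcw`, cm^2 g^-1) and dry matter (`Kcm`, cm^2 g^-1).
#' The file dialect is plain CSV with header
#' `wavelength,n,Kcab,Kcw,Kcm`, one row per nm.
#'
#' @param path CSV file path.
#' @param constants A constants tibble as returned by [load_optical_constants()]
#'   or [synthetic_optical_constants()].
#' @return `load_optical_constants()` returns a tibble with columns
#'   `wavelength`, `n`, `Kcab`, `Kcw`, `Kcm`, sorted by wavelength.
#' @export
load_optical_constants <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_constants(df)
}

#' @rdname load_optical_constants
#' @export
write_optical_constants <- function(constants, path) {
  constants <- validate_constants(constants)
  readr::write_csv(constants[constants_cols], path)
  invisible(path)
}

#' Synthetic optical constants for testing
#'
#' Builds smooth, physically plausible constants curves: a chlorophyll
#' coefficient with absorption bands centred at 450 nm (blue) and 650 nm
#' (red), a water coefficient rising toward the near infrared with a band
#' near 970 nm, a small flat dry-matter coefficient, and a slowly varying
#' refractive index around 1.35-1.45.  The seed perturbs band amplitudes
#' and widths by a few percent so that distinct seeds give distinct (but
#' equally plausible) curves; a given seed is fully deterministic.
#'
#' These curves are synthetic stand-ins used by the test-suite and the
#' cohort simulator; real applications should supply a measured constants
#' table via [load_optical_constants()].
#'
#' @param seed Integer seed.
#' @param grid Wavelength grid (nm), default [spectral_grid()].
#' @return A constants tibble (see [load_optical_constants()]).
#' @export
synthetic_optical_constants <- function(seed = 0, grid = spectral_grid()) {
  validate_grid(grid)
  wl <- as.numeric(grid)
  set.seed(as.integer(seed))
  jit <- function(x, frac = 0.05) x * (1 + frac * (runif(1) - 0.5))
  gauss <- function(mu, sd) exp(-0.5 * ((wl - mu) / sd)^2)
  # chlorophyll: blue and red bands; amplitudes sized so Cab ~ 30 ug cm^-2
  # yields optical depths of order 1 in the absorption bands
  Kcab <- jit(0.085) * gauss(450, jit(32)) + jit(0.050) * gauss(650, jit(22)) +
    0.002 * gauss(550, 120)
  # water: monotone NIR rise plus the 970 nm band (per-g coefficients)
  Kcw <- jit(24) * gauss(970, jit(45)) + jit(4) * ((wl - 400) / 600)^3
  # dry matter: small, nearly flat, slight blue rise
  Kcm <- jit(8) + jit(3) * exp(-(wl - 400) / 300)
  n <- jit(1.40) + 0.045 * cos((wl - 400) / 600 * pi)
  tibble(wavelength = wl, n = n, Kcab = Kcab, Kcw = Kcw, Kcm = Kcm)
}
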