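# Wet-lab conversion formulas: spectrophotometric chlorophyll, equivalent
# water thickness and dry matter per unit leaf area.

#' Rice leaf area from length and width
#'
#' `A = a * b * 0.7746` with the rice leaf-area correction coefficient.
#'
#' @param a Maximum leaf length, cm.
#' @param b Maximum leaf width, cm.
#' @return Leaf area, cm^2.
#' @export
leaf_area <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) {
    abort("leaf dimensions must be positive", class = "leafplates_value_error")
  }
  a * b * 0.7746
}

#' Chlorophyll a and b concentrations from absorbances
#'
#' Lambert-Beer two-wavelength formulas for a 95% ethanol extract read at
#' 665 and 649 nm: `Ca = 13.95 A665 - 6.88 A649`,
#' `Cb = 24.96 A649 - 7.32 A665` (mg L^-1).  Negative concentrations
#' (possible for extreme absorbance ratios) are clipped to zero with a
#' warning.
#'
#' @param A665,A649 Absorbances, `>= 0`.
#' @return Tibble with `Ca`, `Cb` in mg L^-1.
#' @export
chlorophyll_ab <- function(A665, A649) {
  stopifnot(all(A665 >= 0), all(A649 >= 0))
  Ca <- 13.95 * A665 - 6.88 * A649
  Cb <- 24.96 * A649 - 7.32 * A665
  if (any(Ca < 0) || any(Cb < 0)) {
    warn("negative chlorophyll concentration clipped to 0")
  }
  tibble(Ca = pmax(Ca, 0), Cb = pmax(Cb, 0))
}

#' Area density of total chlorophyll
#'
#' Converts extract concentrations to leaf-area density:
#' `Cab = (Ca + Cb) * extract_volume / leaf_area_equiv`, with
#' mg L^-1 x mL = ug, giving ug cm^-2.
#'
#' @param Ca,Cb Concentrations, mg L^-1.
#' @param extract_volume Extract volume, mL (default 50).
#' @param leaf_area_equiv Leaf area equivalent of the extracted sample, cm^2.
#' @return Cab in ug cm^-2.
#' @export
chlorophyll_area_density <- function(Ca, Cb, extract_volume = 50, leaf_area_equiv) {
  if (any(leaf_area_equiv <= 0)) {
    abort("leaf area must be positive", class = "leafplates_value_error")
  }
  (Ca + Cb) * extract_volume / leaf_area_equiv
}

#' Equivalent water thickness
#'
#' Leaf water mass per unit area, `Cw = (M_fresh - M_dry) / A_leaf`
#' (g cm^-2).
#'
#' @param m_fresh,m_dry Fresh and dry mass, g, with `m_dry <= m_fresh`.
#' @param area Leaf area, cm^2.
#' @return Cw in g cm^-2.
#' @export
equivalent_water_thickness <- function(m_fresh, m_dry, area) {
  if (any(m_dry > m_fresh)) {
    abort("dry mass cannot exceed fresh mass", class = "leafplates_value_error")
  }
  if (any(area <= 0)) abort("leaf area must be positive", class = "leafplates_value_error")
  (m_fresh - m_dry) / area
}

#' Dry matter content per unit area
#'
#' `Cm = M_dry / A_leaf` (g cm^-2).
#'
#' @inheritParams equivalent_water_thickness
#' @return Cm in g cm^-2.
#' @export
dry_matter <- function(m_dry, area) {
  if (any(area <= 0)) abort("leaf area must be positive", class = "leafplates_value_error")
  m_dry / area
}

#' Turn a lab sheet into model biochemistry
#'
#' Takes one row per sample with the raw lab measurements (`sample_id`,
#' `leaf_len`, `leaf_wid` in cm, absorbances `A665`, `A649`,
#' `extract_volume` in mL, `fresh_mass`, `dry_mass` in g) and returns the
#' biochemistry table consumed by the forward models (`Cab` ug cm^-2, `Cw`
#' and `Cm` g cm^-2, plus the default structure parameter `N = 1`).
#'
#' @param lab Tibble of lab measurements.
#' @param N Structure parameter to attach (default 1).
#' @return Biochemistry tibble.
#' @export
process_lab_sheet <- function(lab, N = 1) {
  lab <- as_tibble(lab)
  area <- leaf_area(lab$leaf_len, lab$leaf_wid)
  conc <- chlorophyll_ab(lab$A665, lab$A649)
  vol <- if ("extract_volume" %in% names(lab)) lab$extract_volume else 50
  tibble(sample_id = lab$sample_id,
         N = N,
         Cab = chlorophyll_area_density(conc$Ca, conc$Cb, vol, area),
         Cw = equivalent_water_thickness(lab$fresh_mass, lab$dry_mass, area),
         Cm = dry_matter(lab$dry_mass, area))
}
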