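#' Leaf biochemistry and layer-partition containers
#'
#' `leaf_biochem()` bundles the four inputs of the plate models: the
#' structure parameter `N` (effective plate count, dimensionless), total
#' chlorophyll `Cab` (ug cm^-2), equivalent water thickness `Cw` (g cm^-2)
#' and dry matter `Cm` (g cm^-2).  `layer_partition()` describes how those
#' totals split between the upper (illuminated) and lower optical layer of
#' the two-layer model: `N1`, `N2` are per-layer structure parameters and
#' `Cab12`, `Cm12`, `Cw12` the fractions of each constituent assigned to
#' the upper layer.  Water is placed entirely in the upper layer by default
#' (`Cw12 = 1`), which is where optimization consistently puts it.
#'
#' @param N,N1,N2 Structure parameters, `> 0`.
#' @param Cab Chlorophyll content, ug cm^-2.
#' @param Cw Equivalent water thickness, g cm^-2.
#' @param Cm Dry matter content, g cm^-2.
#' @param Cab12,Cm12,Cw12 Upper-layer fractions in `[0, 1]`.
#' @return A one-row tibble.
#' @export
leaf_biochem <- function(N = 1, Cab = 30, Cw = 0.015, Cm = 0.005) {
  stopifnot(N > 0, Cab >= 0, Cw >= 0, Cm >= 0)
  tibble(N = N, Cab = Cab, Cw = Cw, Cm = Cm)
}

#' @rdname leaf_biochem
#' @export
layer_partition <- function(N1 = 2, N2 = 0.25, Cab12 = 0.9, Cm12 = 0.9, Cw12 = 1) {
  stopifnot(N1 > 0, N2 > 0,
            Cab12 >= 0, Cab12 <= 1, Cm12 >= 0, Cm12 <= 1, Cw12 >= 0, Cw12 <= 1)
  tibble(N1 = N1, N2 = N2, Cab12 = Cab12, Cm12 = Cm12, Cw12 = Cw12)
}

#' Per-layer absorption optical depths
#'
#' Optical depth per sublayer of each of the two layers:
#' `k1 = (Kcab Cab12 Cab + Kcw Cw12 Cw + Kcm Cm12 Cm) / N1` and
#' `k2` with the complementary fractions over `N2`.  Summing `N1 k1 + N2 k2`
#' recovers the whole-leaf constituent absorption exactly.
#'
#' @param constants Optical-constants tibble (see [load_optical_constants()]).
#' @param biochem One-row tibble from [leaf_biochem()].
#' @param partition One-row tibble from [layer_partition()].
#' @return Tibble with `wavelength`, `k1`, `k2`.
#' @export
layer_absorption <- function(constants, biochem, partition) {
  constants <- validate_constants(constants)
  p <- partition
  if (p$N1 <= 0 || p$N2 <= 0) {
    abort("layer structure parameters must be positive", class = "leafplates_domain_error")
  }
  total_ab <- constants$Kcab * biochem$Cab
  total_w <- constants$Kcw * biochem$Cw
  total_m <- constants$Kcm * biochem$Cm
  tibble(
    wavelength = constants$wavelength,
    k1 = (total_ab * p$Cab12 + total_w * p$Cw12 + total_m * p$Cm12) / p$N1,
    k2 = (total_ab * (1 - p$Cab12) + total_w * (1 - p$Cw12) + total_m * (1 - p$Cm12)) / p$N2
  )
}

# Precompute everything that depends only on constants and alpha: the two
# cone-averaged transmittances and the interior interface coefficients.
# Reused across all candidates of an inversion.
precompute_surface <- function(constants, alpha) {
  n <- constants$n
  t90 <- average_transmittance(90, n)
  list(
    wavelength = constants$wavelength,
    n = n,
    ta = average_transmittance(alpha, n),
    t90 = t90,
    to = t90 / n^2,
    ri = 1 - t90 / n^2,
    Kcab = constants$Kcab, Kcw = constants$Kcw, Kcm = constants$Kcm
  )
}

# elementwise two-layer pipeline; tau1/tau2 vectors or wavelength x candidate
# matrices, N1/N2 scalars or per-candidate vectors
.two_layer_pipeline <- function(sf, tau1, tau2, N1, N2) {
  if (any(N1 < 1)) {
    abort("upper-layer structure parameter N1 must be >= 1 (the directional entry plate)",
          class = "leafplates_domain_error")
  }
  top_first <- .elementary_from_coefs(sf$ta, sf$t90, sf$to, sf$ri, tau1)
  top_rest <- stokes_stack(.elementary_from_coefs(sf$t90, sf$t90, sf$to, sf$ri, tau1),
                           N1 - 1)
  layer1 <- combine_two_layers(top_first, top_rest)
  layer2 <- stokes_stack(.elementary_from_coefs(sf$t90, sf$t90, sf$to, sf$ri, tau2), N2)
  combine_two_layers(layer1, layer2)
}

#' Two-layer partitioned plate forward model
#'
#' Simulates leaf reflectance and transmittance for a leaf treated as two
#' stacked optical layers with distinct structure parameters and
#' constituent loads.  The upper layer receives directional illumination in
#' a cone of half-angle `alpha` (first plate), with all internal passes
#' isotropic; each layer is a generalized (real-valued) Stokes pile; the
#' two layers are coupled by the adding rule over all interlayer bounces.
#'
#' @inheritParams layer_absorption
#' @param alpha Incidence cone half-angle, degrees (default 40, the
#'   plate-model convention for directly illuminated leaves).
#' @return A [leaf_spectrum()] tibble with `reflectance` and
#'   `transmittance`.
#' @export
#' @examples
#' cst <- synthetic_optical_constants(seed = 1)
#' spec <- forward_two_layer(cst, leaf_biochem(Cab = 40), layer_partition())
#' range(spec$reflectance)
forward_two_layer <- function(constants, biochem, partition, alpha = 40) {
  constants <- validate_constants(constants)
  ks <- layer_absorption(constants, biochem, partition)
  sf <- precompute_surface(constants, alpha)
  out <- .two_layer_pipeline(sf,
                             absorption_transmissivity(ks$k1),
                             absorption_transmissivity(ks$k2),
                             partition$N1, partition$N2)
  leaf_spectrum(constants$wavelength, out$R_dn, out$T_dn)
}

#' Uniform-leaf plate forward model (PROSPECT-style baseline)
#'
#' The classical generalized plate model: one homogeneous leaf of structure
#' parameter `N` with per-sublayer optical depth
#' `k = (Kcab Cab + Kcw Cw + Kcm Cm) / N`; a directional first plate topped
#' on an isotropic pile of `N - 1` plates.
#'
#' @inheritParams forward_two_layer
#' @return A [leaf_spectrum()] tibble.
#' @export
forward_uniform <- function(constants, biochem, alpha = 40) {
  constants <- validate_constants(constants)
  N <- biochem$N
  if (N < 1) warn("structure parameter N below 1: plate pile extrapolated")
  k <- (constants$Kcab * biochem$Cab + constants$Kcw * biochem$Cw +
          constants$Kcm * biochem$Cm) / N
  tau <- absorption_transmissivity(k)
  sf <- precompute_surface(constants, alpha)
  first <- .elementary_from_coefs(sf$ta, sf$t90, sf$to, sf$ri, tau)
  rest <- stokes_stack(.elementary_from_coefs(sf$t90, sf$t90, sf$to, sf$ri, tau),
                       max(N - 1, 0))
  out <- combine_two_layers(first, rest)
  leaf_spectrum(constants$wavelength, out$R_dn, out$T_dn)
}

# Batch forward over a population: params is a data frame / list with
# vectors N1, N2, Cab12, Cm12, Cw12 (one entry per candidate); returns the
# reflectance matrix (wavelength x candidate).  Used by the inversion.
.forward_two_layer_batch <- function(sf, biochem, params) {
  P <- length(params$N1)
  ab <- sf$Kcab * biochem$Cab
  w <- sf$Kcw * biochem$Cw
  m <- sf$Kcm * biochem$Cm
  k1 <- (outer(ab, params$Cab12) + outer(w, params$Cw12) + outer(m, params$Cm12))
  k1 <- sweep(k1, 2, params$N1, "/")
  k2 <- (outer(ab, 1 - params$Cab12) + outer(w, 1 - params$Cw12) +
           outer(m, 1 - params$Cm12))
  k2 <- sweep(k2, 2, params$N2, "/")
  out <- .two_layer_pipeline(sf, absorption_transmissivity(k1),
                             absorption_transmissivity(k2),
                             params$N1, params$N2)
  out$R_dn
}

# Batch uniform forward: params$N per candidate.
.forward_uniform_batch <- function(sf, biochem, params) {
  ktot <- sf$Kcab * biochem$Cab + sf$Kcw * biochem$Cw + sf$Kcm * biochem$Cm
  k <- outer(ktot, 1 / params$N)
  tau <- absorption_transmissivity(k)
  first <- .elementary_from_coefs(sf$ta, sf$t90, sf$to, sf$ri, tau)
  rest <- stokes_stack(.elementary_from_coefs(sf$t90, sf$t90, sf$to, sf$ri, tau),
                       pmax(params$N - 1, 0))
  combine_two_layers(first, rest)$R_dn
}
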