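# Plate-optics primitives: Fresnel cone-averaged transmittance, the
# exponential-integral absorption transmissivity, single plates, Stokes
# piles of identical plates (real-valued plate count), and adding of
# stacked layers.  All functions are elementwise over wavelength and accept
# vectors or matrices (wavelength x candidate), which is what makes the
# evolutionary inversion affordable in pure R.

#' Exponential integral E1
#'
#' Vectorized E1(x) = integral from x to infinity of t^-1 exp(-t) dt, by
#' power series for x <= 2 and a modified-Lentz continued fraction above.
#' Accurate to ~1e-15 relative over the range used by the absorption model.
#'
#' @param x Nonnegative numeric vector (or matrix).
#' @return E1(x), same shape as `x`; `Inf` at `x = 0`.
#' @export
expint_e1 <- function(x) {
  if (any(x < 0)) abort("E1 requires x >= 0", class = "leafplates_domain_error")
  out <- x
  out[x == 0] <- Inf
  small <- x > 0 & x <= 2
  if (any(small)) {
    xs <- x[small]
    term <- xs
    s <- xs
    for (m in 2:30) {
      term <- term * (-xs) / m
      s <- s + term / m
    }
    out[small] <- -0.577215664901532861 - log(xs) + s
  }
  big <- x > 2
  if (any(big)) {
    xb <- x[big]
    b <- xb + 1
    c <- 1e300
    d <- 1 / b
    h <- d
    for (m in 1:35) {
      a <- -m * m
      b <- b + 2
      d <- 1 / (a * d + b)
      c <- b + a / c
      h <- h * d * c
    }
    out[big] <- h * exp(-xb)
  }
  out
}

# cache for Gauss-Legendre nodes (Golub-Welsch on the Jacobi matrix)
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(k, a, b) {
  key <- paste(k, a, b)
  hit <- .gl_cache[[key]]
  if (!is.null(hit)) return(hit)
  i <- seq_len(k - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  res <- list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
  .gl_cache[[key]] <- res
  res
}

# unpolarized Fresnel transmission factor, incidence from vacuum into index n
fresnel_transmission <- function(theta, n) {
  ci <- cos(theta)
  st <- sin(theta) / n
  ct <- sqrt(1 - st^2)
  rs <- ((ci - n * ct) / (ci + n * ct))^2
  rp <- ((n * ci - ct) / (n * ci + ct))^2
  1 - (rs + rp) / 2
}

#' Cone-averaged Fresnel transmittance
#'
#' Mean unpolarized Fresnel transmittance for light entering a medium of
#' relative refractive index `n` from vacuum, averaged over an incidence
#' cone of half-angle `alpha`, with the usual projected-solid-angle weight
#' sin(theta) cos(theta).  Computed by 64-node Gauss-Legendre quadrature.
#' The reverse direction (from inside the medium out) follows from the
#' Stern reciprocity identity `tav(alpha, n -> 1) = n^-2 tav(alpha, 1 -> n)`
#' and is returned when `from_inside = TRUE`.
#'
#' @param alpha Cone half-angle in degrees, in (0, 90].  `alpha = 90` is the
#'   isotropic (Lambertian) case used for all internal passes.
#' @param n Refractive index (vector), `>= 1`.
#' @param from_inside Apply the Stern identity for the medium-to-vacuum
#'   direction.
#' @return Transmittance fraction(s) in `[0, 1]`.
#' @export
average_transmittance <- function(alpha, n, from_inside = FALSE) {
  if (any(n < 1)) abort("refractive index must be >= 1", class = "leafplates_domain_error")
  if (alpha <= 0 || alpha > 90) {
    abort("alpha must be in (0, 90] degrees", class = "leafplates_domain_error")
  }
  a <- alpha * pi / 180
  q <- gauss_legendre(64, 0, a)
  wgt <- q$w * sin(q$x) * cos(q$x)
  # rows: quadrature nodes, cols: n values
  tf <- outer(q$x, n, fresnel_transmission)
  tav <- colSums(tf * wgt) / sum(wgt)
  tav[n == 1] <- 1
  if (from_inside) tav <- tav / n^2
  tav
}

#' Absorption transmissivity of a compact layer
#'
#' Fraction of isotropic incident radiation transmitted through a compact
#' absorbing layer of optical depth `k`:
#' `tau(k) = (1 - k) exp(-k) + k^2 E1(k)`.
#'
#' @param k Optical depth(s), `>= 0`.
#' @return `tau` in `[0, 1]`; `tau(0) = 1`.
#' @export
absorption_transmissivity <- function(k) {
  if (any(k < 0)) abort("optical depth k must be >= 0", class = "leafplates_domain_error")
  tau <- k
  z <- k == 0
  tau[z] <- 1
  if (any(!z)) {
    kk <- k[!z]
    tau[!z] <- (1 - kk) * exp(-kk) + kk^2 * expint_e1(kk)
  }
  pmin(pmax(tau, 0), 1)
}

#' Layer optics container
#'
#' Four directional reflectance/transmittance fractions of a (stack of)
#' plate(s): `R_dn`/`T_dn` for light arriving from above, `R_up`/`T_up`
#' from below.  Elementwise vectors or matrices over wavelength.
#'
#' @param R_dn,T_dn,R_up,T_up Fractions in `[0, 1]`.
#' @return A `layer_optics` list.
#' @export
layer_optics <- function(R_dn, T_dn, R_up = R_dn, T_up = T_dn) {
  structure(list(R_dn = R_dn, T_dn = T_dn, R_up = R_up, T_up = T_up),
            class = "layer_optics")
}

#' Single compact plate with rough interfaces
#'
#' Reflectance and transmittance of one compact absorbing plate bounded by
#' air, with directional illumination from above within a cone of half-angle
#' `alpha` and isotropic radiation everywhere else (internal bounces and
#' illumination from below).  All internal bounce orders are summed in
#' closed form (geometric series over the two interior interface
#' reflections).
#'
#' @param alpha Incidence cone half-angle (degrees) for the top surface.
#' @param n Refractive index (vector over wavelength).
#' @param tau Absorption transmissivity of the plate interior (vector or
#'   matrix; see [absorption_transmissivity()]).
#' @return A [layer_optics()] object.
#' @export
elementary_layer <- function(alpha, n, tau) {
  ta <- average_transmittance(alpha, n)
  t90 <- average_transmittance(90, n)
  to <- t90 / n^2          # interior -> air, Stern identity
  ri <- 1 - to             # interior interface reflectance (from inside)
  .elementary_from_coefs(ta, t90, to, ri, tau)
}

# core plate formula; ta/t90/to/ri are per-wavelength vectors, tau may be a
# wavelength x candidate matrix (column recycling)
.elementary_from_coefs <- function(ta, t90, to, ri, tau) {
  denom <- 1 - ri^2 * tau^2
  common <- tau^2 * ri * to / denom
  layer_optics(
    R_dn = (1 - ta) + ta * common,
    T_dn = ta * tau * to / denom,
    R_up = (1 - t90) + t90 * common,
    T_up = t90 * tau * to / denom
  )
}

#' Stokes pile of identical plates
#'
#' Reflectance and transmittance of `n_sub` identical isotropic plates,
#' by the classical closed-form solution of the pile-of-plates system.
#' With single-plate values r, t the discriminant is
#' `D = sqrt((1+r+t)(1+r-t)(1-r+t)(1-r-t))` and
#' `a = (1 + r^2 - t^2 + D)/(2r)`, `b = (1 - r^2 + t^2 + D)/(2t)`;
#' the pile of m plates is
#' `R(m) = a (b^{2m} - 1) / (a^2 b^{2m} - 1)` and
#' `T(m) = b^m (a^2 - 1) / (a^2 b^{2m} - 1)`.
#' `n_sub` may be any nonnegative real; values below 1 extrapolate the
#' closed form (the structure parameter is an effective, not a physical,
#' plate count).
#'
#' @param layer A [layer_optics()] for the isotropic elementary plate
#'   (its `R_up`/`T_up` side is used, which equals `R_dn`/`T_dn` for
#'   isotropic plates).
#' @param n_sub Plate count, real, `>= 0`.  `0` returns the identity layer.
#' @return A [layer_optics()] object (symmetric).
#' @export
stokes_stack <- function(layer, n_sub) {
  r <- layer$R_up
  t <- layer$T_up
  if (any(n_sub < 0)) abort("n_sub must be >= 0", class = "leafplates_domain_error")
  d2 <- (1 + r + t) * (1 + r - t) * (1 - r + t) * (1 - r - t)
  if (any(d2 < -1e-12)) {
    abort("invalid optical regime: r + t > 1 gives a complex Stokes discriminant",
          class = "leafplates_numeric_domain_error")
  }
  D <- sqrt(pmax(d2, 0))
  # broadcast n_sub (scalar, per-wavelength vector, or per-candidate vector
  # against a wavelength x candidate matrix) to the shape of r
  m <- if (length(n_sub) == 1) {
    r * 0 + n_sub
  } else if (is.matrix(r) && length(n_sub) == ncol(r)) {
    matrix(n_sub, nrow(r), ncol(r), byrow = TRUE)
  } else {
    r * 0 + n_sub
  }
  eps <- 1e-12
  scatterless <- r < eps               # no interface contrast: Beer-like pile
  opaque <- t < eps & !scatterless     # only the first plate is visible
  conservative <- (1 - r - t) < 1e-11 & !scatterless & !opaque  # a,b -> 1 limit
  general <- !scatterless & !opaque & !conservative

  R <- r * 0
  T <- r * 0
  if (any(general)) {
    rg <- r[general]; tg <- t[general]; Dg <- D[general]; mg <- m[general]
    a <- (1 + rg^2 - tg^2 + Dg) / (2 * rg)
    b <- (1 - rg^2 + tg^2 + Dg) / (2 * tg)
    bm <- b^mg
    den <- a^2 * bm^2 - 1
    R[general] <- a * (bm^2 - 1) / den
    T[general] <- bm * (a^2 - 1) / den
  }
  if (any(conservative)) {
    # non-absorbing pile: exact limit of the Stokes solution
    rc <- r[conservative]; mc <- m[conservative]
    R[conservative] <- mc * rc / (1 + (mc - 1) * rc)
    T[conservative] <- 1 - R[conservative]
  }
  if (any(scatterless)) {
    T[scatterless] <- t[scatterless]^m[scatterless]
    R[scatterless] <- 0
  }
  if (any(opaque)) {
    R[opaque] <- r[opaque]
    T[opaque] <- 0
  }
  zero <- m == 0                       # empty pile is the identity layer
  R[zero] <- 0
  T[zero] <- 1
  layer_optics(R_dn = R, T_dn = T)
}

#' Couple two stacked layers
#'
#' Total reflectance and transmittance of two layers stacked on top of each
#' other, closing the geometric series over all interlayer bounces:
#' `R = R1v + T1v R2v T1^ / (1 - R1^ R2v)` and
#' `T = T1v T2v / (1 - R1^ R2v)` (v = from above, ^ = from below), plus the
#' matching expressions for illumination from below.  This is the standard
#' adding rule of plate models; identical media touch with no extra Fresnel
#' interface (each layer's own interfaces are already inside its plate
#' solution).
#'
#' @param top,bottom [layer_optics()] objects.
#' @return A [layer_optics()] object for the coupled stack.
#' @export
combine_two_layers <- function(top, bottom) {
  den <- 1 - top$R_up * bottom$R_dn
  if (any(den <= 0)) {
    abort("physically inconsistent layers: interlayer series does not converge",
          class = "leafplates_physics_error")
  }
  layer_optics(
    R_dn = top$R_dn + top$T_dn * bottom$R_dn * top$T_up / den,
    T_dn = top$T_dn * bottom$T_dn / den,
    R_up = bottom$R_up + bottom$T_up * top$R_up * bottom$T_dn / den,
    T_up = bottom$T_up * top$T_up / den
  )
}
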