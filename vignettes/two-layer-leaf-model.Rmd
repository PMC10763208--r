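---
title: "A two-layer plate model for rice leaf spectra and its evolutionary inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer plate model for rice leaf spectra and its evolutionary inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Leaf radiative-transfer models map biochemistry — chlorophyll content
`Cab` (µg cm⁻²), equivalent water thickness `Cw` (g cm⁻²), dry matter
`Cm` (g cm⁻²) — plus an effective structure parameter `N` to the leaf's
reflectance and transmittance spectrum, here over 400–1000 nm at 1 nm
(601 bands).  Classical plate models (the PROSPECT lineage) assume those
constituents are spread uniformly through the mesophyll.  Rice leaves are
visibly stratified: palisade tissue rich in chloroplasts sits under the
upper epidermis, spongy tissue with large air gaps below.  `leafplates`
implements a two-layer variant of the generalized plate model in which the
totals are split between an upper (illuminated) and a lower optical layer,
and retrieves the split from a measured spectrum with an in-package
NSGA-III optimizer.

## The forward model

**Surface terms.**  Light enters the leaf through a rough epidermis.  The
cone-averaged unpolarized Fresnel transmittance
`tav(α, n)` is computed by 64-node Gauss–Legendre quadrature of the
Fresnel transmission factor weighted by `sin θ cos θ` over the incidence
cone; `average_transmittance()` also exposes the reverse
(medium-to-vacuum) direction through the Stern reciprocity
`tav(α, n→1) = n⁻² tav(α, 1→n)`.  The first pass uses a cone of
half-angle `α = 40°` (the plate-model convention for direct
illumination); all internal and return passes are isotropic (`α = 90°`).
The incidence angle is a tunable argument of every forward function.

**Absorption.**  A compact sublayer of optical depth `k` transmits the
fraction

`τ(k) = (1 − k) e⁻ᵏ + k² E₁(k)`,

with `E₁` the exponential integral.  `E₁` is evaluated in-package
(`expint_e1()`) by a 30-term power series for `x ≤ 2` and a 35-iteration
modified-Lentz continued fraction above, accurate to ~1e-13 relative; the
test-suite cross-checks it against `pracma::expint` and adaptive
quadrature.  It is written as fully vectorized arithmetic because the
optimizer evaluates millions of depths per inversion.

**One plate, a pile of plates, two layers.**  `elementary_layer()` closes
the geometric series over all internal bounces of a single plate.
`stokes_stack()` extends one isotropic plate to a pile of `m` identical
plates with the classical closed form: with single-plate `r`, `t`,

`D = √((1+r+t)(1+r−t)(1−r+t)(1−r−t))`,
`a = (1 + r² − t² + D)/(2r)`, `b = (1 − r² + t² + D)/(2t)`,
`R(m) = a(b²ᵐ − 1)/(a²b²ᵐ − 1)`, `T(m) = bᵐ(a² − 1)/(a²b²ᵐ − 1)`.

`m` may be any nonnegative real; values below 1 (the retrieved lower
layer is often near 0.1–0.5) evaluate the same closed form — an
extrapolation, since a fractional plate count has no direct physical
meaning.  `combine_two_layers()` couples two stacks by the adding rule,
i.e. the complete geometric series over interlayer bounces:

`R = R₁↓ + T₁↓ R₂↓ T₁↑ / (1 − R₁↑ R₂↓)`, `T = T₁↓ T₂↓ / (1 − R₁↑ R₂↓)`.

Touching layers share the same medium, so the internal boundary carries
no Fresnel term of its own; every interface lives inside a plate's own
solution.  All three closed forms are verified against explicit
bounce-enumeration / repeated-adding oracles, and the adding rule is
associative to 1e-12, which is what makes the model-reduction property
below exact.

**The two-layer leaf.**  Per-layer sublayer optical depths are

`k₁(λ) = (Kcab·Cab₁₂·Cab + Kcw·Cw₁₂·Cw + Kcm·Cm₁₂·Cm)/N₁`,
`k₂(λ)` with the complementary fractions over `N₂`,

where `Kᵢ(λ)` are specific absorption coefficients and `Cab₁₂, Cw₁₂,
Cm₁₂ ∈ [0, 1]` the upper-layer fractions.  Note the per-constituent
products `Kᵢ Cᵢ`: this is what makes `N₁k₁ + N₂k₂` equal the whole-leaf
constituent absorption exactly (a unit-tested conservation law).  Layer 1
is the illuminated side: one directional plate plus an isotropic pile of
`N₁ − 1`; layer 2 is an isotropic pile of `N₂`; the two are coupled by
the adding rule.  With a proportional split
(`Cab₁₂ = Cw₁₂ = Cm₁₂ = N₁/(N₁+N₂)`) the construction collapses exactly
to the uniform model with `N = N₁ + N₂` — `forward_uniform()`, the
PROSPECT-style baseline — which the suite asserts to 1e-8 across the
grid.  Water defaults to the upper layer entirely (`Cw₁₂ = 1`):
inversions consistently drive it there, and fixing it removes one search
dimension.

## The inversion

The optimizer searches the unit box `[0,1]⁴` with the affine encoding

`N₁ = N(2 + 0.01 x₁)`, `N₂ = N(0.1 + 2.9 x₂)`, `Cab₁₂ = x₃`, `Cm₁₂ = x₄`,

(`N = 1` by default, so `N₁ ∈ [2, 2.01]`, `N₂ ∈ [0.1, 3]`), minimizing
the relative-deviation fitness

`y = Σλ |R_mod(λ) − R_meas(λ)| / R_meas(λ)`,

so `y = 6.01` on the 601-band grid is a 1% mean relative error.  Measured
reflectance at or below zero is floored at 1e-6 (blue-band noise guard).

NSGA-III is implemented in-package: fast non-dominated sorting (checked
against a brute-force dominance matrix), Das–Dennis reference points,
adaptive normalization with achievement-scalarizing extreme points and
intercept fallback to per-axis maxima, niche-preserving truncation of the
last front, simulated-binary crossover (`η_c = 30`) and polynomial
mutation (`η_m = 20`, probability `1/d`).  One deliberate deviation from
the canonical algorithm: a non-empty niche contributes its *closest*
remaining candidate rather than a random one, which makes the degenerate
single-reference case select exactly the K smallest perpendicular
distances and removes one source of run-to-run noise.  Randomness enters
only through the seeded base-R RNG, so entire runs are bit-reproducible.

Because the fitness is a single scalar, NSGA-III degenerates in the
default `mode = "faithful"` (M = 1) to elitist rank selection on `y`.  A
`mode = "band_split"` (M = 3) variant optimizes the fitness separately
over the blue-green (400–560 nm), yellow-red (560–780 nm) and
near-infrared (780–1000 nm) bands and reports the best compromise by
minimal total; it is provided because a multi-objective driver on a
scalar loss is otherwise an odd fit, but the faithful mode is the
default.  Interior band edges belong to the band on their left, so the
three bands partition the 601 wavelengths deterministically.

Accuracy is reported as relative RMSE — RMS error divided by the
band-mean measured reflectance (`rmse_spectral()`, with
`relative = FALSE` for the plain version).  The uniform baseline is fitted
per sample by the same optimizer over `N ∈ [1, 3]`, so model comparisons
(`compare_models()`) hold the fitting machinery fixed.

## The synthetic cohort generator

No public rice spectra accompany the model, so `simulate_cohort()`
emulates the study conditions: four growth periods
(tillering/jointing/heading/grouting) with 38/60/60/60 samples and
per-period min–max envelopes for `Cab`, `Cw`, `Cm`; ground-truth
partitions drawn from `N₁ ∈ [2, 2.01]`, `N₂ ∈ [0.1, 3]`,
`Cab₁₂ ∈ [0.1157, 1]`, `Cm₁₂ ∈ [0, 1]`; spectra from the forward model
plus iid Gaussian noise (`noise_sd = 0.01` reflectance units, a typical
field-spectrometer magnitude) clipped to `[0, 1]`.  Draws are uniform
within the envelopes, since only range information is available.
`synthetic_optical_constants()` supplies smooth stand-in coefficient
curves — chlorophyll bands at 450 and 650 nm, water rising into the NIR
with a 970 nm band, flat dry matter, slowly varying `n ≈ 1.35–1.45` —
sized so that cohort spectra span realistic reflectance levels.

What passing tests on such cohorts show: the optics are internally
consistent, the optimizer recovers parameters that are identifiable, and
the pipeline is deterministic.  What they cannot show: agreement with
real rice leaves, which would require measured spectra and calibrated
absorption-coefficient curves (`load_optical_constants()` accepts any
user-supplied table).  Synthetic noise is iid and additive; real spectra
carry correlated instrument and illumination structure that the
Savitzky–Golay preprocessing (`sg_smooth()`, default window 11, order 3)
only partly mimics.

## Numerical choices and degenerate inputs

* Conservative (non-absorbing) piles make the Stokes `a, b` system 0/0;
  below an absorptance of 1e-11 the exact limit
  `R(m) = m r/(1 + (m−1) r)` is used.
* Scatterless plates (`r < 1e-12`, no index contrast) reduce to `tᵐ`;
  opaque plates (`t < 1e-12`) return the first plate's reflectance.
* `r + t > 1` (a non-physical layer) raises a numeric-domain error rather
  than returning a complex discriminant.
* The empty pile (`m = 0`) is the identity layer, which is how `N₁ = 1`
  and the baseline `N = 1` fall out of the same code path.
* Sort/selection ties and the GA are driven by one seeded RNG stream;
  per-sample seeds in cohort inversions are derived as
  `seed + 7919·i` (kept below 2³¹).

## Problem sizes used by the tests and acceptance script

Module tests run mostly on a coarse 10 nm grid (61 bands), where every
closed form is still exercised.  Recovery checks use the full 601-band
grid with population 60 and 60 generations — about 3 s per sample, and
ample for this 4-parameter search: noiseless self-inversions recover
`Cab₁₂` to well under ±0.05 with `y` far below the 1%-error threshold,
and noisy fits reach the injected noise floor to within a 2% convergence
margin.  The acceptance script simulates 12-sample cohorts (3 per
period).  The package default (`ga_config()`: population 100, 200
generations) is the canonical setting for harder, real-data inversions.

## Known limitations

* The structure parameters are effective quantities; `N₂ < 1` in
  particular has no direct anatomical reading, and retrieved `N₂` is the
  least identifiable of the four (its influence on the spectrum is weak
  when the lower layer absorbs little — visible as the largest recovery
  spread in the tests).
* Chlorophyll here lumps carotenoids and anthocyanins; no attempt is
  made to separate them or to stratify them independently.
* The epidermis is treated as a smooth Lambertian-rough interface; real
  cuticle texture, trichomes and stomata are outside the model, as are
  polarization and bidirectional effects.
* The shipped constants are synthetic stand-ins; quantitative use
  requires measured coefficient curves.
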