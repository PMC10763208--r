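# Shared fixtures built in code.  The coarse grid keeps module tests fast;
# acceptance checks that need the full 601-band grid build it themselves.

fixture_constants <- function(seed = 1, coarse = FALSE) {
  grid <- if (coarse) spectral_grid(by = 10) else spectral_grid()
  synthetic_optical_constants(seed = seed, grid = grid)
}

# random valid symmetric layer (R + T <= 1)
random_layer <- function() {
  r <- runif(1, 0.01, 0.5)
  t <- runif(1, 0.01, 1 - r - 0.01)
  layer_optics(R_dn = r, T_dn = t)
}

random_biochem <- function() {
  leaf_biochem(N = runif(1, 1, 3),
               Cab = runif(1, 6.15, 110.7),
               Cw = runif(1, 0.0024, 0.15),
               Cm = runif(1, 0.0013, 0.0131))
}

random_partition <- function() {
  layer_partition(N1 = runif(1, 2, 2.01), N2 = runif(1, 0.1, 3),
                  Cab12 = runif(1), Cm12 = runif(1))
}

small_cohort <- function(n = c(2L, 1L, 1L, 1L), noise_sd = 0, seed = 42,
                         constants = fixture_constants()) {
  periods <- default_periods()
  periods$n <- n
  spec <- cohort_spec(periods = periods, noise_sd = noise_sd, seed = seed)
  simulate_cohort(spec, constants)
}

# noise-free spectra implied by a set's stored ground truth
truth_spectra <- function(set, constants) {
  ids <- set$biochem$sample_id
  lapply(seq_along(ids), function(i) {
    d <- dplyr::left_join(set$biochem[i, ], set$truth[i, ], by = "sample_id")
    forward_two_layer(constants, d[c("N", "Cab", "Cw", "Cm")],
                      d[c("N1", "N2", "Cab12", "Cm12", "Cw12")],
                      alpha = set$alpha)
  })
}
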