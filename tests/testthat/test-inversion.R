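cst <- fixture_constants(seed = 2, coarse = TRUE)

test_that("band RMSE matches closed-form scaling and the naive loop", {
  wl <- cst$wavelength
  set.seed(121)
  m <- runif(length(wl), 0.05, 0.6)
  expect_equal(rmse_spectral(m, m, wl), 0)
  # uniform relative perturbation: rmse = |c| * rms(m) / mean(m)
  for (c_ in c(0.1, -0.25)) {
    got <- rmse_spectral(m, m * (1 + c_), wl, lo = 560, hi = 780)
    keep <- wl > 560 & wl <= 780
    expected <- abs(c_) * sqrt(mean(m[keep]^2)) / mean(m[keep])
    expect_lt(abs(got - expected), 1e-12)
  }
  s <- runif(length(wl), 0.05, 0.6)
  expect_lt(abs(rmse_spectral(m, s, wl) - oracle_rmse(m, s, wl, 400, 1000)), 1e-12)
  for (b in seq_len(nrow(band_definitions()))) {
    bd <- band_definitions()[b, ]
    expect_lt(abs(rmse_spectral(m, s, wl, bd$lo, bd$hi) -
                    oracle_rmse(m, s, wl, bd$lo, bd$hi)), 1e-12)
  }
  # plain RMSE exposed as well
  expect_equal(rmse_spectral(m, s, wl, relative = FALSE), sqrt(mean((m - s)^2)))
})

test_that("band edges partition the grid deterministically", {
  wl <- spectral_grid()
  bands <- band_definitions()[-1, ]
  masks <- lapply(seq_len(nrow(bands)),
                  function(i) band_mask(wl, bands$lo[i], bands$hi[i]))
  counts <- rowSums(do.call(cbind, masks))
  expect_true(all(counts == 1))
  expect_true(masks[[1]][wl == 560])
  expect_true(masks[[2]][wl == 780])
})

test_that("self-inversion on noiseless spectra recovers the partition", {
  set <- small_cohort(n = c(1L, 1L, 0L, 0L), noise_sd = 0, seed = 13, constants = cst)
  inv <- invert_cohort(set, cst, ga_config(pop_size = 40, generations = 50, seed = 2))
  res <- dplyr::left_join(inv$results, set$truth, by = "sample_id",
                          suffix = c("", "_true"))
  n_bands <- nrow(cst)
  expect_true(all(res$fitness < 0.01 * n_bands))  # < 1% mean relative error
  expect_true(all(abs(res$Cab12 - res$Cab12_true) < 0.05))
  expect_true(all(res$rmse_full >= 0))
})

test_that("inversion is reproducible and zero generations returns the best of the initial population", {
  set <- small_cohort(n = c(1L, 0L, 0L, 0L), noise_sd = 0, seed = 14, constants = cst)
  measured <- tibble::tibble(wavelength = set$spectra$wavelength,
                             reflectance = set$spectra$S001)
  cfg <- ga_config(pop_size = 20, generations = 5, seed = 3)
  a <- invert_sample(measured, set$biochem[1, ], cst, cfg)
  b <- invert_sample(measured, set$biochem[1, ], cst, cfg)
  expect_identical(tidy(a), tidy(b))
  expect_identical(a$trace, b$trace)
  cfg0 <- ga_config(pop_size = 20, generations = 0, seed = 3)
  z <- invert_sample(measured, set$biochem[1, ], cst, cfg0)
  set.seed(3)
  X0 <- matrix(runif(20 * 4), 20, 4)
  params <- encode_partition(X0, N = set$biochem$N[1])
  sf <- precompute_surface(cst, 40)
  R0 <- .forward_two_layer_batch(sf, set$biochem[1, ], params)
  y0 <- apply(R0, 2, function(r) fitness_y(r, measured$reflectance))
  expect_equal(z$fitness, min(y0), tolerance = 1e-10)
})

test_that("parameter summaries match hand arithmetic and the two-pass oracle", {
  one <- tibble::tibble(N1 = 2, N2 = 0.3, Cab12 = 0.9, Cm12 = 0.8)
  s1 <- summarize_parameters(one)
  expect_equal(s1$min, s1$max)
  expect_equal(s1$min, s1$mean)
  expect_equal(s1$variance, rep(0, 4))
  two <- tibble::tibble(N1 = c(2, 2), N2 = c(0.2, 0.4),
                        Cab12 = c(0.8, 1.0), Cm12 = c(0.5, 0.7))
  s2 <- summarize_parameters(two)
  expect_equal(s2$mean[s2$parameter == "Cab12"], 0.9)
  expect_equal(s2$variance[s2$parameter == "Cab12"], 0.01)
  set.seed(131)
  many <- tibble::tibble(N1 = runif(100, 2, 2.01), N2 = runif(100, 0.1, 3),
                         Cab12 = runif(100), Cm12 = runif(100))
  sm <- summarize_parameters(many)
  for (p in sm$parameter) {
    expect_lt(abs(sm$variance[sm$parameter == p] - oracle_var(many[[p]])), 1e-10)
  }
  expect_error(summarize_parameters(list()), class = "leafplates_value_error")
  # permutation invariance
  perm <- many[sample(100), ]
  expect_equal(summarize_parameters(perm), sm)
})

test_that("parameter correlations match the textbook formula", {
  set.seed(141)
  n <- 30
  res <- tibble::tibble(sample_id = sprintf("S%03d", 1:n),
                        N1 = runif(n, 2, 2.01), N2 = runif(n, 0.1, 3),
                        Cab12 = runif(n), Cm12 = runif(n))
  bio <- tibble::tibble(sample_id = res$sample_id, N = runif(n, 1, 3),
                        Cab = 100 * res$Cab12 + rnorm(n),      # strongly linked
                        Cw = runif(n, 0.002, 0.15),
                        Cm = runif(n, 0.001, 0.013))
  cm <- parameter_correlations(res, bio)
  expect_true(all(abs(cm) <= 1 + 1e-12))
  for (i in rownames(cm)) {
    for (j in colnames(cm)) {
      expect_lt(abs(cm[i, j] - oracle_cor(res[[i]], bio[[j]])), 1e-12)
    }
  }
  # perfect linear and anti-linear pairs
  bio2 <- bio
  bio2$Cab <- 3 * res$Cab12 + 1
  bio2$Cw <- -2 * res$N2 + 5
  cm2 <- parameter_correlations(res, bio2)
  expect_equal(cm2["Cab12", "Cab"], 1)
  expect_equal(cm2["N2", "Cw"], -1)
  # zero variance propagates as NA with a warning
  bio3 <- bio
  bio3$Cm <- 0.005
  expect_warning(cm3 <- parameter_correlations(res, bio3), "zero-variance")
  expect_true(all(is.na(cm3[, "Cm"])))
})

test_that("model comparison emits both models and all bands for every sample", {
  set <- small_cohort(n = c(1L, 1L, 0L, 0L), noise_sd = 0.01, seed = 15, constants = cst)
  cmp <- compare_models(set, cst, ga_config(pop_size = 20, generations = 10, seed = 4))
  expect_setequal(unique(cmp$per_sample$model), c("two_layer", "uniform"))
  expect_equal(nrow(cmp$per_sample), 2 * 2 * nrow(band_definitions()))
  expect_true(all(cmp$per_sample$rmse >= 0))
  expect_equal(nrow(cmp$summary), nrow(band_definitions()))
  expect_equal(cmp$summary$delta, cmp$summary$two_layer - cmp$summary$uniform)
  empty <- set
  empty$biochem <- empty$biochem[0, ]
  expect_error(compare_models(empty, cst), class = "leafplates_value_error")
})
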