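#' Invert layer parameters from a measured spectrum
#'
#' Retrieves the two-layer partition (N1, N2, Cab12, Cm12) of one leaf from
#' its measured reflectance by running the NSGA-III optimizer over the
#' unit-box encoding (see [encode_partition()]), with the relative-deviation
#' fitness ([fitness_y()]) as objective.  Biochemistry (Cab, Cw, Cm, N) is a
#' known input, not optimized.  In `mode = "faithful"` the fitness is a
#' single scalar over the full grid; in `mode = "band_split"` it is
#' evaluated separately over the blue-green, yellow-red and near-infrared
#' bands (three objectives) and the reported best individual minimizes
#' their sum.
#'
#' @param measured A [leaf_spectrum()] tibble (or tibble with `wavelength`
#'   and `reflectance`) on the constants grid.
#' @param biochem One-row tibble from [leaf_biochem()].
#' @param constants Optical-constants tibble.
#' @param config A [ga_config()].
#' @param alpha Incidence cone half-angle, degrees.
#' @param mode `"faithful"` (scalar fitness, default) or `"band_split"`.
#' @param sample_id Optional label carried into the result.
#' @return A `leaf_inversion` object: list with `sample_id`, `partition`
#'   (one-row tibble), `fitness`, `rmse` (per-band tibble), `trace`,
#'   `config`, `mode`.  Has [tidy()] and [glance()] methods.
#' @export
invert_sample <- function(measured, biochem, constants, config = ga_config(),
                          alpha = 40, mode = c("faithful", "band_split"),
                          sample_id = "sample") {
  mode <- match.arg(mode)
  constants <- validate_constants(constants)
  measured <- as_tibble(measured)
  if (!isTRUE(all.equal(measured$wavelength, constants$wavelength))) {
    abort("measured spectrum and constants must share one wavelength grid",
          class = "leafplates_grid_error")
  }
  r_meas <- pmax(measured$reflectance, 1e-6)
  sf <- precompute_surface(constants, alpha)
  wl <- constants$wavelength
  bands <- band_definitions()[-1, ]
  band_rows <- purrr::map(seq_len(nrow(bands)),
                          ~ band_mask(wl, bands$lo[.x], bands$hi[.x]))
  M <- if (mode == "faithful") 1L else 3L
  config$n_obj <- M
  objective <- function(X) {
    params <- encode_partition(X, N = biochem$N)
    R <- .forward_two_layer_batch(sf, biochem, params)
    dev <- abs(R - r_meas) / r_meas      # recycles r_meas down columns
    if (M == 1) {
      colSums(dev)
    } else {
      vapply(band_rows, function(kp) colSums(dev[kp, , drop = FALSE]),
             numeric(ncol(dev)))
    }
  }
  run <- nsga3_run(objective, n_var = 4, config = config, vectorized = TRUE)
  partition <- encode_partition(matrix(run$best$x, 1), N = biochem$N)
  modelled <- forward_two_layer(constants, biochem, partition, alpha)
  fit <- fitness_y(modelled$reflectance, r_meas)
  rmse_tbl <- band_definitions() %>%
    mutate(rmse = purrr::map2_dbl(.data$lo, .data$hi,
                                  ~ rmse_spectral(r_meas, modelled$reflectance,
                                                  wl, .x, .y)))
  structure(list(sample_id = sample_id, partition = partition, fitness = fit,
                 rmse = rmse_tbl, trace = run$trace, config = config,
                 mode = mode, modelled = modelled),
            class = "leaf_inversion")
}

#' @export
tidy.leaf_inversion <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = x$sample_id), x$partition)
}

#' @export
glance.leaf_inversion <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$rmse[c("band", "rmse")], names_from = "band",
                             values_from = "rmse", names_prefix = "rmse_")
  dplyr::bind_cols(tibble(sample_id = x$sample_id, fitness = x$fitness), wide)
}

#' @export
print.leaf_inversion <- function(x, ...) {
  cat("Two-layer inversion of", x$sample_id, "\n")
  cat("  fitness y =", format(x$fitness, digits = 6),
      "(mean relative error", sprintf("%.2f%%)", 100 * x$fitness / nrow(x$modelled)), "\n")
  print(x$partition)
  invisible(x)
}

#' @export
autoplot.leaf_inversion <- function(object, ...) {
  df <- tibble(generation = seq_along(object$trace), best_fitness = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$generation, .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "generation", y = "best fitness y") +
    ggplot2::theme_minimal()
}

#' Invert every sample of a spectra set
#'
#' Runs [invert_sample()] over all samples of a [simulate_cohort()] /
#' [read_spectra_set()] object.  Each sample gets its own deterministic
#' seed derived from `config$seed` and the sample index, so the whole
#' cohort inversion is reproducible.
#'
#' @param spectra_set A `spectra_set` object.
#' @param constants Optical-constants tibble.
#' @param config A [ga_config()].
#' @inheritParams invert_sample
#' @return List of class `cohort_inversion` with `results` (one row per
#'   sample: retrieved parameters, fitness, per-band relative RMSE) and
#'   `inversions` (the individual `leaf_inversion` objects).
#' @export
invert_cohort <- function(spectra_set, constants, config = ga_config(),
                          alpha = 40, mode = "faithful") {
  ids <- spectra_set$biochem$sample_id
  inversions <- purrr::map(seq_along(ids), function(i) {
    cfg <- config
    cfg$seed <- (config$seed + 7919L * i) %% .Machine$integer.max
    measured <- tibble(wavelength = spectra_set$spectra$wavelength,
                       reflectance = spectra_set$spectra[[ids[i]]])
    invert_sample(measured, spectra_set$biochem[i, ], constants, cfg,
                  alpha = alpha, mode = mode, sample_id = ids[i])
  })
  results <- purrr::map_dfr(inversions, function(iv) {
    dplyr::bind_cols(tidy(iv), glance(iv)[-1])
  })
  if ("period" %in% names(spectra_set$biochem)) {
    results <- left_join(results,
                         spectra_set$biochem[c("sample_id", "period")],
                         by = "sample_id")
  }
  structure(list(results = results, inversions = inversions, config = config),
            class = "cohort_inversion")
}

#' Fit the uniform-leaf baseline to a measured spectrum
#'
#' For fairness the baseline structure parameter N is optimized over
#' `[1, 3]` with the same optimizer and fitness as the two-layer inversion.
#'
#' @inheritParams invert_sample
#' @return List with `N`, `fitness`, `rmse` (per-band tibble), `modelled`.
#' @export
fit_uniform_baseline <- function(measured, biochem, constants,
                                 config = ga_config(), alpha = 40) {
  constants <- validate_constants(constants)
  measured <- as_tibble(measured)
  r_meas <- pmax(measured$reflectance, 1e-6)
  sf <- precompute_surface(constants, alpha)
  config$n_obj <- 1L
  objective <- function(X) {
    N <- 1 + 2 * X[, 1]
    R <- .forward_uniform_batch(sf, biochem, list(N = N))
    colSums(abs(R - r_meas) / r_meas)
  }
  run <- nsga3_run(objective, n_var = 1, config = config, vectorized = TRUE)
  N_hat <- 1 + 2 * run$best$x[1]
  bio <- biochem
  bio$N <- N_hat
  modelled <- forward_uniform(constants, bio, alpha)
  wl <- constants$wavelength
  rmse_tbl <- band_definitions() %>%
    mutate(rmse = purrr::map2_dbl(.data$lo, .data$hi,
                                  ~ rmse_spectral(r_meas, modelled$reflectance,
                                                  wl, .x, .y)))
  list(N = N_hat, fitness = run$best$scalar, rmse = rmse_tbl, modelled = modelled)
}

#' Compare the two-layer model against the uniform baseline
#'
#' Inverts every sample with the two-layer model and fits the uniform
#' baseline to the same spectra, then tabulates per-band relative RMSE for
#' both models and their difference.
#'
#' @inheritParams invert_cohort
#' @return List of class `model_comparison` with `per_sample` (long tibble:
#'   sample, band, model, rmse), `summary` (per band: mean RMSE of each
#'   model and mean delta = two_layer - uniform), and `two_layer` (the
#'   [invert_cohort()] result).
#' @export
compare_models <- function(spectra_set, constants, config = ga_config(),
                           alpha = 40) {
  ids <- spectra_set$biochem$sample_id
  if (length(ids) == 0) abort("empty sample set", class = "leafplates_value_error")
  two <- invert_cohort(spectra_set, constants, config, alpha)
  base <- purrr::map(seq_along(ids), function(i) {
    cfg <- config
    cfg$seed <- (config$seed + 104729L * i) %% .Machine$integer.max
    measured <- tibble(wavelength = spectra_set$spectra$wavelength,
                       reflectance = spectra_set$spectra[[ids[i]]])
    fit_uniform_baseline(measured, spectra_set$biochem[i, ], constants, cfg, alpha)
  })
  per_sample <- dplyr::bind_rows(
    purrr::map_dfr(two$inversions, function(iv) {
      mutate(iv$rmse[c("band", "rmse")], sample_id = iv$sample_id,
             model = "two_layer")
    }),
    purrr::map_dfr(seq_along(base), function(i) {
      mutate(base[[i]]$rmse[c("band", "rmse")], sample_id = ids[i],
             model = "uniform")
    })
  )
  summary <- per_sample %>%
    group_by(.data$band, .data$model) %>%
    summarise(mean_rmse = mean(.data$rmse), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "model", values_from = "mean_rmse") %>%
    mutate(delta = .data$two_layer - .data$uniform)
  structure(list(per_sample = per_sample, summary = summary, two_layer = two,
                 baseline = base),
            class = "model_comparison")
}

#' @export
autoplot.model_comparison <- function(object, ...) {
  ggplot2::ggplot(object$per_sample,
                  ggplot2::aes(.data$band, .data$rmse, fill = .data$model)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "relative RMSE") +
    ggplot2::theme_minimal()
}
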