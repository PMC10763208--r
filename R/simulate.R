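# Synthetic cohort generation: biochemistry drawn per growth period from
# the observed min-max envelopes, two-layer partitions from the search
# bounds, spectra from the forward model plus additive Gaussian noise.

#' Default per-period biochemistry envelopes
#'
#' Observed min-max ranges of rice leaf biochemistry per growth period
#' (chlorophyll in ug cm^-2, water and dry matter in g cm^-2), with the
#' study's per-period sample counts.
#'
#' @return Tibble with one row per growth period.
#' @export
default_periods <- function() {
  tibble(
    period = c("tillering", "jointing", "heading", "grouting"),
    n = c(38L, 60L, 60L, 60L),
    Cab_min = c(6.1493, 6.2138, 8.6600, 7.5908),
    Cab_max = c(110.6944, 57.9034, 61.8711, 57.6898),
    Cw_min = c(0.0024, 0.0038, 0.0042, 0.0036),
    Cw_max = c(0.0596, 0.1498, 0.0203, 0.0169),
    Cm_min = c(0.0013, 0.0022, 0.0026, 0.0023),
    Cm_max = c(0.0131, 0.0130, 0.0129, 0.0073)
  )
}

#' Default two-layer partition envelopes
#'
#' Ranges from which ground-truth partitions are drawn: the N1/N2 bounds of
#' the search-space encoding (N1 in [2, 2.01], N2 in [0.1, 3] for N = 1)
#' and the observed envelopes of the constituent fractions.
#'
#' @return One-row tibble of min/max pairs.
#' @export
default_partition_ranges <- function() {
  tibble(N1_min = 2, N1_max = 2.01, N2_min = 0.1, N2_max = 3,
         Cab12_min = 0.1157, Cab12_max = 1, Cm12_min = 0, Cm12_max = 1)
}

#' Cohort specification
#'
#' Bundles everything the simulator needs: per-period sample counts and
#' biochemistry ranges, partition ranges, additive reflectance noise and
#' seed.  Defaults emulate the study conditions (218 samples over four
#' growth periods, 1 nm grid, noise_sd 0.01 reflectance units).
#'
#' @param periods Tibble as [default_periods()]; shrink `n` for quick runs.
#' @param partition_ranges Tibble as [default_partition_ranges()].
#' @param noise_sd Additive Gaussian reflectance noise, `>= 0`.
#' @param alpha Incidence cone half-angle for the forward model, degrees.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(periods = default_periods(),
                        partition_ranges = default_partition_ranges(),
                        noise_sd = 0.01, alpha = 40, seed = 1) {
  stopifnot(noise_sd >= 0, all(periods$n >= 0))
  structure(list(periods = periods, partition_ranges = partition_ranges,
                 noise_sd = noise_sd, alpha = alpha, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a spectra cohort
#'
#' Draws biochemistry uniformly within per-period ranges and partitions
#' within their envelopes, runs the two-layer forward model, adds iid
#' Gaussian noise (sd = `noise_sd`), clips to `[0, 1]`, and stores the
#' ground truth.  Fully deterministic given `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @param constants Optical-constants tibble.
#' @return A `spectra_set`: list with `spectra` (wide tibble: `wavelength`
#'   plus one column per sample), `biochem`, `truth`, `noise_sd`, `alpha`,
#'   `seed`.
#' @export
simulate_cohort <- function(spec, constants) {
  constants <- validate_constants(constants)
  set.seed(spec$seed)
  pr <- spec$partition_ranges
  draws <- purrr::map_dfr(seq_len(nrow(spec$periods)), function(i) {
    p <- spec$periods[i, ]
    if (p$n == 0) return(tibble())
    tibble(
      period = p$period,
      N = 1,
      Cab = runif(p$n, p$Cab_min, p$Cab_max),
      Cw = runif(p$n, p$Cw_min, p$Cw_max),
      Cm = runif(p$n, p$Cm_min, p$Cm_max),
      N1 = runif(p$n, pr$N1_min, pr$N1_max),
      N2 = runif(p$n, pr$N2_min, pr$N2_max),
      Cab12 = runif(p$n, pr$Cab12_min, pr$Cab12_max),
      Cm12 = runif(p$n, pr$Cm12_min, pr$Cm12_max),
      Cw12 = 1
    )
  })
  n_total <- nrow(draws)
  draws$sample_id <- sprintf("S%03d", seq_len(n_total))
  spectra <- tibble(wavelength = constants$wavelength)
  for (i in seq_len(n_total)) {
    d <- draws[i, ]
    spec_i <- forward_two_layer(constants, d[c("N", "Cab", "Cw", "Cm")],
                                d[c("N1", "N2", "Cab12", "Cm12", "Cw12")],
                                alpha = spec$alpha)
    r <- spec_i$reflectance
    if (spec$noise_sd > 0) {
      r <- pmin(pmax(r + rnorm(length(r), 0, spec$noise_sd), 0), 1)
    }
    spectra[[d$sample_id]] <- r
  }
  structure(list(
    spectra = spectra,
    biochem = draws[c("sample_id", "period", "N", "Cab", "Cw", "Cm")],
    truth = draws[c("sample_id", "N1", "N2", "Cab12", "Cm12", "Cw12")],
    noise_sd = spec$noise_sd, alpha = spec$alpha, seed = spec$seed
  ), class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat("spectra_set:", ncol(x$spectra) - 1, "samples x", nrow(x$spectra),
      "bands (noise sd", x$noise_sd, ", seed", x$seed, ")\n")
  invisible(x)
}

#' @export
autoplot.spectra_set <- function(object, ...) {
  long <- tidyr::pivot_longer(object$spectra, -"wavelength",
                              names_to = "sample_id", values_to = "reflectance")
  ggplot2::ggplot(long, ggplot2::aes(.data$wavelength, .data$reflectance,
                                     group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "wavelength (nm)", y = "reflectance") +
    ggplot2::theme_minimal()
}

#' Read and write spectra sets
#'
#' A spectra set is stored as a directory of plain CSV files:
#' `spectra.csv` (wavelength plus one column per sample), `biochem.csv`,
#' optionally `truth.csv`, and `meta.yaml` (noise sd, alpha, seed).  The
#' round trip is lossless to full double precision.
#'
#' @param spectra_set A `spectra_set` object.
#' @param dir Directory path.
#' @return `read_spectra_set()` returns a `spectra_set`.
#' @export
write_spectra_set <- function(spectra_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # readr writes shortest round-trip doubles, so the csv is lossless
  wr <- function(df, f) readr::write_csv(df, file.path(dir, f))
  wr(spectra_set$spectra, "spectra.csv")
  wr(spectra_set$biochem, "biochem.csv")
  if (!is.null(spectra_set$truth)) wr(spectra_set$truth, "truth.csv")
  yaml::write_yaml(list(noise_sd = spectra_set$noise_sd,
                        alpha = spectra_set$alpha,
                        seed = spectra_set$seed),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' @rdname write_spectra_set
#' @export
read_spectra_set <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  spectra <- rd("spectra.csv")
  biochem <- rd("biochem.csv")
  ids <- setdiff(names(spectra), "wavelength")
  if (!setequal(ids, biochem$sample_id)) {
    abort("spectra columns and biochemistry sample ids do not match",
          class = "leafplates_format_error")
  }
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path)) rd("truth.csv") else NULL
  meta_path <- file.path(dir, "meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  structure(list(spectra = spectra, biochem = biochem, truth = truth,
                 noise_sd = meta$noise_sd %||% NA_real_,
                 alpha = meta$alpha %||% 40,
                 seed = meta$seed %||% NA_integer_),
            class = "spectra_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
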