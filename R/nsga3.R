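# In-package NSGA-III: fast non-dominated sorting, Das-Dennis reference
# points, adaptive normalization with achievement-scalarizing extreme
# points, niche-preserving selection, SBX crossover and polynomial
# mutation.  Minimization throughout; decision space is the unit box.

#' Fast non-dominated sorting
#'
#' Partitions a population into Pareto fronts (minimization): front 1 is
#' the non-dominated set, front 2 the non-dominated set of the remainder,
#' and so on.  Every individual appears in exactly one front.
#'
#' @param objectives Numeric matrix, one row per individual, one column per
#'   objective (a vector is treated as a single objective).
#' @return List of integer vectors of row indices, best front first.
#' @export
fast_nondominated_sort <- function(objectives) {
  F <- as.matrix(objectives)
  n <- nrow(F)
  if (n == 0) abort("empty population", class = "leafplates_value_error")
  M <- ncol(F)
  # dom[i, j]: i dominates j
  dom <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    le <- rep(TRUE, n)
    lt <- rep(FALSE, n)
    for (k in seq_len(M)) {
      le <- le & (F[i, k] <= F[, k])
      lt <- lt | (F[i, k] < F[, k])
    }
    dom[i, ] <- le & lt
  }
  n_dominators <- colSums(dom)
  fronts <- list()
  alive <- rep(TRUE, n)
  while (any(alive)) {
    front <- which(alive & n_dominators == 0)
    fronts[[length(fronts) + 1]] <- front
    alive[front] <- FALSE
    if (length(front) > 0) {
      n_dominators <- n_dominators - colSums(dom[front, , drop = FALSE])
    }
  }
  fronts
}

#' Structured reference points on the unit simplex
#'
#' Das-Dennis simplex-lattice points with denominator `p`: all nonnegative
#' M-vectors with entries in {0, 1/p, ..., 1} summing to 1.  There are
#' `choose(M + p - 1, p)` of them.
#'
#' @param M Number of objectives, `>= 1`.
#' @param p Number of divisions, `>= 1`.
#' @return Matrix with one reference point per row.
#' @export
generate_reference_points <- function(M, p) {
  stopifnot(M >= 1, p >= 1)
  if (M == 1) return(matrix(1, 1, 1))
  rec <- function(left, dims) {
    if (dims == 1) return(matrix(left, 1, 1))
    do.call(rbind, lapply(0:left, function(i) {
      rest <- rec(left - i, dims - 1)
      cbind(i, rest, deparse.level = 0)
    }))
  }
  rec(p, M) / p
}

#' Adaptive normalization of a population's objectives
#'
#' Translates objectives by the running ideal point (per-axis minima) and
#' scales each axis by the intercept of the hyperplane through the extreme
#' points, selected by an achievement-scalarizing function.  Degenerate
#' extreme-point systems (singular or with nonpositive intercepts) fall
#' back to the per-axis maxima; an all-identical population falls back to
#' unit intercepts with a warning.
#'
#' @param objectives Numeric matrix (rows = individuals).
#' @param state Optional previous normalization state (to carry the running
#'   ideal point across generations).
#' @return List with `objectives` (normalized matrix) and `state`
#'   (`ideal`, `intercepts`).
#' @export
adaptive_normalize <- function(objectives, state = NULL) {
  F <- as.matrix(objectives)
  M <- ncol(F)
  ideal <- apply(F, 2, min)
  if (!is.null(state)) ideal <- pmin(ideal, state$ideal)
  F1 <- sweep(F, 2, ideal)
  span <- apply(F1, 2, max)
  if (M == 1) {
    a <- max(span, .Machine$double.eps)
  } else if (all(span <= 0)) {
    warn("all individuals identical: unit intercepts used for normalization")
    a <- rep(1, M)
  } else {
    extremes <- matrix(0, M, M)
    for (i in seq_len(M)) {
      wvec <- rep(1e-6, M)
      wvec[i] <- 1
      asf <- apply(sweep(F1, 2, wvec, "/"), 1, max)
      extremes[i, ] <- F1[which.min(asf), ]
    }
    a <- tryCatch({
      plane <- solve(extremes, rep(1, M))
      ai <- 1 / plane
      if (any(!is.finite(ai)) || any(ai <= 1e-12)) stop("degenerate")
      ai
    }, error = function(e) pmax(span, .Machine$double.eps))
  }
  list(objectives = sweep(F1, 2, a, "/"), state = list(ideal = ideal, intercepts = a))
}

# perpendicular distance of each row of F (normalized) to each reference line
perpendicular_distances <- function(F, refs) {
  Rn <- refs / sqrt(rowSums(refs^2))
  proj <- F %*% t(Rn)                      # scalar projections
  d2 <- matrix(rowSums(F^2), nrow(F), nrow(refs)) - proj^2
  sqrt(pmax(d2, 0))
}

#' Niche-preserving selection from the last front
#'
#' Given the members already accepted (fronts 1..l-1) and the partially
#' accepted last front, associates every individual with its nearest
#' reference line in normalized objective space and repeatedly fills the
#' least-crowded niche with its closest remaining candidate (ties between
#' equally crowded niches broken through the ambient RNG stream).
#'
#' @param norm_objectives Normalized objective matrix for all of S_t.
#' @param accepted Row indices already accepted.
#' @param last_front Row indices of the last (partial) front.
#' @param K Number to select from `last_front`.
#' @param refs Reference-point matrix from [generate_reference_points()].
#' @return Integer vector of `K` selected indices from `last_front`.
#' @export
niche_select <- function(norm_objectives, accepted, last_front, K, refs) {
  if (K > length(last_front)) {
    abort("cannot select more individuals than the last front holds",
          class = "leafplates_value_error")
  }
  if (K == length(last_front)) return(last_front)
  if (K == 0) return(integer(0))
  F <- as.matrix(norm_objectives)
  d <- perpendicular_distances(F, as.matrix(refs))
  assign_ref <- max.col(-d, ties.method = "first")
  assign_dist <- d[cbind(seq_len(nrow(F)), assign_ref)]
  rho <- tabulate(assign_ref[accepted], nbins = nrow(refs))
  candidates <- last_front
  chosen <- integer(0)
  while (length(chosen) < K) {
    cand_refs <- unique(assign_ref[candidates])
    jmin <- cand_refs[rho[cand_refs] == min(rho[cand_refs])]
    if (length(jmin) > 1) jmin <- jmin[sample.int(length(jmin), 1)] else jmin <- jmin[1]
    members <- candidates[assign_ref[candidates] == jmin]
    pick <- members[which.min(assign_dist[members])]
    chosen <- c(chosen, pick)
    candidates <- setdiff(candidates, pick)
    rho[jmin] <- rho[jmin] + 1
  }
  chosen
}

#' Optimizer configuration
#'
#' Canonical NSGA-III settings: simulated-binary crossover with
#' distribution index `eta_c = 30`, polynomial mutation with `eta_m = 20`
#' and per-variable probability `1/d`, population 100, 200 generations.
#' `n_obj = 1` is the faithful scalar-fitness mode in which NSGA-III
#' degenerates to elitist rank selection; `n_obj = 3` with `divisions = 12`
#' is the band-split mode.
#'
#' @param pop_size Even population size.
#' @param generations Number of generations (`0` evaluates only the initial
#'   population).
#' @param n_obj Number of objectives M.
#' @param eta_c,eta_m SBX / polynomial-mutation distribution indices.
#' @param p_mut Per-variable mutation probability (`NULL` = `1/d`).
#' @param divisions Reference-point divisions p (`NULL`: 12 for M >= 2).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @return A `ga_config` list.
#' @export
ga_config <- function(pop_size = 100, generations = 200, n_obj = 1,
                      eta_c = 30, eta_m = 20, p_mut = NULL,
                      divisions = NULL, seed = 1) {
  stopifnot(pop_size > 0, pop_size %% 2 == 0, generations >= 0, n_obj >= 1)
  structure(list(pop_size = pop_size, generations = generations, n_obj = n_obj,
                 eta_c = eta_c, eta_m = eta_m, p_mut = p_mut,
                 divisions = if (is.null(divisions)) 12 else divisions,
                 seed = as.integer(seed)),
            class = "ga_config")
}

# SBX crossover on [0,1]^d, vectorized over a whole mating pool
sbx_crossover <- function(X, eta_c, p_cross = 0.9) {
  n <- nrow(X)
  d <- ncol(X)
  half <- n %/% 2
  P1 <- X[seq_len(half), , drop = FALSE]
  P2 <- X[half + seq_len(half), , drop = FALSE]
  u <- matrix(runif(half * d), half, d)
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta_c + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta_c + 1)))
  # apply per pair with prob p_cross, per variable with prob 0.5
  do_pair <- matrix(runif(half) <= p_cross, half, d)
  do_var <- matrix(runif(half * d) <= 0.5, half, d)
  beta[!(do_pair & do_var)] <- 1
  C1 <- 0.5 * ((1 + beta) * P1 + (1 - beta) * P2)
  C2 <- 0.5 * ((1 - beta) * P1 + (1 + beta) * P2)
  Y <- rbind(C1, C2)
  pmin(pmax(Y, 0), 1)
}

# polynomial mutation on [0,1]^d
poly_mutate <- function(X, eta_m, p_mut) {
  n <- nrow(X)
  d <- ncol(X)
  do <- matrix(runif(n * d) <= p_mut, n, d)
  u <- matrix(runif(n * d), n, d)
  x <- X
  lo <- 0; hi <- 1
  d1 <- (x - lo) / (hi - lo)
  d2 <- (hi - x) / (hi - lo)
  pw <- 1 / (eta_m + 1)
  dq <- ifelse(u <= 0.5,
               (2 * u + (1 - 2 * u) * (1 - d1)^(eta_m + 1))^pw - 1,
               1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta_m + 1))^pw)
  x[do] <- (x + dq * (hi - lo))[do]
  pmin(pmax(x, 0), 1)
}

# environmental selection: pick pop_size from the combined population
environmental_select <- function(FR, pop_size, refs, norm_state) {
  fronts <- fast_nondominated_sort(FR)
  accepted <- integer(0)
  l <- 0
  while (length(accepted) < pop_size) {
    l <- l + 1
    if (length(accepted) + length(fronts[[l]]) <= pop_size) {
      accepted <- c(accepted, fronts[[l]])
    } else break
  }
  if (length(accepted) < pop_size) {
    last <- fronts[[l]]
    K <- pop_size - length(accepted)
    st <- c(accepted, last)
    nm <- adaptive_normalize(FR[st, , drop = FALSE], norm_state)
    norm_state <- nm$state
    # indices within st
    sel_local <- niche_select(nm$objectives,
                              accepted = seq_along(accepted),
                              last_front = length(accepted) + seq_along(last),
                              K = K, refs = refs)
    accepted <- c(accepted, st[sel_local])
  }
  list(idx = accepted, state = norm_state)
}

#' Run the NSGA-III optimizer
#'
#' Elitist (mu + lambda) generational loop on the unit box: random
#' initialization, SBX crossover and polynomial mutation, then
#' environmental selection by non-dominated sorting plus niche-preserving
#' truncation of the last front.  Non-finite objective values are penalized
#' with `+Inf`.  The entire run is reproducible from `config$seed`.
#'
#' @param fn Objective function.  With `vectorized = TRUE` (default) it
#'   receives a `pop_size x d` matrix and must return a `pop_size x M`
#'   matrix (or vector for M = 1); otherwise it maps one parameter vector
#'   to an M-vector.
#' @param n_var Number of decision variables d.
#' @param config A [ga_config()].
#' @param vectorized Whether `fn` is batched.
#' @return List with `x` (final decision matrix), `objectives`, `best`
#'   (list with `x`, `objectives`, `scalar` — scalar is the objective sum),
#'   and `trace` (per-generation best scalar).
#' @export
nsga3_run <- function(fn, n_var, config = ga_config(), vectorized = TRUE) {
  stopifnot(n_var >= 1)
  M <- config$n_obj
  evaluate <- function(X) {
    F <- if (vectorized) fn(X) else t(apply(X, 1, fn))
    F <- matrix(as.numeric(F), nrow = nrow(X), ncol = M)
    bad <- !is.finite(F)
    if (any(bad)) F[bad] <- Inf
    F
  }
  set.seed(config$seed)
  N <- config$pop_size
  p_mut <- if (is.null(config$p_mut)) 1 / n_var else config$p_mut
  refs <- generate_reference_points(M, config$divisions)
  X <- matrix(runif(N * n_var), N, n_var)
  F <- evaluate(X)
  norm_state <- NULL
  trace <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    mates <- X[sample.int(N), , drop = FALSE]
    Y <- poly_mutate(sbx_crossover(mates, config$eta_c), config$eta_m, p_mut)
    FY <- evaluate(Y)
    XR <- rbind(X, Y)
    FR <- rbind(F, FY)
    sel <- environmental_select(FR, N, refs, norm_state)
    norm_state <- sel$state
    X <- XR[sel$idx, , drop = FALSE]
    F <- FR[sel$idx, , drop = FALSE]
    trace[g] <- min(rowSums(F))
  }
  scalar <- rowSums(F)
  b <- which.min(scalar)
  list(x = X, objectives = F,
       best = list(x = X[b, ], objectives = F[b, ], scalar = scalar[b]),
       trace = trace)
}

#' Decode a unit-box vector into a layer partition
#'
#' The search-space encoding of the two-layer inversion:
#' `N1 = N (2 + 0.01 x1)`, `N2 = N (0.1 + 2.9 x2)`, `Cab12 = x3`,
#' `Cm12 = x4`, with water fixed in the upper layer (`Cw12 = 1`).
#'
#' @param x Numeric vector (or 4-column matrix) in `[0, 1]^4`.
#' @param N Whole-leaf structure parameter (default 1).
#' @return A [layer_partition()] tibble (one row per candidate).
#' @export
encode_partition <- function(x, N = 1) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  stopifnot(ncol(X) == 4, all(X >= 0 & X <= 1))
  tibble(N1 = N * (2 + 0.01 * X[, 1]),
         N2 = N * (0.1 + 2.9 * X[, 2]),
         Cab12 = X[, 3], Cm12 = X[, 4], Cw12 = 1)
}

#' Relative-deviation fitness between spectra
#'
#' Sum over the spectral grid of the absolute relative deviation of the
#' modelled from the measured reflectance,
#' `y = sum_l |R_mod(l) - R_meas(l)| / R_meas(l)`.  A value of 6.01 on the
#' 601-band grid corresponds to a mean relative error of 1%.  Measured
#' reflectance at or below zero is floored at `1e-6` with a warning.
#'
#' @param r_mod,r_meas Reflectance vectors on a common grid (or
#'   [leaf_spectrum()] tibbles).
#' @return Nonnegative scalar; `0` iff identical.
#' @export
fitness_y <- function(r_mod, r_meas) {
  if (is.data.frame(r_mod)) r_mod <- r_mod$reflectance
  if (is.data.frame(r_meas)) r_meas <- r_meas$reflectance
  stopifnot(length(r_mod) == length(r_meas))
  if (any(r_meas <= 0)) {
    warn("measured reflectance <= 0 floored at 1e-6 in fitness")
    r_meas <- pmax(r_meas, 1e-6)
  }
  sum(abs(r_mod - r_meas) / r_meas)
}
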