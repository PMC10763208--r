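test_that("non-dominated sorting matches the brute-force dominance oracle", {
  # hand-checkable case
  F <- rbind(c(1, 2), c(2, 1), c(3, 3))
  fronts <- fast_nondominated_sort(F)
  expect_equal(fronts, list(c(1L, 2L), 3L))
  # all identical: one front
  Fi <- matrix(1, 5, 3)
  expect_equal(fast_nondominated_sort(Fi), list(1:5))
  expect_error(fast_nondominated_sort(matrix(numeric(0), 0, 2)),
               class = "leafplates_value_error")
  # randomized cross-check
  set.seed(81)
  for (i in 1:20) {
    F <- matrix(runif(150), 50, 3)
    fronts <- fast_nondominated_sort(F)
    rank <- integer(50)
    for (l in seq_along(fronts)) rank[fronts[[l]]] <- l
    expect_equal(rank, oracle_sort(F))
    expect_equal(sort(unlist(fronts)), 1:50)
  }
})

test_that("reference points enumerate the simplex lattice", {
  rp <- generate_reference_points(2, 4)
  expect_equal(nrow(rp), 5)
  expect_equal(sort(rp[, 1]), c(0, 0.25, 0.5, 0.75, 1))
  expect_true(all(abs(rowSums(rp) - 1) < 1e-12))
  rp3 <- generate_reference_points(3, 12)
  expect_equal(nrow(rp3), choose(14, 12))
  expect_true(all(abs(rowSums(rp3) - 1) < 1e-12))
  expect_true(all(rp3 >= 0))
  for (cfg in list(c(2, 4), c(3, 5), c(4, 6))) {
    expect_equal(nrow(generate_reference_points(cfg[1], cfg[2])),
                 choose(cfg[1] + cfg[2] - 1, cfg[2]))
  }
})

test_that("adaptive normalization places the ideal at the origin and the intercepts on the unit simplex", {
  # already normalized population is unchanged
  F <- rbind(diag(3), c(0.2, 0.3, 0.4))
  nm <- adaptive_normalize(F)
  expect_equal(nm$state$ideal, rep(0, 3))
  expect_equal(nm$objectives, F)
  # translation is absorbed into the ideal point
  shift <- c(5, -2, 7)
  nm2 <- adaptive_normalize(sweep(F, 2, shift, "+"))
  expect_equal(nm2$state$ideal, shift)
  expect_equal(nm2$objectives, F)
  # random population: recomputed intercept points satisfy sum(f_n) = 1
  set.seed(91)
  for (i in 1:10) {
    Fr <- matrix(rexp(60), 20, 3)
    nmr <- adaptive_normalize(Fr)
    a <- nmr$state$intercepts
    ideal <- nmr$state$ideal
    intercept_points <- diag(a)
    normalized <- sweep(intercept_points, 2, a, "/")
    expect_true(all(abs(rowSums(normalized) - 1) < 1e-9))
    expect_true(all(apply(nmr$objectives, 2, min) >= -1e-12))
  }
  expect_warning(adaptive_normalize(matrix(1, 4, 2)), "identical")
})

test_that("niche selection is deterministic under a fixed seed and handles degenerate cases", {
  set.seed(101)
  F <- matrix(runif(60), 20, 3)
  nm <- adaptive_normalize(F)
  refs <- generate_reference_points(3, 4)
  # K equal to the whole front: everything selected
  expect_equal(niche_select(nm$objectives, integer(0), 1:20, 20, refs), 1:20)
  # single reference point: the K smallest perpendicular distances win
  one_ref <- matrix(1 / 3, 1, 3)
  d <- sqrt(rowSums(F^2) - (F %*% rep(1 / sqrt(3), 3))^2)
  got <- niche_select(F, integer(0), 1:20, 5, one_ref)
  expect_setequal(got, order(d)[1:5])
  expect_error(niche_select(nm$objectives, integer(0), 1:5, 6, refs),
               class = "leafplates_value_error")
  # reproducibility of the randomized tie-breaks
  pick <- function() {
    set.seed(7)
    niche_select(nm$objectives, 1:8, 9:20, 6, refs)
  }
  expect_identical(pick(), pick())
})

test_that("the optimizer recovers a separable optimum, respects population size, and is bit-reproducible", {
  sphere <- function(X) rowSums((X - 0.3)^2)
  cfg <- ga_config(pop_size = 40, generations = 100, seed = 5)
  run <- nsga3_run(sphere, n_var = 4, config = cfg)
  expect_lt(run$best$scalar, 1e-3)
  expect_equal(dim(run$x), c(40, 4))
  expect_equal(length(run$trace), 100)
  # trace of the best fitness never worsens (elitism)
  expect_true(all(diff(run$trace) <= 1e-12))
  run2 <- nsga3_run(sphere, n_var = 4, config = cfg)
  expect_identical(run, run2)
  # zero generations evaluates the initial population only
  run0 <- nsga3_run(sphere, n_var = 4,
                    config = ga_config(pop_size = 40, generations = 0, seed = 5))
  set.seed(5)
  X0 <- matrix(runif(40 * 4), 40, 4)
  expect_equal(run0$x, X0)
  expect_equal(run0$best$scalar, min(sphere(X0)))
  # error recovery improves with generations (median over seeds)
  errs <- sapply(1:5, function(s) {
    short <- nsga3_run(sphere, n_var = 4,
                       config = ga_config(pop_size = 20, generations = 10, seed = s))
    long <- nsga3_run(sphere, n_var = 4,
                      config = ga_config(pop_size = 20, generations = 60, seed = s))
    c(short$best$scalar, long$best$scalar)
  })
  expect_lt(median(errs[2, ]), median(errs[1, ]))
})

test_that("multi-objective runs keep population size and dominance consistency", {
  # two conflicting objectives on one variable
  fn <- function(X) cbind(X[, 1]^2, (X[, 1] - 1)^2)
  cfg <- ga_config(pop_size = 20, generations = 30, n_obj = 2, divisions = 10, seed = 9)
  run <- nsga3_run(fn, n_var = 1, config = cfg)
  expect_equal(nrow(run$x), 20)
  # final population should approximate the Pareto set x in [0, 1]
  fronts <- fast_nondominated_sort(run$objectives)
  expect_gt(length(fronts[[1]]), 10)
})

test_that("partition encoding follows the affine search-space mapping", {
  lo <- encode_partition(c(0, 0, 0, 0), N = 1)
  expect_equal(unlist(lo[c("N1", "N2", "Cab12", "Cm12")], use.names = FALSE),
               c(2, 0.1, 0, 0))
  expect_equal(lo$Cw12, 1)
  hi <- encode_partition(c(1, 1, 1, 1), N = 1)
  expect_equal(unlist(hi[c("N1", "N2", "Cab12", "Cm12")], use.names = FALSE),
               c(2.01, 3, 1, 1))
  mid <- encode_partition(rep(0.5, 4), N = 1)
  expect_equal(mid$N1, 2.005)
  expect_equal(mid$N2, 1.55)
  # scales with the whole-leaf structure parameter
  sc <- encode_partition(c(0, 0, 0.5, 0.5), N = 2)
  expect_equal(sc$N1, 4)
  expect_equal(sc$N2, 0.2)
})

test_that("relative-deviation fitness matches its analytic values and the naive loop", {
  r <- runif(601, 0.05, 0.6)
  expect_equal(fitness_y(r, r), 0)
  expect_equal(fitness_y(2 * r, r), 601)
  set.seed(111)
  a <- runif(601, 0.01, 0.9)
  b <- runif(601, 0.01, 0.9)
  expect_lt(abs(fitness_y(a, b) - oracle_fitness(a, b)), 1e-12)
  expect_warning(fitness_y(a, c(0, b[-1])), "floored")
})
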