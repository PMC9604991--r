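# cheap whole-batch settings: 6 regions, short horizon
batch_connectome <- function() synthesize_connectome(6, seed = 4)
batch_params <- function() model_params(G = 2.5, L = 1.5, v = 3.5,
                                        t_total = 12, t_transient = 3)
# bounds wide enough that any dynamics count as feasible (isolates the
# median-FC / correlation logic from the plausibility gate)
open_bounds <- constraint_bounds(mean_R_range = c(-0.1, 1.1),
                                 mean_local_range = c(-0.1, 1.1),
                                 global_meta_min = -1, local_meta_min = -1)

test_that("batches are deterministic and vary only by initial phases", {
  cn <- batch_connectome()
  p <- batch_params()
  b1 <- run_batch(p, cn, n_runs = 3, seed_base = 10)
  b2 <- run_batch(p, cn, n_runs = 3, seed_base = 10)
  expect_equal(b1[[2]]$sfc, b2[[2]]$sfc)
  expect_equal(b1[[3]]$summary$mean_R, b2[[3]]$summary$mean_R)
  # different seeds give different runs
  expect_false(isTRUE(all.equal(b1[[1]]$sfc, b1[[2]]$sfc)))
})

test_that("fast batch path agrees with the trajectory path", {
  cn <- batch_connectome()
  p <- batch_params()
  fast <- run_batch(p, cn, n_runs = 1, seed_base = 2)[[1]]
  full <- run_batch(p, cn, n_runs = 1, seed_base = 2,
                    keep_trajectories = TRUE)[[1]]
  expect_equal(fast$summary$mean_R, full$summary$mean_R)
  expect_equal(fast$summary$local_meta, full$summary$local_meta)
  expect_equal(fast$sfc, full$sfc, tolerance = 1e-3)
  expect_s3_class(full$trajectory, "trajectory")
})

test_that("a batch median compared against itself scores 1 when feasible", {
  cn <- batch_connectome()
  p <- batch_params()
  b <- run_batch(p, cn, n_runs = 3, seed_base = 1)
  med <- apply(vapply(b, `[[`, matrix(0, 6, 6), "sfc"), c(1, 2), median)
  self <- evaluate_fitness(p, cn, med, n_runs = 3, seed_base = 1,
                           bounds = open_bounds)
  expect_true(self$feasible)
  expect_equal(self$score, 1)
  # single-run batch: the median is that run
  one <- run_batch(p, cn, n_runs = 1, seed_base = 1)
  f1 <- evaluate_fitness(p, cn, one[[1]]$sfc, n_runs = 1, seed_base = 1,
                         bounds = open_bounds)
  expect_equal(f1$score, 1)
})

test_that("violated constraint medians are penalized below every correlation", {
  cn <- synthesize_connectome(8, seed = 6)
  # zero delays in the FC-producing coupling range: near-full synchrony,
  # almost no metastability -> several bounds violated
  p <- model_params(G = 3.57, L = 1, v = Inf, t_total = 12, t_transient = 3)
  f <- evaluate_fitness(p, cn, diag(8), n_runs = 3, seed_base = 1)
  expect_false(f$feasible)
  expect_gte(f$violations, 2)
  expect_lte(f$score, -3)
  expect_lt(f$score, -1)   # below any attainable correlation

  # a boundary median is infeasible under strict inequalities: reuse the
  # achieved medians as the bound itself
  g <- evaluate_fitness(p, cn, diag(8), n_runs = 3, seed_base = 1,
                        bounds = constraint_bounds(
                          mean_R_range = c(f$medians[["mean_R"]], 1.1),
                          mean_local_range = c(-0.1, 1.1),
                          global_meta_min = -1, local_meta_min = -1))
  expect_false(g$feasible)
  expect_equal(g$score, -3)
})

test_that("evaluate_fitness checks target dimensions", {
  cn <- batch_connectome()
  expect_error(evaluate_fitness(batch_params(), cn, diag(5), n_runs = 1),
               "6x6")
})
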