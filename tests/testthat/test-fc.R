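test_that("alpha_envelope recovers in-band amplitude and rejects out-of-band", {
  t <- seq(1e-3, 45, by = 1e-3)
  env <- alpha_envelope(sin(2 * pi * 10.5 * t), fs = 1000)
  expect_equal(env$fs_env, 5)
  interior <- env$env[10:(nrow(env$env) - 10), 1]
  expect_true(all(abs(interior - 1) < 0.02))

  env40 <- alpha_envelope(sin(2 * pi * 40 * t), fs = 1000)
  expect_lt(max(env40$env), 0.05)

  expect_equal(max(alpha_envelope(rep(0, 45000), fs = 1000)$env), 0)
  expect_error(alpha_envelope(matrix(rnorm(100), 50), fs = 20), "too low")
})

test_that("alpha_envelope is homogeneous in signal amplitude", {
  set.seed(31)
  x <- matrix(rnorm(20000), ncol = 2)
  a <- alpha_envelope(x, fs = 500)
  b <- alpha_envelope(3 * x, fs = 500)
  expect_equal(b$env, 3 * a$env, tolerance = 1e-10)
})

test_that("static_fc is a Pearson correlation matrix with guards", {
  set.seed(5)
  base <- abs(rnorm(500)) + 1
  env <- cbind(base, base, -base + 10)
  fc <- static_fc(env)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[1, 3], -1)
  expect_equal(diag(fc), rep(1, 3))

  noise <- matrix(rnorm(500 * 4), 500, 4)
  fcn <- static_fc(noise)
  expect_lt(max(abs(fcn[upper.tri(fcn)])), 0.15)

  flat <- cbind(rnorm(100), rep(1, 100))
  expect_error(static_fc(flat), "region 2")
  expect_error(static_fc(matrix(rnorm(8), 4, 2)), "10 envelope samples")
})

test_that("fc_similarity correlates strict upper triangles", {
  set.seed(8)
  A <- cor(matrix(rnorm(68 * 40), 40))
  expect_equal(fc_similarity(A, A), 1)
  expect_equal(fc_similarity(A, -A), -1)
  expect_length(A[upper.tri(A)], 2278)   # 68 regions
  expect_error(fc_similarity(A, diag(3)), "mismatch")
})

test_that("trfc_recurrence yields the expected window combinatorics", {
  set.seed(12)
  env <- structure(list(fs_env = 5,
                        env = matrix(abs(rnorm(1500 * 4)), 1500, 4)),
                   class = "envelope_set")   # 300 s at 5 Hz
  rec <- trfc_recurrence(env, window_s = 15, overlap_s = 12)
  expect_equal(rec$n_windows, 96)
  expect_length(rec$values, 4560)
  expect_true(all(rec$values >= -1 & rec$values <= 1))

  # duplicated stationary blocks give perfect recurrence
  block <- matrix(abs(rnorm(75 * 3)) + 0.5, 75, 3)
  env2 <- structure(list(fs_env = 5, env = do.call(rbind, rep(list(block), 4))),
                    class = "envelope_set")
  rec2 <- trfc_recurrence(env2, window_s = 15, overlap_s = 0)
  expect_equal(rec2$values, rep(1, length(rec2$values)))

  short <- structure(list(fs_env = 5, env = matrix(rnorm(80), 40, 2)),
                     class = "envelope_set")
  expect_error(trfc_recurrence(short), "2 windows")
})

test_that("ks_distance is the two-sample ECDF supremum", {
  expect_equal(ks_distance(1:5, 1:5), 0)
  expect_equal(ks_distance(c(0.1, 0.2), c(5, 6)), 1)
  expect_equal(ks_distance(c(0.1, 0.2, 0.3), c(0.2, 0.3, 0.4)), 1 / 3)
  set.seed(21)
  a <- rnorm(200); b <- rnorm(150, mean = 0.4)
  expect_equal(ks_distance(a, b),
               unname(stats::ks.test(a, b)$statistic))
  expect_equal(ks_distance(a, b), ks_distance(b, a))
  expect_error(ks_distance(numeric(0), 1), "non-empty")
})

test_that("nodal_strength sums off-diagonal connectivity", {
  fc <- matrix(0.5, 3, 3); diag(fc) <- 1
  expect_equal(nodal_strength(fc), rep(1, 3))
  expect_equal(nodal_strength(diag(4)), rep(0, 4))
  set.seed(2)
  m <- cor(matrix(rnorm(200), 20))
  expect_equal(nodal_strength(m), colSums(m) - diag(m))
})

test_that("the pipeline discriminates parameter regimes better than seeds", {
  cn <- synthesize_connectome(6, seed = 4)
  pA <- model_params(G = 2.5, L = 1.5, v = 3.5, t_total = 20, t_transient = 4)
  pB <- model_params(G = 0.5, L = 4,   v = 3.5, t_total = 20, t_transient = 4)
  a1 <- run_batch(pA, cn, 1, seed_base = 1)[[1]]$sfc
  a2 <- run_batch(pA, cn, 1, seed_base = 2)[[1]]$sfc
  b1 <- run_batch(pB, cn, 1, seed_base = 1)[[1]]$sfc
  expect_gt(fc_similarity(a1, a2), fc_similarity(a1, b1))
})
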