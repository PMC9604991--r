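test_that("ensemble_equilibrium follows the closed form with clamping", {
  expect_equal(ensemble_equilibrium(4, 1), sqrt(0.5))
  expect_equal(ensemble_equilibrium(2, 1), 0)
  expect_equal(ensemble_equilibrium(1, 1), 0)
  expect_equal(ensemble_equilibrium(-3, 1), 0)
  expect_error(ensemble_equilibrium(4, 0), "Delta")
})

test_that("the right-hand side matches hand-computed derivatives", {
  # isolated ensemble: local terms only
  d <- oa_rhs(r = 0.5, psi = 0, delayed_z = matrix(0.5 + 0i, 1, 1),
              A = matrix(0, 1, 1), G = 0, L = 4, Delta = 1)
  expect_equal(d$dr, 0.25)
  expect_equal(d$dpsi, 2 * pi * 10.5)

  # two coupled ensembles, equal phases, zero delay
  z <- matrix(complex(modulus = 0.5, argument = 0), 2, 2)
  d2 <- oa_rhs(r = c(0.5, 0.5), psi = c(0, 0), delayed_z = z,
               A = matrix(c(0, 1, 1, 0), 2, 2), G = 2, L = c(4, 4),
               Delta = 1)
  expect_equal(d2$dr[1], 0.4375)
  expect_equal(d2$dpsi[1], 2 * pi * 10.5)   # sin(0) = 0
})

test_that("the Euler integrator reproduces single-step and fixed-point behavior", {
  cn <- single_connectome()
  p1 <- model_params(G = 0, L = 0, Delta = 1, dt = 1e-3,
                     t_total = 1e-3, t_transient = 0)
  tr <- integrate_model(p1, cn, r_init = 0.5, psi_init = 0)
  expect_equal(tr$r[2, 1], 0.4995)

  p2 <- model_params(G = 0, L = 4, Delta = 1, t_total = 10, t_transient = 0)
  tr2 <- integrate_model(p2, cn, r_init = sqrt(0.5), psi_init = 0)
  expect_lt(max(abs(tr2$r - sqrt(0.5))), 1e-4)

  expect_true(all(tr2$r >= p2$r_floor & tr2$r <= 1))
  expect_true(all(tr2$psi >= -pi & tr2$psi < pi))
})

test_that("one compiled step equals the reference right-hand side", {
  cn <- pair_connectome(d_mm = 3.42)        # 1 ms delay at 3.42 m/s
  p <- model_params(G = 2.5, L = c(1, 3), Delta = 1, v = 3.42,
                    dt = 1e-3, t_total = 0.001, t_transient = 0)
  ini <- init_history(p, cn, psi_init = c(0.3, -1.2), r_init = c(0.4, 0.6))
  tr <- integrate_model(p, cn, psi_init = c(0.3, -1.2), r_init = c(0.4, 0.6))
  # delayed z seen by each pair comes one step back in the history buffer
  depth <- nrow(ini$history)
  zd <- rbind(ini$history[depth - 1, ], ini$history[depth - 1, ])
  d <- oa_rhs(r = ini$r, psi = ini$psi, delayed_z = zd,
              A = cn$weights, G = p$G, L = p$L, Delta = p$Delta)
  expect_equal(tr$r[2, ], ini$r + p$dt * d$dr, tolerance = 1e-12)
  expect_equal(tr$psi[2, ], oanet:::wrap_phase(ini$psi + p$dt * d$dpsi),
               tolerance = 1e-12)
})

test_that("history initialization holds the decoupled equilibrium", {
  cn <- pair_connectome(d_mm = 50)
  p <- model_params(G = 3, L = 4, Delta = 1, v = 1)   # 50 ms delay
  ini <- init_history(p, cn, seed = 3)
  expect_equal(nrow(ini$history), max(ini$delay_steps) + 1L)
  expect_true(all(abs(Mod(ini$history) - sqrt(0.5)) < 1e-6))
  ini2 <- init_history(p, cn, seed = 3)
  expect_identical(ini$history, ini2$history)

  p0 <- model_params(G = 3, L = 4, Delta = 1, v = Inf)
  expect_equal(nrow(init_history(p0, cn, seed = 1)$history), 1L)
})

test_that("halving the step changes the endpoint by first-order amounts", {
  cn <- pair_connectome(d_mm = 17.1)
  run_end <- function(dt) {
    p <- model_params(G = 2, L = c(1.5, 2.5), Delta = 1, v = 3.42,
                      dt = dt, t_total = 2, t_transient = 0)
    tr <- integrate_model(p, cn, psi_init = c(0.4, 2.0),
                          r_init = c(0.3, 0.5))
    tr$r[nrow(tr$r), ]
  }
  expect_lt(max(abs(run_end(1e-3) - run_end(5e-4))), 1e-3)
})

test_that("bisection on the decoupled model recovers the critical coupling", {
  expect_equal(find_critical_coupling(Delta = 1), 2, tolerance = 0.02)
})

test_that("trajectories survive the run container round-trip", {
  cn <- single_connectome()
  p <- quick_params(G = 0, L = 4)
  tr <- integrate_model(p, cn, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  write_trajectory(tr, path)
  expect_equal(read_trajectory(path)$r, tr$r)
  txt <- withr::local_tempfile(fileext = ".txt")
  export_trajectory_text(tr, txt, every = 100L)
  m <- read_matrix_text(txt)
  expect_equal(nrow(m), length(seq(1, length(tr$times), by = 100)))
})
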