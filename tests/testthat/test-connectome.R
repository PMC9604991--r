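test_that("load_connectome symmetrizes weights and validates inputs", {
  wd <- withr::local_tempdir()
  wp <- file.path(wd, "w.txt"); dp <- file.path(wd, "d.txt")

  write_matrix_text(matrix(c(0, 4, 2, 0), 2, 2), wp)   # W = [[0,2],[4,0]]
  write_matrix_text(matrix(c(0, 5, 5, 0), 2, 2), dp)
  cn <- load_connectome(wp, dp)
  expect_equal(cn$weights, matrix(c(0, 3, 3, 0), 2, 2))

  sym <- matrix(c(0, 1.5, 1.5, 0), 2, 2)
  write_matrix_text(sym, wp)
  expect_equal(load_connectome(wp, dp)$weights, sym)

  write_matrix_text(matrix(0, 3, 3), dp)
  expect_error(load_connectome(wp, dp), "mismatch")

  write_matrix_text(matrix(c(0, -1, -1, 0), 2, 2), wp)
  write_matrix_text(matrix(c(0, 5, 5, 0), 2, 2), dp)
  expect_error(load_connectome(wp, dp), "negative.*\\(2,1\\)|negative.*\\(1,2\\)")

  writeLines(c("0 1 2", "1 0 3"), wp)
  expect_error(load_connectome(wp, dp), "not square")
})

test_that("normalize_weights rescales to unit mean edge weight", {
  cn <- connectome(matrix(c(0, 2, 0, 2, 0, 4, 0, 4, 0), 3, 3),
                   matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3) * 10)
  nz <- normalize_weights(cn)
  ut <- nz$weights[upper.tri(nz$weights)]
  expect_equal(sort(ut[ut > 0]), c(2 / 3, 4 / 3))
  expect_equal(mean(ut[ut > 0]), 1)
  expect_equal(nz$weights, t(nz$weights))
  expect_equal(which(nz$weights == 0), which(cn$weights == 0))

  ones <- connectome(matrix(1, 4, 4) - diag(4), matrix(10, 4, 4) - diag(10, 4))
  expect_equal(normalize_weights(ones)$weights, ones$weights)

  single <- connectome(matrix(c(0, 2, 2, 0), 2, 2), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(normalize_weights(single)$weights[1, 2], 1)

  expect_error(normalize_weights(connectome(matrix(0, 2, 2), matrix(0, 2, 2))),
               "all-zero")
})

test_that("normalize_weights is idempotent and supports the degree convention", {
  cn <- synthesize_connectome(8, seed = 5)
  once <- normalize_weights(cn)
  expect_equal(normalize_weights(once)$weights, once$weights)
  deg <- normalize_weights(cn, method = "degree")
  expect_equal(mean(rowSums(deg$weights)), 1)
  expect_equal(normalize_weights(deg, "degree")$weights, deg$weights)
})

test_that("synthesize_connectome is deterministic and obeys the invariants", {
  a <- synthesize_connectome(4, seed = 1)
  b <- synthesize_connectome(4, seed = 1)
  expect_identical(a$weights, b$weights)
  expect_identical(a$distances, b$distances)
  expect_false(identical(a$weights, synthesize_connectome(4, seed = 2)$weights))

  cn <- synthesize_connectome(10, seed = 7)
  expect_equal(cn$weights, t(cn$weights))
  expect_equal(diag(cn$weights), rep(0, 10))
  expect_true(all(cn$weights >= 0))
  expect_equal(cn$distances, t(cn$distances))
  expect_setequal(as.vector(cn$homotopic_pairs), 1:10)

  # mirrored barycenters: within-hemisphere distances are identical
  half <- 5L
  dl <- cn$distances[1:half, 1:half]
  dr <- cn$distances[half + 1:half, half + 1:half]
  expect_equal(dl, dr)
})

test_that("synthesized connectomes round-trip through the text writer", {
  cn <- synthesize_connectome(6, seed = 2)
  wd <- withr::local_tempdir()
  wp <- file.path(wd, "w.txt"); dp <- file.path(wd, "d.txt")
  write_connectome(cn, wp, dp)
  back <- load_connectome(wp, dp)
  expect_equal(back$weights, cn$weights, tolerance = 1e-8)
  expect_equal(back$distances, cn$distances, tolerance = 1e-8)
  expect_identical(back$homotopic_pairs, cn$homotopic_pairs)
  # writing the reloaded object reproduces the files bit-exactly
  wp2 <- file.path(wd, "w2.txt"); dp2 <- file.path(wd, "d2.txt")
  write_connectome(back, wp2, dp2)
  expect_identical(readLines(wp2), readLines(wp))
  expect_identical(readLines(dp2), readLines(dp))
})

test_that("compute_delays converts mm and velocity into seconds", {
  cn <- pair_connectome(d_mm = 34.2)
  tau <- compute_delays(cn, v = 3.42)
  expect_equal(tau[1, 2], 0.01)
  expect_equal(diag(tau), c(0, 0))
  expect_equal(compute_delays(cn, Inf), matrix(0, 2, 2))
  expect_equal(compute_delays(cn, 2 * 3.42), tau / 2)
  expect_error(compute_delays(cn, 0), "positive")
  expect_error(compute_delays(cn, -1), "positive")
})
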