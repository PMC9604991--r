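tiny_config <- function(out = NULL) {
  list(connectome = list(synth = list(E = 4, seed = 2)),
       model = list(G = 2, L = 1.5, v = 3.5, t_total = 8, t_transient = 2),
       pipeline = list(window_s = 2, overlap_s = 1),
       fitness = list(n_runs = 2, seed_base = 1))
}

test_that("config validation reports missing pieces with field paths", {
  expect_error(validate_run_config(list(model = list(G = 1, L = 1))),
               "connectome")
  expect_error(validate_run_config(
    list(connectome = list(weights = "nope.txt", distances = "nope.txt"),
         model = list(G = 1, L = 1))),
    "weights.*not found")
  expect_error(validate_run_config(
    list(connectome = list(synth = list(E = 4)), model = list(L = 1))),
    "G and L")
  cfg <- validate_run_config(tiny_config())
  expect_equal(cfg$model$mode, "fitness")
})

test_that("simulate_workflow writes a complete, reproducible run directory", {
  cfg <- tiny_config()
  out1 <- withr::local_tempdir()
  res1 <- simulate_workflow(cfg, out1)
  expect_true(all(file.exists(file.path(out1,
    c("config.yaml", "VERSION", "trajectory.rds", "trajectory_r.txt",
      "summary.json", "signal_decimated.txt")))))
  expect_match(readLines(file.path(out1, "VERSION")), "^oanet ")
  out2 <- withr::local_tempdir()
  res2 <- simulate_workflow(cfg, out2)
  expect_equal(res1$trajectory$r, res2$trajectory$r)
})

test_that("fc_workflow reports self-similarity 1 and KS 0", {
  set.seed(14)
  t <- seq(1e-3, 40, by = 1e-3)
  sig <- sapply(1:3, function(k)
    (1 + 0.3 * sin(2 * pi * 0.2 * t + k)) * sin(2 * pi * 10.5 * t + k))
  out <- withr::local_tempdir()
  res <- fc_workflow(sig, fs = 1000, out_dir = out,
                     config = list(pipeline = list(window_s = 5,
                                                   overlap_s = 2)))
  expect_true(file.exists(file.path(out, "sfc.txt")))
  expect_true(file.exists(file.path(out, "trfc_recurrence.txt")))
  expect_null(res$similarity)   # no reference supplied

  res2 <- fc_workflow(sig, fs = 1000, out_dir = withr::local_tempdir(),
                      config = list(pipeline = list(window_s = 5,
                                                    overlap_s = 2)),
                      reference_fc = res$sfc,
                      reference_recurrence = res$recurrence$values)
  expect_equal(res2$similarity, 1)
  expect_equal(res2$ks, 0)

  expect_error(fc_workflow(sig, fs = 1000,
                           out_dir = withr::local_tempdir(),
                           reference_fc = diag(5)),
               "regions")
})

test_that("fit_workflow recovers archives and reports for each optimizer", {
  cfg <- tiny_config()
  cfg$optimizer <- list(scenario = "scenario1", algorithms = c("pso", "ade"),
                        pop = 5, gens = 2, seed = 1)
  cn <- resolve_connectome(cfg)
  p <- resolve_model_params(cfg, cn$n_regions)
  target <- evaluate_fitness(p, cn, diag(4), n_runs = 2,
                             seed_base = 1)$median_sfc
  out <- withr::local_tempdir()
  runs <- fit_workflow(cfg, out, target_sfc = target)
  expect_named(runs, c("pso", "ade"))
  for (alg in names(runs)) {
    expect_true(file.exists(file.path(out, paste0("archive_", alg, ".tsv"))))
    expect_true(file.exists(file.path(out, paste0("report_", alg, ".json"))))
    arc <- read.delim(file.path(out, paste0("archive_", alg, ".tsv")))
    expect_equal(nrow(arc), 5 * 3)
    expect_named(arc, c("G", "L", "v", "score"))
  }
})

test_that("scenario 2 demands a homotopically paired connectome", {
  cn <- synthesize_connectome(4, seed = 1)
  wd <- withr::local_tempdir()
  wp <- file.path(wd, "w.txt"); dp <- file.path(wd, "d.txt")
  write_matrix_text(cn$weights, wp)
  write_matrix_text(cn$distances, dp)
  cfg <- list(connectome = list(weights = wp, distances = dp),
              model = list(G = 2, L = 1, t_total = 5, t_transient = 1),
              optimizer = list(scenario = "scenario2", pop = 5, gens = 1))
  expect_error(fit_workflow(cfg, withr::local_tempdir(), target_sfc = diag(4)),
               "homotopic")
})

test_that("oracle_check guards instance size and reports per-ensemble RMSE", {
  cn <- pair_connectome()
  p <- model_params(G = 1, L = c(1, 1), v = 3.42, t_total = 1,
                    t_transient = 0)
  res <- oracle_check(p, cn, N = 200, seed = 1)
  expect_length(res$rmse, 2)
  expect_true(is.finite(res$max_rmse))

  big <- synthesize_connectome(68, seed = 1)
  expect_error(oracle_check(model_params(G = 1, L = 1, t_total = 1,
                                         t_transient = 0), big),
               "E <= 4")
  expect_error(oracle_check(p, cn, N = 20000), "N <= 10000")
})

test_that("the command-line entry point synthesizes connectomes", {
  cli <- system.file("cli", "oanet", package = "oanet")
  expect_true(nzchar(cli))
  out <- withr::local_tempdir()
  withr::local_envvar(R_LIBS = paste(.libPaths(), collapse = .Platform$path.sep))
  status <- system2("Rscript",
                    c(cli, "synth-connectome", "--regions", "6",
                      "--seed", "2", "--out", out),
                    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(out, "weights.txt")))
  cn <- load_connectome(file.path(out, "weights.txt"),
                        file.path(out, "distances.txt"))
  expect_equal(cn$n_regions, 6)
})
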