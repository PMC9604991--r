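#' Load and validate a run configuration
#'
#' Run configurations are YAML (or plain R lists) with blocks:
#' `connectome` (either `weights`/`distances` file paths or a `synth` block
#' with `E` and `seed`), `model` (coupling and integration parameters;
#' `mode: fitness` simulates 66 s, `mode: trfc` 321 s, both discarding a
#' 19 s transient), `pipeline` (band, window, overlap), `fitness`
#' (`n_runs`, `seed_base`, constraint bounds), `optimizer` (`scenario`,
#' `algorithms`, `pop`, `gens`, `seed`, `target_fc` path) and `output`
#' (directory).
#'
#' @param path YAML file path.
#' @return validated config list of class `run_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_run_config(yaml::read_yaml(path))
}

#' @rdname load_run_config
#' @param config a named list with the blocks described above.
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  cn <- config$connectome
  if (is.null(cn)) stop("config$connectome is required")
  if (is.null(cn$synth)) {
    for (f in c("weights", "distances")) {
      if (is.null(cn[[f]])) stop("config$connectome$", f, " is required")
      if (!file.exists(cn[[f]]))
        stop("config$connectome$", f, ": file not found: ", cn[[f]])
    }
  } else {
    if (is.null(cn$synth$E)) stop("config$connectome$synth$E is required")
  }
  m <- config$model
  if (is.null(m$G) || is.null(m$L))
    stop("config$model must provide G and L")
  config$model$mode <- if (is.null(m$mode)) "fitness" else
    match.arg(m$mode, c("fitness", "trfc"))
  if (is.null(config$pipeline)) config$pipeline <- list()
  if (is.null(config$fitness)) config$fitness <- list()
  structure(config, class = c("run_config", "list"))
}

#' @rdname load_run_config
#' @export
resolve_connectome <- function(config) {
  cn <- config$connectome
  if (!is.null(cn$synth)) {
    seed <- if (is.null(cn$synth$seed)) 1L else cn$synth$seed
    synthesize_connectome(cn$synth$E, seed = seed)
  } else {
    load_connectome(cn$weights, cn$distances)
  }
}

#' @rdname load_run_config
#' @param E number of regions (for recycling `L`).
#' @export
resolve_model_params <- function(config, E) {
  m <- config$model
  pick <- function(x, default) if (is.null(x)) default else x
  v <- pick(m$v, Inf)
  if (identical(v, "Inf") || identical(v, 0)) v <- Inf
  t_total <- pick(m$t_total,
                  if (identical(config$model$mode, "trfc")) 321 else 66)
  model_params(G = m$G, L = unlist(m$L), Omega_hz = pick(m$Omega_hz, 10.5),
               Delta = pick(m$Delta, 1), v = v, dt = pick(m$dt, 1e-3),
               t_total = t_total, t_transient = pick(m$t_transient, 19),
               r_floor = pick(m$r_floor, 1e-3), seed = pick(m$seed, 1L))
}

prepare_out_dir <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  writeLines(paste0("oanet ", as.character(utils::packageVersion("oanet"))),
             file.path(out_dir, "VERSION"))
  invisible(out_dir)
}

#' Simulate one model run and write its outputs
#'
#' Integrates the model defined by `config`, writes the trajectory
#' container, the decimated text export, the synchrony summary JSON, the
#' neural signal (post-transient, ready for the FC pipeline), plus a copy
#' of the resolved config and a version stamp.
#'
#' @param config a `run_config` (see [load_run_config()]).
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with the trajectory and summary.
#' @export
simulate_workflow <- function(config, out_dir) {
  config <- validate_run_config(config)
  cn <- resolve_connectome(config)
  params <- resolve_model_params(config, cn$n_regions)
  prepare_out_dir(config, out_dir)
  traj <- integrate_model(params, cn)
  summ <- summarize_trajectory(traj)
  write_trajectory(traj, file.path(out_dir, "trajectory.rds"))
  export_trajectory_text(traj, file.path(out_dir, "trajectory_r.txt"))
  write_summary_json(summ, file.path(out_dir, "summary.json"))
  keep <- traj$times >= params$t_transient
  sig <- neural_signal(traj)[keep, , drop = FALSE]
  write_matrix_text(sig[seq(1L, nrow(sig), by = 10L), , drop = FALSE],
                    file.path(out_dir, "signal_decimated.txt"))
  invisible(list(trajectory = traj, summary = summ, signal = sig,
                 connectome = cn, params = params))
}

#' Functional-connectivity report for a signal
#'
#' Applies the envelope pipeline to a signal matrix, writes the static FC,
#' nodal strengths and trFC recurrence sample, and -- when a reference FC
#' matrix and/or reference recurrence sample are supplied -- the similarity
#' (upper-triangle correlation) and KS distance against them.
#'
#' @param signal numeric matrix of neural activity (rows time points).
#' @param fs sampling rate of `signal` in Hz.
#' @param out_dir output directory.
#' @param config optional `run_config` for pipeline settings (window,
#'   overlap).
#' @param reference_fc optional path to (or matrix of) a reference FC.
#' @param reference_recurrence optional path to (or vector of) reference
#'   recurrence values.
#' @return invisibly, a list with `sfc`, `recurrence`, `strength` and any
#'   comparison fields.
#' @export
fc_workflow <- function(signal, fs, out_dir, config = list(),
                        reference_fc = NULL, reference_recurrence = NULL) {
  pl <- config$pipeline
  pick <- function(x, default) if (is.null(x)) default else x
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- alpha_envelope(signal, fs = fs,
                        band = pick(pl$band, c(8, 13)),
                        env_lp = pick(pl$env_lp, 0.5),
                        fs_env = pick(pl$fs_env, 5))
  sfc <- static_fc(env)
  strength <- nodal_strength(sfc)
  out <- list(sfc = sfc, strength = strength)
  write_matrix_text(sfc, file.path(out_dir, "sfc.txt"))
  writeLines(formatC(strength, digits = 9L, format = "g"),
             file.path(out_dir, "nodal_strength.txt"))
  rec <- tryCatch(trfc_recurrence(env, window_s = pick(pl$window_s, 15),
                                  overlap_s = pick(pl$overlap_s, 12)),
                  error = function(e) NULL)
  if (!is.null(rec)) {
    out$recurrence <- rec
    writeLines(formatC(rec$values, digits = 9L, format = "g"),
               file.path(out_dir, "trfc_recurrence.txt"))
  }
  report <- list(n_regions = ncol(sfc),
                 n_upper_triangle = length(upper_tri_vec(sfc)))
  if (!is.null(reference_fc)) {
    ref <- if (is.character(reference_fc)) read_matrix_text(reference_fc)
           else as.matrix(reference_fc)
    if (!identical(dim(ref), dim(sfc)))
      stop("reference FC is ", nrow(ref), "x", ncol(ref),
           " but signal has ", ncol(sfc), " regions")
    out$similarity <- report$fc_similarity <- fc_similarity(sfc, ref)
  }
  if (!is.null(reference_recurrence) && !is.null(rec)) {
    refr <- if (is.character(reference_recurrence))
      scan(reference_recurrence, quiet = TRUE) else reference_recurrence
    out$ks <- report$ks_distance <- ks_distance(rec$values, refr)
  }
  jsonlite::write_json(report, file.path(out_dir, "fc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Fit model parameters to a target FC
#'
#' Runs the configured optimizer(s) on the chosen scenario against a target
#' static FC. Scenario 1 searches `(G, L, v)`; scenario 2 searches one
#' local coupling per homotopic pair with `G` and `v` fixed from the
#' config. Each optimizer's full evaluation archive is written as a
#' tab-separated log and the best parameters as a JSON report. If no
#' feasible parameters were found within the budget, the report carries a
#' warning field instead of raising an error.
#'
#' @param config a `run_config` with an `optimizer` block.
#' @param out_dir output directory.
#' @param target_sfc optional target FC matrix (otherwise read from
#'   `config$optimizer$target_fc`).
#' @return invisibly, a named list of `optimizer_run` objects.
#' @export
fit_workflow <- function(config, out_dir, target_sfc = NULL) {
  config <- validate_run_config(config)
  opt <- config$optimizer
  if (is.null(opt)) stop("config$optimizer is required")
  pick <- function(x, default) if (is.null(x)) default else x
  cn <- resolve_connectome(config)
  if (is.null(target_sfc)) {
    if (is.null(opt$target_fc))
      stop("provide target_sfc or config$optimizer$target_fc")
    target_sfc <- read_matrix_text(opt$target_fc)
  }
  scenario <- pick(opt$scenario, "scenario1")
  if (scenario == "scenario2" && is.null(cn$homotopic_pairs))
    stop("scenario2 requires a connectome with homotopic pairing")
  prepare_out_dir(config, out_dir)
  n_runs <- pick(config$fitness$n_runs, 20L)
  seed_base <- pick(config$fitness$seed_base, 1L)
  base <- resolve_model_params(config, cn$n_regions)

  make_params <- if (scenario == "scenario1") {
    space <- do.call(scenario1_space, pick(opt$bounds, list()))
    function(x) modifyList2(base, G = x[1], L = x[2], v = x[3])
  } else {
    space <- scenario2_space(cn)
    function(x) modifyList2(base, L = expand_homotopic(x, cn$homotopic_pairs))
  }
  objective <- function(x) {
    -evaluate_fitness(make_params(x), cn, target_sfc, n_runs = n_runs,
                      seed_base = seed_base)$score
  }

  algorithms <- pick(opt$algorithms, "pso")
  runs <- list()
  for (alg in algorithms) {
    fun <- switch(alg, pso = pso_minimize, ade = ade_minimize,
                  stop("unknown algorithm: ", alg))
    run <- fun(objective, space, pop = pick(opt$pop, 20L),
               gens = pick(opt$gens, 200L), seed = pick(opt$seed, 1L))
    runs[[alg]] <- run
    arc <- data.frame(run$archive$parameters,
                      score = -run$archive$values)
    write.table(arc, file.path(out_dir, paste0("archive_", alg, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    best_fit <- evaluate_fitness(make_params(run$best_parameters), cn,
                                 target_sfc, n_runs = n_runs,
                                 seed_base = seed_base)
    report <- list(algorithm = alg,
                   best_parameters = as.list(run$best_parameters),
                   best_score = -run$best_value,
                   feasible = best_fit$feasible,
                   constraint_medians = as.list(best_fit$medians))
    if (!any(-run$archive$values > -2))
      report$warning <- "no feasible parameters found within the budget"
    jsonlite::write_json(report,
                         file.path(out_dir, paste0("report_", alg, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(runs)
}

# rebuild model_params with some fields replaced
modifyList2 <- function(params, ...) {
  repl <- list(...)
  args <- unclass(params)
  for (nm in names(repl)) args[[nm]] <- repl[[nm]]
  do.call(model_params, args)
}

#' Check the mean-field reduction against the microscopic oracle
#'
#' Runs the finite-N Kuramoto simulator and the reduced model on matched
#' settings (same connectome, parameters, and initial order parameters) and
#' reports the per-ensemble RMSE between the microscopic `|z_n(t)|` and the
#' reduced `r_n(t)`. Restricted to small instances (`E <= 4`,
#' `N <= 10000`), where the comparison is meaningful and affordable.
#'
#' @param params a [model_params()].
#' @param connectome a [connectome()] with at most 4 regions.
#' @param N oscillators per ensemble (at most 10000).
#' @param seed seed shared by both simulators' initial conditions.
#' @param r_init initial synchrony for both systems (scalar or length E).
#'   The default, 0.3, is deliberately above the finite-sample noise floor:
#'   a sample of N phases cannot represent a Kuramoto order parameter below
#'   about `1/sqrt(N)` (0.014 at N = 5000), so matching at the mean-field
#'   incoherence floor is impossible and the comparison would measure the
#'   initial-condition gap, not the reduction error.
#' @param rmse_tol pass threshold on the per-ensemble trajectory RMSE.
#' @return list with `rmse` (per ensemble), `max_rmse`, `pass`, and both
#'   trajectories.
#' @export
oracle_check <- function(params, connectome, N = 5000L, seed = 1L,
                         r_init = 0.3, rmse_tol = 0.05) {
  E <- connectome$n_regions
  if (E > 4L) stop("oracle check is restricted to E <= 4 (got ", E, ")")
  if (N > 10000L) stop("oracle check is restricted to N <= 10000")
  L <- expand_L(params, E)
  psi0 <- with_seed(seed, runif(E, -pi, pi))
  r0 <- rep_len(pmax(r_init, params$r_floor), E)
  traj <- integrate_model(params, connectome, psi_init = psi0, r_init = r0)
  micro <- simulate_micro(micro_params(params, N), connectome, seed = seed,
                          psi_init = psi0, r_init = r0)
  rmod <- Mod(micro$z)
  rmse <- sqrt(colMeans((traj$r - rmod)^2))
  list(rmse = rmse, max_rmse = max(rmse), pass = max(rmse) < rmse_tol,
       reduced = traj, micro = micro)
}
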