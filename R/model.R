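#' Model parameters for the mean-field brain model
#'
#' Collects the parameters of the delayed Ott-Antonsen system. Each region
#' (ensemble) `n` evolves a complex Kuramoto order parameter
#' `z_n = r_n exp(i psi_n)`:
#' \deqn{\dot r_n = -\Delta r_n + (L_n/2)(1-r_n^2) r_n +
#'   (G/2E)(1-r_n^2) \sum_{p \ne n} A_{np} r_p(t-\tau_{np})
#'   \cos(\psi_p(t-\tau_{np}) - \psi_n)}
#' \deqn{\dot \psi_n = \Omega + (G/2E)(r_n + 1/r_n) \sum_{p \ne n} A_{np}
#'   r_p(t-\tau_{np}) \sin(\psi_p(t-\tau_{np}) - \psi_n)}
#' with `Omega = 2 pi Omega_hz` in rad/s and delays `tau = D / v`.
#'
#' @param G global coupling (1/s), nonnegative.
#' @param L local coupling(s) (1/s); a scalar is recycled to all ensembles.
#' @param Omega_hz central natural frequency in Hz (converted to rad/s
#'   internally).
#' @param Delta Lorentzian half-width of the natural-frequency distribution
#'   (1/s), positive.
#' @param v spike-propagation velocity in m/s; `Inf` means instantaneous
#'   coupling (all delays zero).
#' @param dt Euler integration step (s).
#' @param t_total simulated duration after time zero (s).
#' @param t_transient prefix discarded by summary statistics (s).
#' @param r_floor lower clamp for `r`; the phase equation contains `1/r_n`,
#'   so `r` is kept at or above this floor.
#' @param seed integer seed used for random initial phases.
#' @return an object of class `model_params`.
#' @export
model_params <- function(G, L, Omega_hz = 10.5, Delta = 1, v = Inf,
                         dt = 1e-3, t_total = 66, t_transient = 19,
                         r_floor = 1e-3, seed = 1L) {
  stopifnot_scalar(G, "G")
  if (G < 0) stop("'G' must be >= 0")
  stopifnot_scalar(Delta, "Delta", positive = TRUE)
  stopifnot_scalar(dt, "dt", positive = TRUE)
  stopifnot_scalar(t_total, "t_total", positive = TRUE)
  stopifnot_scalar(t_transient, "t_transient")
  if (t_transient < 0 || t_total <= t_transient)
    stop("need t_total > t_transient >= 0")
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0)
    stop("'v' must be > 0 (Inf for zero delays)")
  if (!is.numeric(L) || any(!is.finite(L)))
    stop("'L' must be finite numeric")
  structure(list(G = G, L = as.numeric(L), Omega_hz = Omega_hz,
                 Delta = Delta, v = v, dt = dt, t_total = t_total,
                 t_transient = t_transient, r_floor = r_floor,
                 seed = as.integer(seed)),
            class = "model_params")
}

expand_L <- function(params, E) {
  L <- params$L
  if (length(L) == 1L) L <- rep(L, E)
  if (length(L) != E)
    stop("length(L) = ", length(L), " does not match E = ", E)
  L
}

#' Decoupled equilibrium synchrony of one ensemble
#'
#' For an isolated ensemble (`G = 0`) the stable stationary synchrony is
#' `sqrt(1 - 2 Delta / L)` above the critical coupling `L > 2 Delta`, and 0
#' (incoherence) at or below it.
#'
#' @param L local coupling (1/s); vectorized.
#' @param Delta Lorentzian half-width (1/s), positive.
#' @return equilibrium `r` in `[0, 1)`.
#' @export
ensemble_equilibrium <- function(L, Delta) {
  if (any(Delta <= 0)) stop("'Delta' must be > 0")
  ifelse(L > 2 * Delta, sqrt(pmax(0, 1 - 2 * Delta / L)), 0)
}

#' Mean-field right-hand side (reference implementation)
#'
#' Plain-R evaluation of the time derivatives of `(r, psi)` given the matrix
#' of delayed order parameters seen by each pair. This mirrors the compiled
#' integrator kernel and is exposed for inspection and testing.
#'
#' @param r,psi numeric vectors of length E (current state).
#' @param delayed_z E x E complex matrix, `delayed_z[n, p] = z_p(t - tau_np)`.
#' @param A E x E weight matrix.
#' @param G global coupling.
#' @param L per-ensemble local couplings (length E).
#' @param Delta half-width (scalar or length E).
#' @param Omega_hz central frequency in Hz.
#' @return a list with elements `dr` and `dpsi` (rad/s).
#' @export
oa_rhs <- function(r, psi, delayed_z, A, G, L, Delta, Omega_hz = 10.5) {
  E <- length(r)
  Omega_rad <- 2 * pi * Omega_hz
  Delta <- rep_len(Delta, E)
  L <- rep_len(L, E)
  Aoff <- A
  diag(Aoff) <- 0
  # S_n = sum_p A_np z_p(t - tau_np); phase differences via complex products
  S <- rowSums(Aoff * delayed_z)
  cpl <- exp(-1i * psi) * S
  gc <- if (E > 0) G / (2 * E) else 0
  dr <- -Delta * r + L / 2 * (1 - r^2) * r + gc * (1 - r^2) * Re(cpl)
  dpsi <- Omega_rad + gc * (r + 1 / r) * Im(cpl)
  list(dr = dr, dpsi = dpsi)
}

#' Initialize state and history buffer
#'
#' Builds the delayed system's history on `[-tau_max, 0]`: initial phases are
#' drawn uniformly on `[-pi, pi)` and initial synchrony is set to the clamped
#' decoupled equilibrium `max(ensemble_equilibrium(L, Delta), r_floor)` at
#' `t = -tau_max`; each ensemble is then advanced independently (global
#' coupling forced to zero) with the same Euler scheme, filling the buffer at
#' every step.
#'
#' @param params a [model_params()].
#' @param connectome a [connectome()].
#' @param seed seed for the initial phases; defaults to `params$seed`.
#' @param psi_init optional explicit initial phases (overrides the draw).
#' @param r_init optional explicit initial synchrony values.
#' @return list with `r`, `psi` (state at `t = 0`), `history` (depth x E
#'   complex matrix, chronological, last row is `t = 0`) and `delay_steps`.
#' @export
init_history <- function(params, connectome, seed = NULL,
                         psi_init = NULL, r_init = NULL) {
  E <- connectome$n_regions
  L <- expand_L(params, E)
  if (is.null(psi_init)) {
    if (is.null(seed)) seed <- params$seed
    psi_init <- with_seed(seed, runif(E, -pi, pi))
  }
  if (is.null(r_init))
    r_init <- pmax(ensemble_equilibrium(L, params$Delta), params$r_floor)
  tau <- compute_delays(connectome, params$v)
  delay_steps <- matrix(as.integer(round(tau / params$dt)), E, E)
  depth <- max(delay_steps) + 1L
  Omega_rad <- 2 * pi * params$Omega_hz
  r <- pmin(1, pmax(params$r_floor, r_init))
  psi <- wrap_phase(psi_init)
  history <- matrix(complex(real = 0, imaginary = 0), depth, E)
  for (s in seq_len(depth - 1L)) {
    history[s, ] <- complex(modulus = r, argument = psi)
    dr <- -params$Delta * r + L / 2 * (1 - r^2) * r
    r <- pmin(1, pmax(params$r_floor, r + params$dt * dr))
    psi <- wrap_phase(psi + params$dt * Omega_rad)
  }
  history[depth, ] <- complex(modulus = r, argument = psi)
  list(r = r, psi = psi, history = history, delay_steps = delay_steps)
}

wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi)
  y - pi
}

#' Integrate the delayed mean-field model
#'
#' Time-delayed first-order Euler integration of the reduced system on a
#' connectome. Delays are rounded to the nearest integer number of steps.
#' The history on `[-tau_max, 0]` is generated as in [init_history()]; the
#' coupled system is then advanced from `t = 0` to `t = t_total`, recording
#' every step. After each step `r` is clamped to `[r_floor, 1]` and `psi`
#' wrapped to `[-pi, pi)`.
#'
#' @inheritParams init_history
#' @return an object of class `trajectory`: list with `times` (s), matrices
#'   `r` and `psi` (rows are time points, columns ensembles), `dt`,
#'   `t_transient` and the originating `params`.
#' @export
integrate_model <- function(params, connectome, seed = NULL,
                            psi_init = NULL, r_init = NULL) {
  stopifnot(inherits(params, "model_params"), inherits(connectome, "connectome"))
  E <- connectome$n_regions
  L <- expand_L(params, E)
  if (is.null(psi_init)) {
    if (is.null(seed)) seed <- params$seed
    psi_init <- with_seed(seed, runif(E, -pi, pi))
  }
  if (length(psi_init) != E) stop("psi_init must have length E")
  if (is.null(r_init))
    r_init <- pmax(ensemble_equilibrium(L, params$Delta), params$r_floor)
  r_init <- rep_len(r_init, E)
  tau <- compute_delays(connectome, params$v)
  delay_steps <- matrix(as.integer(round(tau / params$dt)), E, E)
  n_steps <- as.integer(round(params$t_total / params$dt))
  out <- integrate_oa_cpp(connectome$weights, delay_steps, params$G, L,
                          rep_len(params$Delta, E),
                          rep(2 * pi * params$Omega_hz, E), params$dt,
                          n_steps, r_init, psi_init, params$r_floor)
  structure(list(times = seq(0, by = params$dt, length.out = n_steps + 1L),
                 r = out$r, psi = out$psi, dt = params$dt,
                 t_transient = params$t_transient, params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", ncol(x$r), " ensembles, ",
      length(x$times), " samples (", round(max(x$times), 3), " s at dt = ",
      x$dt, " s)\n", sep = "")
  invisible(x)
}

#' Save / load a trajectory container
#'
#' The run container stores times, `r`, `psi` and the generating parameters
#' in a single serialized file; [export_trajectory_text()] writes a decimated
#' delimited-text view for interchange.
#'
#' @param traj a `trajectory`.
#' @param path file path.
#' @return `write_trajectory` the path, invisibly; `read_trajectory` the
#'   trajectory.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  saveRDS(traj, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  traj <- readRDS(path)
  stopifnot(inherits(traj, "trajectory"))
  traj
}

#' @rdname write_trajectory
#' @param every keep every `every`-th sample in the text export.
#' @export
export_trajectory_text <- function(traj, path, every = 10L) {
  keep <- seq(1L, length(traj$times), by = as.integer(every))
  m <- cbind(time = traj$times[keep], traj$r[keep, , drop = FALSE])
  txt <- apply(m, 1L, function(row)
    paste(formatC(row, digits = 9L, format = "g"), collapse = " "))
  writeLines(txt, path)
  invisible(path)
}

#' Locate the critical local coupling by bisection
#'
#' Numerically recovers the synchronization threshold of an isolated
#' ensemble (`G = 0`): the local coupling above which long-run synchrony is
#' sustained (`r > 1e-3`) and below which the ensemble decays to
#' incoherence. Near the threshold transients decay at rate `|1 - L/(2
#' Delta)|`, which is arbitrarily slow, so a fixed horizon cannot classify
#' reliably; instead each candidate `L` is integrated in blocks of
#' `block_s` seconds until the trajectory either reaches the `r` clamp
#' floor (decayed) or its tail log-slope flattens out (stationary plateau),
#' and the `r > 1e-3` predicate is applied to that stationary estimate.
#' The analytic value is `2 Delta`.
#'
#' @param Delta Lorentzian half-width (1/s).
#' @param lower,upper bisection bracket for `L`.
#' @param r0 initial synchrony for each probe run.
#' @param block_s block duration in seconds.
#' @param max_blocks cap on blocks per probe.
#' @param tol bracket width at which bisection stops.
#' @param dt Euler step (s).
#' @return the estimated critical coupling (1/s).
#' @export
find_critical_coupling <- function(Delta = 1, lower = 0, upper = 6,
                                   r0 = 0.5, block_s = 50, max_blocks = 12L,
                                   tol = 0.01, dt = 1e-3) {
  cn1 <- connectome(matrix(0, 1, 1), matrix(0, 1, 1))
  sustained <- function(L) {
    p <- model_params(G = 0, L = L, Delta = Delta, dt = dt,
                      t_total = block_s, t_transient = 0)
    r_start <- r0
    slope_prev <- NA_real_
    for (b in seq_len(max_blocks)) {
      traj <- integrate_model(p, cn1, r_init = r_start, psi_init = 0)
      n <- length(traj$times)
      r_end <- traj$r[n, 1]
      if (r_end <= p$r_floor + 1e-12) return(FALSE)
      i_mid <- which.min(abs(traj$times - 0.8 * block_s))
      slope <- (log(r_end) - log(traj$r[i_mid, 1])) / (0.2 * block_s)
      if (slope > -1e-4) return(r_end > 1e-3)
      # constant negative log-slope = pure exponential decay, no plateau
      if (!is.na(slope_prev) && abs(slope - slope_prev) < 5e-5 &&
          slope < -2e-4) return(FALSE)
      slope_prev <- slope
      r_start <- r_end
    }
    r_end > 1e-3
  }
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sustained(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
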