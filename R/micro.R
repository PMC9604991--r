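#' Sample Lorentzian (Cauchy) natural frequencies
#'
#' Draws oscillator frequencies from the Lorentzian distribution with given
#' center and half-width-at-half-maximum via the inverse CDF,
#' `center + hwhm * tan(pi (u - 1/2))`. Draws outside `center +/- 20 hwhm`
#' are rejected and resampled: the untruncated tails produce occasional
#' oscillators too fast for a fixed Euler step, while truncation this far out
#' perturbs the mean-field reduction negligibly.
#'
#' @param n number of draws.
#' @param center center frequency (rad/s).
#' @param hwhm half-width at half-maximum (1/s), positive.
#' @param seed optional integer seed.
#' @return numeric vector of `n` frequencies (rad/s).
#' @export
lorentzian_sample <- function(n, center, hwhm, seed = NULL) {
  if (hwhm <= 0) stop("'hwhm' must be > 0")
  draw <- function(m) center + hwhm * tan(pi * (runif(m) - 0.5))
  body <- function() {
    x <- draw(n)
    bad <- abs(x - center) > 20 * hwhm
    while (any(bad)) {
      x[bad] <- draw(sum(bad))
      bad <- abs(x - center) > 20 * hwhm
    }
    x
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' Sample phases with a prescribed Kuramoto order parameter
#'
#' Draws `n` phases whose realized order parameter matches a target modulus
#' `r0` and mean phase `psi0`. Offsets are taken from a wrapped Cauchy
#' distribution centered at zero; its concentration is calibrated by
#' bisection until the realized sample modulus is within `tol` of `r0`
#' (the same uniform variates are reused across bisection steps, so the
#' result is deterministic given the seed). The draw is finally rotated so
#' the realized mean phase equals `psi0`.
#'
#' @param n number of phases.
#' @param r0 target order-parameter modulus in `[0, 1)`.
#' @param psi0 target mean phase (rad).
#' @param seed optional integer seed.
#' @param tol calibration tolerance on the realized modulus.
#' @return numeric vector of `n` phases in `[-pi, pi)`.
#' @export
sample_phases_kop <- function(n, r0, psi0 = 0, seed = NULL, tol = 1e-4) {
  if (r0 < 0 || r0 >= 1) stop("'r0' must be in [0, 1)")
  body <- function() {
    u <- runif(n)
    offsets <- function(rho) {
      if (rho <= 0) return(2 * pi * u - pi)
      # wrapped Cauchy quantile: location 0, concentration rho
      2 * atan((1 - rho) / (1 + rho) * tan(pi * (u - 0.5)))
    }
    realized <- function(rho) Mod(mean(exp(1i * offsets(rho))))
    lo <- 0; hi <- 1 - 1e-12
    if (realized(lo) >= r0) {
      rho <- lo
    } else {
      for (it in 1:60) {
        rho <- (lo + hi) / 2
        if (abs(realized(rho) - r0) < tol) break
        if (realized(rho) < r0) lo <- rho else hi <- rho
      }
    }
    th <- offsets(rho)
    z <- mean(exp(1i * th))
    wrap_phase(th - Arg(z) + psi0)
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' Parameters of the microscopic (finite-N) oracle
#'
#' @param params a [model_params()] carrying couplings, frequency
#'   distribution, velocity and integration settings.
#' @param N oscillators per ensemble (>= 2).
#' @return an object of class `micro_params`.
#' @export
micro_params <- function(params, N = 5000L) {
  stopifnot(inherits(params, "model_params"))
  if (N < 2) stop("'N' must be >= 2")
  structure(list(params = params, N = as.integer(N)), class = "micro_params")
}

#' Simulate the finite-N network-of-networks Kuramoto model
#'
#' Brute-force microscopic counterpart of the reduced model: each ensemble
#' holds `N` Kuramoto oscillators with Lorentzian natural frequencies,
#' all-to-all instantaneous coupling `L_n/N` within ensembles and delayed
#' coupling `(G/E) A_np / N` between ensembles. In the limit of infinite `N`
#' its per-ensemble order parameters obey the reduced equations, so this
#' simulator serves as an independent oracle for [integrate_model()].
#'
#' Initial phases at `t = -tau_max` are drawn per ensemble via
#' [sample_phases_kop()] so that the initial ensemble order parameter matches
#' the reduced model's `(r_init, psi_init)`; the history is then evolved
#' decoupled, as in the reduced integrator.
#'
#' @param mp a [micro_params()].
#' @param connectome a [connectome()].
#' @param seed integer seed for frequencies and initial phases; defaults to
#'   the embedded `model_params` seed.
#' @param psi_init,r_init optional target initial order parameters per
#'   ensemble (defaults: uniform random phases, clamped decoupled
#'   equilibrium).
#' @param record_every store the ensemble order parameters every this many
#'   steps.
#' @return list with `times`, complex matrix `z` (rows time, columns
#'   ensembles), and the drawn `omega`.
#' @export
simulate_micro <- function(mp, connectome, seed = NULL,
                           psi_init = NULL, r_init = NULL,
                           record_every = 1L) {
  stopifnot(inherits(mp, "micro_params"), inherits(connectome, "connectome"))
  p <- mp$params
  E <- connectome$n_regions
  N <- mp$N
  L <- expand_L(p, E)
  if (is.null(seed)) seed <- p$seed
  if (is.null(psi_init))
    psi_init <- with_seed(seed, runif(E, -pi, pi))
  if (is.null(r_init))
    r_init <- pmax(ensemble_equilibrium(L, p$Delta), p$r_floor)
  r_init <- rep_len(pmin(1 - 1e-9, r_init), E)
  omega <- with_seed(seed + 1L, {
    t(vapply(seq_len(E),
             function(n) lorentzian_sample(N, 2 * pi * p$Omega_hz, p$Delta),
             numeric(N)))
  })
  theta0 <- with_seed(seed + 2L, {
    t(vapply(seq_len(E),
             function(n) sample_phases_kop(N, r_init[n], psi_init[n]),
             numeric(N)))
  })
  tau <- compute_delays(connectome, p$v)
  delay_steps <- matrix(as.integer(round(tau / p$dt)), E, E)
  n_steps <- as.integer(round(p$t_total / p$dt))
  out <- simulate_micro_cpp(connectome$weights, delay_steps, p$G, L,
                            omega, theta0, p$dt, n_steps,
                            as.integer(record_every))
  times <- seq(0, by = p$dt * record_every, length.out = nrow(out$z))
  list(times = times, z = out$z, omega = omega)
}
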