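#' Global Kuramoto order parameter of the ensemble mean phases
#'
#' `R = |mean(exp(i psi))|` over the `E` ensembles: 0 for incoherent mean
#' phases, 1 for full between-ensemble synchrony.
#'
#' @param psi_row numeric vector of E phases (rad).
#' @return scalar in `[0, 1]`.
#' @export
global_kop <- function(psi_row) {
  if (length(psi_row) < 1L) stop("need at least one phase")
  Mod(mean(exp(1i * psi_row)))
}

#' Metastability: standard deviation of a synchrony series over time
#'
#' Population (second-moment) standard deviation; for the series lengths
#' used here the difference from the sample SD is negligible, and the
#' population form is fixed for reproducibility.
#'
#' @param series numeric vector, length >= 2.
#' @return nonnegative scalar.
#' @export
sd_over_time <- function(series) {
  n <- length(series)
  if (n < 2L) stop("need at least 2 samples")
  sqrt(mean((series - mean(series))^2))
}

#' Simulated neural activity from a trajectory
#'
#' Projects each ensemble's order parameter to a real signal as the
#' imaginary part of `r exp(i psi)`, i.e. `r sin(psi)` -- the standard
#' neural-activity proxy for order-parameter models.
#'
#' @param traj a `trajectory` from [integrate_model()].
#' @return numeric matrix, rows time points, columns ensembles.
#' @export
neural_signal <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  traj$r * sin(traj$psi)
}

#' Dominant spectral peak of a signal
#'
#' Periodogram argmax over `[1, fs/2)` Hz. The demeaned, Hann-windowed
#' signal is zero-padded so the frequency grid is at least as fine as
#' `resolution` Hz.
#'
#' @param signal numeric vector (at least 2 s of samples).
#' @param fs sampling rate (Hz).
#' @param resolution maximum frequency-grid spacing (Hz).
#' @return peak frequency in Hz.
#' @export
peak_frequency <- function(signal, fs, resolution = 0.25) {
  n <- length(signal)
  if (n < 2 * fs) stop("need at least 2 s of samples")
  x <- signal - mean(signal)
  if (all(x == 0)) stop("degenerate input: no spectral peak in a constant signal")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  nfft <- max(n, ceiling(fs / resolution))
  nfft <- 2^ceiling(log2(nfft))
  pad <- c(x * w, rep(0, nfft - n))
  pw <- Mod(fft(pad))^2
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  band <- which(freqs >= 1 & freqs < fs / 2)
  freqs[band][which.max(pw[band])]
}

#' Synchrony and metastability summary of a trajectory
#'
#' Computes, over samples with `t >= t_transient`: the global order
#' parameter time series `R_t`, its time average `mean_R`, the global
#' metastability `global_meta = SD(R)_t`, the grand mean of local synchrony
#' `mean_local`, and the local metastability `local_meta` (SD of each
#' ensemble's `r_n` over time, averaged over ensembles).
#'
#' @param traj a `trajectory`.
#' @param t_transient transient to discard (s); defaults to the value stored
#'   in the trajectory.
#' @return a list of class `synchrony_summary`.
#' @export
summarize_trajectory <- function(traj, t_transient = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(t_transient)) t_transient <- traj$t_transient
  keep <- traj$times >= t_transient
  if (sum(keep) < 2L) stop("fewer than 2 samples after the transient")
  psi <- traj$psi[keep, , drop = FALSE]
  r <- traj$r[keep, , drop = FALSE]
  R_t <- Mod(rowMeans(exp(1i * psi)))
  structure(list(R_t = R_t,
                 mean_R = mean(R_t),
                 global_meta = sd_over_time(R_t),
                 mean_local = mean(r),
                 local_meta = mean(apply(r, 2L, sd_over_time))),
            class = "synchrony_summary")
}

#' @export
print.synchrony_summary <- function(x, ...) {
  cat(sprintf(paste0("<synchrony_summary> mean_R = %.3f, SD(R)_t = %.3f, ",
                     "mean_local = %.3f, local_meta = %.3f\n"),
              x$mean_R, x$global_meta, x$mean_local, x$local_meta))
  invisible(x)
}

#' Write a synchrony summary as flat JSON
#'
#' @param s a `synchrony_summary`.
#' @param path output path.
#' @export
write_summary_json <- function(s, path) {
  stopifnot(inherits(s, "synchrony_summary"))
  jsonlite::write_json(list(mean_R = s$mean_R, global_meta = s$global_meta,
                            mean_local = s$mean_local,
                            local_meta = s$local_meta),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
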