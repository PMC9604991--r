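#' Alpha-band amplitude envelopes
#'
#' MEG-style envelope extraction, applied identically to simulated and
#' pre-parcellated empirical signals: zero-phase band-pass 8-13 Hz, analytic
#' signal magnitude (Hilbert envelope), zero-phase low-pass at 0.5 Hz,
#' one-second trim at each end to remove filter edge artifacts, then
#' downsampling to 5 Hz. Both filters have a fourth-order Butterworth
#' magnitude response, realized as a second-order design run forward and
#' backward ([signal::filtfilt()]), which doubles the effective order and
#' cancels phase distortion.
#'
#' @param x numeric matrix (rows time points, columns regions) or vector.
#' @param fs sampling rate in Hz (>= 30; the 13 Hz band edge must be
#'   resolvable).
#' @param band band-pass edges in Hz.
#' @param env_lp envelope low-pass cutoff in Hz.
#' @param fs_env envelope output rate in Hz.
#' @param edge_trim_s seconds removed at each end after filtering.
#' @return an `envelope_set`: list with `fs_env` and nonnegative matrix
#'   `env` (rows time at `fs_env`, columns regions).
#' @details Zero-phase filtering is applied spectrally: the second-order
#'   digital Butterworth designed by [signal::butter()] has its
#'   squared-magnitude response (the forward-backward, i.e. effective
#'   fourth-order, response) evaluated on the FFT grid and multiplied into
#'   the signal spectrum. This equals the steady-state forward-backward
#'   recursive filter, differs only in edge transients -- which the
#'   `edge_trim_s` trim discards -- and lets the band-pass be fused with
#'   the Hilbert transform in a single FFT pair.
#' @export
alpha_envelope <- function(x, fs, band = c(8, 13), env_lp = 0.5,
                           fs_env = 5, edge_trim_s = 1) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  if (fs < 30 || fs / 2 <= band[2])
    stop("sampling rate ", fs, " Hz is too low for the ", band[2],
         " Hz band edge")
  if (n < 4 * fs) stop("need at least 4 s of signal")
  # pad to a 2-3-5-smooth length: keeps the FFT fast for any duration, and
  # the circular wrap-around lives in the trimmed edges
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  lp <- signal::butter(2, env_lp / (fs / 2), type = "low")
  Hbp <- zero_phase_gain(bp, nfft)
  Hlp <- zero_phase_gain(lp, nfft)
  # analytic-signal weights (one-sided spectrum doubling); nfft is even
  h <- numeric(nfft)
  h[c(1L, nfft / 2L + 1L)] <- 1
  h[2:(nfft / 2L)] <- 2
  xp <- rbind(sweep(x, 2L, colMeans(x)), matrix(0, nfft - n, ncol(x)))
  X <- stats::mvfft(xp)
  e <- Mod(stats::mvfft(X * (Hbp * h), inverse = TRUE) / nfft)[seq_len(n), ,
                                                               drop = FALSE]
  # bridge the circular gap with a ramp so the slow low-pass does not see a
  # cliff at the pad boundary
  ramp <- seq(1, 0, length.out = nfft - n + 2L)[c(-1L, -(nfft - n + 2L))]
  pad <- outer(ramp, e[n, ]) + outer(1 - ramp, e[1, ])
  E2 <- stats::mvfft(rbind(e, pad))
  env <- Re(stats::mvfft(E2 * as.vector(Hlp), inverse = TRUE) /
              nfft)[seq_len(n), , drop = FALSE]
  trim <- as.integer(round(edge_trim_s * fs))
  if (trim > 0) env <- env[(trim + 1):(n - trim), , drop = FALSE]
  step <- as.integer(round(fs / fs_env))
  env <- env[seq(1L, nrow(env), by = step), , drop = FALSE]
  env[env < 0] <- 0   # low-pass ringing can dip slightly below zero
  structure(list(fs_env = fs_env, env = env), class = "envelope_set")
}

# squared-magnitude (zero-phase, forward-backward) response of a digital
# b/a filter on the length-n FFT grid
zero_phase_gain <- function(ba, n) {
  w <- 2 * pi * (seq_len(n) - 1) / n        # digital rad/sample, full circle
  zi <- exp(-1i * w)
  num <- outer(zi, seq_along(ba$b) - 1, `^`) %*% ba$b
  den <- outer(zi, seq_along(ba$a) - 1, `^`) %*% ba$a
  as.vector(Mod(num / den)^2)
}

#' Static functional connectivity
#'
#' Pearson correlation matrix of the downsampled envelopes.
#'
#' @param env an `envelope_set` from [alpha_envelope()], or a plain numeric
#'   matrix of envelope samples.
#' @return symmetric E x E correlation matrix with unit diagonal (class
#'   `fc_matrix` attribute not set; a plain matrix).
#' @export
static_fc <- function(env) {
  m <- if (inherits(env, "envelope_set")) env$env else as.matrix(env)
  if (nrow(m) < 10L) stop("need at least 10 envelope samples")
  v <- apply(m, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance envelope in region ", which(v == 0)[1])
  fc <- cor(m)
  diag(fc) <- 1
  dimnames(fc) <- NULL
  fc
}

#' Similarity between two FC matrices
#'
#' Pearson correlation over the strict upper triangles (`E(E-1)/2` values;
#' 2278 pairs for the 68-region parcellation).
#'
#' @param a,b square FC matrices of identical dimension.
#' @return correlation in `[-1, 1]`.
#' @export
fc_similarity <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("dimension mismatch: ", nrow(a), "x", ncol(a), " vs ",
         nrow(b), "x", ncol(b))
  cor(upper_tri_vec(a), upper_tri_vec(b))
}

#' Time-resolved FC recurrence
#'
#' Slides a window of `window_s` seconds advancing by `window_s - overlap_s`
#' over the envelopes, computes [static_fc()] within each window, and
#' returns the Pearson correlations between the upper-triangle vectors of
#' every window pair -- the recurrence distribution whose histogram
#' characterizes time-resolved FC.
#'
#' @param env an `envelope_set`.
#' @param window_s window length in seconds.
#' @param overlap_s overlap between consecutive windows in seconds.
#' @return a `recurrence_sample`: list with `values` (length
#'   `W(W-1)/2`), `n_windows`, `window_s`, `overlap_s`.
#' @export
trfc_recurrence <- function(env, window_s = 15, overlap_s = 12) {
  stopifnot(inherits(env, "envelope_set"))
  if (overlap_s >= window_s) stop("overlap must be shorter than the window")
  fs <- env$fs_env
  win <- as.integer(round(window_s * fs))
  step <- as.integer(round((window_s - overlap_s) * fs))
  n <- nrow(env$env)
  W <- if (n < win) 0L else (n - win) %/% step + 1L
  if (W < 2L) stop("need at least 2 windows (", W, " available)")
  uppers <- vapply(seq_len(W), function(k) {
    rows <- ((k - 1L) * step + 1L):((k - 1L) * step + win)
    upper_tri_vec(static_fc(env$env[rows, , drop = FALSE]))
  }, numeric(ncol(env$env) * (ncol(env$env) - 1L) / 2L))
  rec <- cor(uppers)
  structure(list(values = upper_tri_vec(rec), n_windows = W,
                 window_s = window_s, overlap_s = overlap_s),
            class = "recurrence_sample")
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' Two-sample KS statistic: the supremum over the pooled sample points of
#' the absolute difference between the empirical CDFs. Computed on the raw
#' samples (no histogram binning).
#'
#' @param a,b numeric vectors (or `recurrence_sample` objects), non-empty.
#' @return KS statistic in `[0, 1]`.
#' @export
ks_distance <- function(a, b) {
  if (inherits(a, "recurrence_sample")) a <- a$values
  if (inherits(b, "recurrence_sample")) b <- b$values
  if (length(a) == 0L || length(b) == 0L) stop("samples must be non-empty")
  x <- sort(unique(c(a, b)))
  Fa <- findInterval(x, sort(a)) / length(a)
  Fb <- findInterval(x, sort(b)) / length(b)
  max(abs(Fa - Fb))
}

#' Nodal static FC strength
#'
#' Sum of a node's FC to all other nodes (row sums excluding the diagonal).
#'
#' @param fc square FC matrix.
#' @return numeric vector of E strengths.
#' @export
nodal_strength <- function(fc) {
  rowSums(fc) - diag(fc)
}
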