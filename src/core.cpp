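// Time-delayed integrators for the mean-field (Ott-Antonsen) brain model and
// its finite-N microscopic Kuramoto counterpart. Both keep a ring buffer of
// per-ensemble complex order parameters z_n = r_n exp(i psi_n) so that delayed
// coupling terms are O(E^2) per step regardless of the delay pattern.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double wrap_pi(double x) {
  // wrap to [-pi, pi)
  const double two_pi = 2.0 * M_PI;
  return x - two_pi * std::floor((x + M_PI) / two_pi);
}

// Forward Euler of the delayed mean-field equations.
//
// dr_n/dt  = -Delta_n r_n + (L_n/2)(1 - r_n^2) r_n
//            + (G/2E)(1 - r_n^2) Re[ e^{-i psi_n} sum_{p != n} A_np z_p(t - tau_np) ]
// dpsi_n/dt = Omega_n + (G/2E)(r_n + 1/r_n) Im[ e^{-i psi_n} sum_{p != n} A_np z_p(t - tau_np) ]
//
// The history over [-tau_max, 0] is generated by the same scheme with G = 0
// (fully decoupled evolution) starting from (r_init, psi_init) at t = -tau_max.
// r is clamped to [r_floor, 1] and psi wrapped to [-pi, pi) after every step.
//
// Returns r and psi recorded at every step from t = 0 to t = n_steps * dt
// (n_steps + 1 rows), plus the filled history buffer at t = 0.
// [[Rcpp::export]]
List integrate_oa_cpp(const arma::mat& A,
                      const arma::imat& delay_steps,
                      double G,
                      const arma::vec& L,
                      const arma::vec& Delta,
                      const arma::vec& Omega_rad,
                      double dt,
                      int n_steps,
                      const arma::vec& r_init,
                      const arma::vec& psi_init,
                      double r_floor,
                      int record_from = 0,
                      bool want_signal = false) {
  const int E = A.n_rows;
  if ((int)A.n_cols != E || (int)delay_steps.n_rows != E ||
      (int)delay_steps.n_cols != E)
    stop("weight and delay matrices must be E x E");
  const int max_delay = delay_steps.max();
  const int depth = max_delay + 1;

  arma::vec r = r_init, psi = psi_init;
  for (int n = 0; n < E; ++n) {
    r[n] = std::min(1.0, std::max(r_floor, r[n]));
    psi[n] = wrap_pi(psi[n]);
  }

  arma::cx_mat ring(depth, E);
  arma::cx_mat hist(depth, E);   // chronological snapshot of [-tau_max, 0]
  // decoupled history fill: global step s = 0 is t = -tau_max, s = max_delay is t = 0
  for (int s = 0; s < max_delay; ++s) {
    const int row = s % depth;
    for (int n = 0; n < E; ++n) {
      ring(row, n) = std::polar(r[n], psi[n]);
      hist(s, n) = ring(row, n);
    }
    for (int n = 0; n < E; ++n) {
      const double rn = r[n];
      const double dr = -Delta[n] * rn + 0.5 * L[n] * (1.0 - rn * rn) * rn;
      r[n] = std::min(1.0, std::max(r_floor, rn + dt * dr));
      psi[n] = wrap_pi(psi[n] + dt * Omega_rad[n]);
    }
  }

  const int n_rec = n_steps - record_from + 1;
  if (n_rec < 1) stop("record_from is past the end of the run");
  arma::mat r_out(n_rec, E), psi_out(want_signal ? 0 : n_rec, E);
  arma::mat sig_out(want_signal ? n_rec : 0, E);
  arma::vec R_out(want_signal ? n_rec : 0);
  const double gc = (E > 0) ? G / (2.0 * E) : 0.0;

  for (int k = 0; k <= n_steps; ++k) {
    const int s = max_delay + k;           // global step index of current time
    const int row = s % depth;
    double sum_re = 0.0, sum_im = 0.0;
    for (int n = 0; n < E; ++n) {
      const std::complex<double> zn = std::polar(r[n], psi[n]);
      ring(row, n) = zn;
      if (k == 0) hist(max_delay, n) = zn;
      if (k >= record_from) {
        const int kr = k - record_from;
        r_out(kr, n) = r[n];
        if (want_signal) {
          sig_out(kr, n) = zn.imag();
          sum_re += zn.real() / r[n];     // unit phasor e^{i psi}
          sum_im += zn.imag() / r[n];
        } else {
          psi_out(kr, n) = psi[n];
        }
      }
    }
    if (want_signal && k >= record_from)
      R_out(k - record_from) =
          std::sqrt(sum_re * sum_re + sum_im * sum_im) / E;
    if (k == n_steps) break;

    for (int n = 0; n < E; ++n) {
      std::complex<double> S(0.0, 0.0);
      for (int p = 0; p < E; ++p) {
        if (p == n) continue;
        const double a = A(n, p);
        if (a == 0.0) continue;
        const int drow = (s - delay_steps(n, p)) % depth;
        S += a * ring(drow, p);
      }
      const std::complex<double> c = std::polar(1.0, -psi[n]) * S;
      const double rn = r[n];
      const double dr = -Delta[n] * rn + 0.5 * L[n] * (1.0 - rn * rn) * rn +
                        gc * (1.0 - rn * rn) * c.real();
      const double dpsi = Omega_rad[n] + gc * (rn + 1.0 / rn) * c.imag();
      const double rn1 = rn + dt * dr;
      const double psin1 = psi[n] + dt * dpsi;
      if (!std::isfinite(rn1) || !std::isfinite(psin1))
        stop("non-finite state at step %d (try a smaller dt)", k + 1);
      r[n] = std::min(1.0, std::max(r_floor, rn1));
      psi[n] = wrap_pi(psin1);
    }
  }

  return List::create(_["r"] = r_out, _["psi"] = psi_out,
                      _["signal"] = sig_out, _["R_t"] = R_out,
                      _["history"] = hist);
}

// Finite-N network-of-networks Kuramoto model whose OA reduction is the
// mean-field system above:
//
// dtheta_i^(n)/dt = omega_i^(n)
//   + (L_n/N) sum_j sin(theta_j^(n) - theta_i^(n))
//   + (G/E) sum_{p != n} A_np (1/N) sum_j sin(theta_j^(p)(t - tau_np) - theta_i^(n))
//
// Both coupling sums collapse onto ensemble order parameters:
// dtheta_i = omega_i + Im[ (L_n z_n + (G/E) sum_p A_np z_p(t - tau_np)) e^{-i theta_i} ].
// History over [-tau_max, 0] evolves each ensemble decoupled (G = 0).
//
// Returns the complex ensemble order parameters z_n recorded every
// `record_every` steps from t = 0.
// [[Rcpp::export]]
List simulate_micro_cpp(const arma::mat& A,
                        const arma::imat& delay_steps,
                        double G,
                        const arma::vec& L,
                        const arma::mat& omega,    // E x N (rad/s)
                        const arma::mat& theta0,   // E x N phases at t = -tau_max
                        double dt,
                        int n_steps,
                        int record_every) {
  const int E = A.n_rows;
  const int N = omega.n_cols;
  if ((int)omega.n_rows != E || (int)theta0.n_rows != E ||
      (int)theta0.n_cols != N)
    stop("omega and theta0 must be E x N");
  const int max_delay = delay_steps.max();
  const int depth = max_delay + 1;

  arma::mat theta = theta0;
  arma::cx_mat ring(depth, E);
  arma::cx_vec z(E);

  auto ensemble_kop = [&](int n) {
    std::complex<double> acc(0.0, 0.0);
    for (int i = 0; i < N; ++i) acc += std::polar(1.0, theta(n, i));
    return acc / (double)N;
  };

  // decoupled history fill
  for (int s = 0; s < max_delay; ++s) {
    const int row = s % depth;
    for (int n = 0; n < E; ++n) {
      z[n] = ensemble_kop(n);
      ring(row, n) = z[n];
    }
    for (int n = 0; n < E; ++n) {
      const std::complex<double> H = L[n] * z[n];
      for (int i = 0; i < N; ++i) {
        const double th = theta(n, i);
        const double drive =
            H.imag() * std::cos(th) - H.real() * std::sin(th);
        theta(n, i) = th + dt * (omega(n, i) + drive);
      }
    }
  }

  const int n_rec = n_steps / record_every + 1;
  arma::cx_mat z_out(n_rec, E);
  const double ge = (E > 0) ? G / (double)E : 0.0;
  int rec = 0;

  for (int k = 0; k <= n_steps; ++k) {
    const int s = max_delay + k;
    const int row = s % depth;
    for (int n = 0; n < E; ++n) {
      z[n] = ensemble_kop(n);
      ring(row, n) = z[n];
    }
    if (k % record_every == 0 && rec < n_rec) {
      for (int n = 0; n < E; ++n) z_out(rec, n) = z[n];
      ++rec;
    }
    if (k == n_steps) break;

    for (int n = 0; n < E; ++n) {
      std::complex<double> H = L[n] * z[n];
      for (int p = 0; p < E; ++p) {
        if (p == n) continue;
        const double a = A(n, p);
        if (a == 0.0) continue;
        const int drow = (s - delay_steps(n, p)) % depth;
        H += ge * a * ring(drow, p);
      }
      const double Hr = H.real(), Hi = H.imag();
      for (int i = 0; i < N; ++i) {
        const double th = theta(n, i);
        const double th1 =
            th + dt * (omega(n, i) + Hi * std::cos(th) - Hr * std::sin(th));
        if (!std::isfinite(th1))
          stop("non-finite phase at step %d", k + 1);
        theta(n, i) = th1;
      }
    }
  }

  return List::create(_["z"] = z_out, _["record_every"] = record_every);
}

// Fitness-path variant of the mean-field integrator: identical dynamics,
// but instead of returning full trajectories it accumulates the synchrony
// summaries (time averages and population SDs of global R and local r over
// the post-transient samples) at every step, and records the neural signal
// Im(z_n) only every `signal_stride` steps past `record_from`.
// [[Rcpp::export]]
List fitness_run_cpp(const arma::mat& A,
                     const arma::imat& delay_steps,
                     double G,
                     const arma::vec& L,
                     const arma::vec& Delta,
                     const arma::vec& Omega_rad,
                     double dt,
                     int n_steps,
                     const arma::vec& r_init,
                     const arma::vec& psi_init,
                     double r_floor,
                     int record_from,
                     int signal_stride) {
  const int E = A.n_rows;
  const int max_delay = delay_steps.max();
  const int depth = max_delay + 1;

  arma::vec r = r_init, psi = psi_init;
  for (int n = 0; n < E; ++n) {
    r[n] = std::min(1.0, std::max(r_floor, r[n]));
    psi[n] = wrap_pi(psi[n]);
  }

  arma::cx_mat ring(depth, E);
  for (int s = 0; s < max_delay; ++s) {
    const int row = s % depth;
    for (int n = 0; n < E; ++n)
      ring(row, n) = std::polar(r[n], psi[n]);
    for (int n = 0; n < E; ++n) {
      const double rn = r[n];
      const double dr = -Delta[n] * rn + 0.5 * L[n] * (1.0 - rn * rn) * rn;
      r[n] = std::min(1.0, std::max(r_floor, rn + dt * dr));
      psi[n] = wrap_pi(psi[n] + dt * Omega_rad[n]);
    }
  }

  const int n_rec = n_steps - record_from + 1;
  if (n_rec < 2) stop("record_from leaves fewer than 2 samples");
  const int n_sig = (n_rec - 1) / signal_stride + 1;
  arma::mat sig_out(n_sig, E);
  double R_sum = 0.0, R_sumsq = 0.0;
  arma::vec r_sum(E, arma::fill::zeros), r_sumsq(E, arma::fill::zeros);
  const double gc = (E > 0) ? G / (2.0 * E) : 0.0;
  int n_acc = 0;

  for (int k = 0; k <= n_steps; ++k) {
    const int s = max_delay + k;
    const int row = s % depth;
    double sum_re = 0.0, sum_im = 0.0;
    const bool rec = (k >= record_from);
    const int kr = k - record_from;
    const bool sig_now = rec && (kr % signal_stride == 0);
    for (int n = 0; n < E; ++n) {
      const std::complex<double> zn = std::polar(r[n], psi[n]);
      ring(row, n) = zn;
      if (rec) {
        r_sum[n] += r[n];
        r_sumsq[n] += r[n] * r[n];
        sum_re += std::cos(psi[n]);
        sum_im += std::sin(psi[n]);
        if (sig_now) sig_out(kr / signal_stride, n) = zn.imag();
      }
    }
    if (rec) {
      const double R =
          std::sqrt(sum_re * sum_re + sum_im * sum_im) / E;
      R_sum += R;
      R_sumsq += R * R;
      ++n_acc;
    }
    if (k == n_steps) break;

    for (int n = 0; n < E; ++n) {
      std::complex<double> S(0.0, 0.0);
      for (int p = 0; p < E; ++p) {
        if (p == n) continue;
        const double a = A(n, p);
        if (a == 0.0) continue;
        const int drow = (s - delay_steps(n, p)) % depth;
        S += a * ring(drow, p);
      }
      const std::complex<double> c = std::polar(1.0, -psi[n]) * S;
      const double rn = r[n];
      const double dr = -Delta[n] * rn + 0.5 * L[n] * (1.0 - rn * rn) * rn +
                        gc * (1.0 - rn * rn) * c.real();
      const double dpsi = Omega_rad[n] + gc * (rn + 1.0 / rn) * c.imag();
      const double rn1 = rn + dt * dr;
      const double psin1 = psi[n] + dt * dpsi;
      if (!std::isfinite(rn1) || !std::isfinite(psin1))
        stop("non-finite state at step %d (try a smaller dt)", k + 1);
      r[n] = std::min(1.0, std::max(r_floor, rn1));
      psi[n] = wrap_pi(psin1);
    }
  }

  const double mean_R = R_sum / n_acc;
  const double global_meta =
      std::sqrt(std::max(0.0, R_sumsq / n_acc - mean_R * mean_R));
  double mean_local = 0.0, local_meta = 0.0;
  for (int n = 0; n < E; ++n) {
    const double m = r_sum[n] / n_acc;
    mean_local += m;
    local_meta += std::sqrt(std::max(0.0, r_sumsq[n] / n_acc - m * m));
  }
  mean_local /= E;
  local_meta /= E;

  return List::create(_["signal"] = sig_out, _["mean_R"] = mean_R,
                      _["global_meta"] = global_meta,
                      _["mean_local"] = mean_local,
                      _["local_meta"] = local_meta);
}
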