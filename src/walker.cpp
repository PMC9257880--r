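// Hybrid dynamics core for the compass-type biped with a phase-oscillator CPG.
//
// The continuous swing phase is a two-DOF mechanical system in (theta1, theta2)
// with theta1 the stance-leg angle from vertical and theta2 the inter-leg
// angle; touchdown is detected on the section s = 2*theta1 - theta2 = 0
// (with theta1 < 0 and ds/dt < 0) and handled by an instantaneous, fully
// inelastic leg-swap collision.  Integration is Euler-Maruyama at a fixed
// time step; torque noise enters the velocity update through the inverse
// mass matrix as independent Wiener increments on each joint torque channel.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct WalkerP {
  double M, m, l, b, g;
};

// Mass matrix entries at inter-leg angle theta2.
inline void mass_matrix(const WalkerP &w, double th2,
                        double &M11, double &M12, double &M22) {
  const double c2 = std::cos(th2);
  M11 = w.M * w.l * w.l + w.m * (w.l * w.l + (w.l - w.b) * (w.l - w.b))
      - 2.0 * w.m * w.l * w.b * c2 + w.m * w.b * w.b;
  M12 = w.m * w.l * w.b * c2 - w.m * w.b * w.b;
  M22 = w.m * w.b * w.b;
}

// Angular accelerations: solve M(theta2) qdd = u - C(q, qd) - G(q).
inline void accel(const WalkerP &w, double th1, double th2, double w1,
                  double w2, double u1, double u2, double &a1, double &a2) {
  double M11, M12, M22;
  mass_matrix(w, th2, M11, M12, M22);
  const double s2 = std::sin(th2);
  const double C1 = -w.m * w.l * w.b * (w2 - 2.0 * w1) * w2 * s2;
  const double C2 = -w.m * w.l * w.b * w1 * w1 * s2;
  const double G1 = -(w.g * w.m * (2.0 * w.l - w.b) + w.g * w.M * w.l) *
                        std::sin(th1) -
                    w.g * w.m * w.b * std::sin(th2 - th1);
  const double G2 = w.g * w.m * w.b * std::sin(th2 - th1);
  const double r1 = u1 - C1 - G1;
  const double r2 = u2 - C2 - G2;
  const double det = M11 * M22 - M12 * M12;
  if (det == 0.0 || !std::isfinite(det))
    stop("singular mass matrix: nonphysical walker parameters");
  a1 = (M22 * r1 - M12 * r2) / det;
  a2 = (M11 * r2 - M12 * r1) / det;
}

// Velocity map through the inelastic touchdown collision, using the
// pre-impact stance angle th1m: Q+(th1m) v+ = Q-(th1m) v-.
inline void collide(const WalkerP &w, double th1m, double w1m, double w2m,
                    double &w1p, double &w2p) {
  const double c2 = std::cos(2.0 * th1m);
  const double Qp11 = -w.M * w.l * w.l - 2.0 * w.m * (w.l - w.b) * (w.l - w.b)
                      - 2.0 * w.m * w.l * w.b * (1.0 - c2);
  const double Qp12 = w.m * w.b * (w.b - w.l * c2);
  const double Qp21 = -w.m * w.l * (w.b - w.l * c2);
  const double Qp22 = w.m * w.l * w.b;
  const double Qm11 = 2.0 * w.m * (w.l - w.b) * (w.b - w.l * c2)
                      - w.M * w.l * w.l * c2;
  const double Qm12 = -w.m * (w.l - w.b) * w.b;
  const double Qm21 = w.m * w.l * (w.l - w.b);
  const double r1 = Qm11 * w1m + Qm12 * w2m;
  const double r2 = Qm21 * w1m; // Qm22 = 0
  const double det = Qp11 * Qp22 - Qp12 * Qp21;
  if (det == 0.0 || !std::isfinite(det))
    stop("singular collision matrix Q+");
  w1p = (Qp22 * r1 - Qp12 * r2) / det;
  w2p = (Qp11 * r2 - Qp21 * r1) / det;
}

// Deterministic, platform-independent Gaussian stream: splitmix64-seeded
// xoshiro-style generator with Box-Muller.
struct GaussStream {
  uint64_t s;
  double spare;
  bool has_spare;
  explicit GaussStream(uint64_t seed) : s(seed), spare(0.0), has_spare(false) {}
  inline uint64_t next_u64() { // splitmix64
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  inline double unif() { // in (0, 1)
    return (next_u64() >> 11) * (1.0 / 9007199254740992.0) +
           (0.5 / 9007199254740992.0);
  }
  inline double norm() {
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 6.283185307179586476925286766559 * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

inline double wrap2pi(double x) {
  const double twopi = 6.283185307179586476925286766559;
  x -= twopi * std::floor(x / twopi);
  if (x >= twopi) x -= twopi;
  if (x < 0.0) x += twopi;
  return x;
}

} // namespace

//' @noRd
// [[Rcpp::export(name = "cg_accel_cpp")]]
NumericVector cg_accel_cpp(NumericVector state, NumericVector torques,
                           NumericVector wp) {
  WalkerP w = {wp[0], wp[1], wp[2], wp[3], wp[4]};
  double a1, a2;
  accel(w, state[0], state[1], state[2], state[3], torques[0], torques[1],
        a1, a2);
  return NumericVector::create(a1, a2);
}

//' @noRd
// [[Rcpp::export(name = "cg_mass_matrix_cpp")]]
NumericMatrix cg_mass_matrix_cpp(double theta2, NumericVector wp) {
  WalkerP w = {wp[0], wp[1], wp[2], wp[3], wp[4]};
  double M11, M12, M22;
  mass_matrix(w, theta2, M11, M12, M22);
  NumericMatrix out(2, 2);
  out(0, 0) = M11; out(0, 1) = M12; out(1, 0) = M12; out(1, 1) = M22;
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cg_collision_cpp")]]
NumericVector cg_collision_cpp(NumericVector state, NumericVector wp) {
  WalkerP w = {wp[0], wp[1], wp[2], wp[3], wp[4]};
  double w1p, w2p;
  collide(w, state[0], state[2], state[3], w1p, w2p);
  return NumericVector::create(-state[0], -state[1], w1p, w2p);
}

//' @noRd
// [[Rcpp::export(name = "cg_energy_cpp")]]
double cg_energy_cpp(NumericVector state, NumericVector wp) {
  WalkerP w = {wp[0], wp[1], wp[2], wp[3], wp[4]};
  const double th1 = state[0], th2 = state[1], w1 = state[2], w2 = state[3];
  double M11, M12, M22;
  mass_matrix(w, th2, M11, M12, M22);
  const double T = 0.5 * (M11 * w1 * w1 + 2.0 * M12 * w1 * w2 + M22 * w2 * w2);
  const double V = w.g * ((w.M * w.l + w.m * (2.0 * w.l - w.b)) * std::cos(th1)
                          - w.m * w.b * std::cos(th1 - th2));
  return T + V;
}

// Full trial engine.  Returns touchdown times, pre- and post-touchdown
// states (columns th1, th2, w1, w2, phi), the torque-cost integral of each
// step cycle, hip displacement, fall diagnostics and (optionally) a
// subsampled trajectory.
//' @noRd
// [[Rcpp::export(name = "cg_simulate_cpp")]]
List cg_simulate_cpp(NumericVector wp, NumericVector cpg, int mode,
                     double xi, int noise_mode, double seed1, double seed2,
                     int n_steps, double dt, NumericVector init,
                     double phi_init, int record_every, bool refine,
                     double fall_theta, double fall_omega,
                     double fall_timeout, double t_stop, double tau_tol,
                     int tau_consec) {
  WalkerP w = {wp[0], wp[1], wp[2], wp[3], wp[4]};
  const double omega = cpg[0], A1 = cpg[1], A2 = cpg[2], delta = cpg[3],
               phi0 = cpg[4];
  double th1 = init[0], th2 = init[1], w1 = init[2], w2 = init[3];
  double phi = wrap2pi(phi_init);
  double t = 0.0, last_td = 0.0, disp = 0.0;

  GaussStream g1(static_cast<uint64_t>(seed1));
  GaussStream g2(static_cast<uint64_t>(seed2));
  const double sq = std::sqrt(dt);
  const bool noisy = xi > 0.0;
  // noise_mode 2: sigma_i = xi * U_i drawn at the start of each step cycle
  // and held constant until the next touchdown (motor-command noise per
  // movement); enters the torques directly.
  double hold1 = 0.0, hold2 = 0.0;
  if (noisy && noise_mode == 2) { hold1 = xi * g1.norm(); hold2 = xi * g2.norm(); }

  NumericVector td_times(n_steps);
  NumericMatrix td_pre(n_steps, 5), td_post(n_steps, 5);
  NumericVector eps_step(n_steps);
  double eps_acc = 0.0;

  std::vector<double> traj;
  const bool record = record_every > 0;

  bool fell = false;
  std::string why;
  int k = 0;
  long iter = 0;
  // Optional early stop for calibration runs: consecutive step periods
  // agreeing to tau_tol for tau_consec touchdowns.
  bool converged = false;
  double prev_tau = -1.0;
  int conv_count = 0;

  while (k < n_steps) {
    if (t_stop > 0.0 && t >= t_stop) break;
    const double u1 = A1 * std::cos(phi) + hold1;
    const double u2 = A2 * std::cos(phi + delta) + hold2;
    double a1, a2;
    accel(w, th1, th2, w1, w2, u1, u2, a1, a2);
    eps_acc += (u1 * u1 + u2 * u2) * dt;

    if (record && iter % record_every == 0) {
      traj.push_back(t);   traj.push_back(th1); traj.push_back(th2);
      traj.push_back(w1);  traj.push_back(w2);  traj.push_back(phi);
      traj.push_back(u1);  traj.push_back(u2);
    }

    double nb1 = 0.0, nb2 = 0.0;
    if (noisy && noise_mode != 2) {
      const double amp = (noise_mode == 0) ? xi * sq : xi * dt;
      const double n1 = amp * g1.norm();
      const double n2 = amp * g2.norm();
      double M11, M12, M22;
      mass_matrix(w, th2, M11, M12, M22);
      const double det = M11 * M22 - M12 * M12;
      nb1 = (M22 * n1 - M12 * n2) / det;
      nb2 = (M11 * n2 - M12 * n1) / det;
    }

    const double th1n = th1 + w1 * dt;
    const double th2n = th2 + w2 * dt;
    const double w1n = w1 + a1 * dt + nb1;
    const double w2n = w2 + a2 * dt + nb2;

    const double s_old = 2.0 * th1 - th2;
    const double s_new = 2.0 * th1n - th2n;
    if (s_old > 0.0 && s_new <= 0.0 && th1n < 0.0 &&
        (2.0 * w1n - w2n) < 0.0) {
      // Event: refine crossing time within (0, dt] by bisection on the
      // linearly advanced angles (single Euler substep, deterministic).
      double h = dt;
      if (refine) {
        double lo = 0.0, hi = dt;
        for (int it = 0; it < 64; ++it) {
          const double mid = 0.5 * (lo + hi);
          const double sm = 2.0 * (th1 + w1 * mid) - (th2 + w2 * mid);
          if (sm > 0.0) lo = mid; else hi = mid;
          if (std::fabs(sm) < 1e-14) { hi = mid; break; }
        }
        h = 0.5 * (lo + hi);
      }
      const double eth1 = th1 + w1 * h, eth2 = th2 + w2 * h;
      const double ew1 = w1 + a1 * h, ew2 = w2 + a2 * h;
      const double ephi = wrap2pi(phi + omega * h);
      const double tev = t + h;

      td_pre(k, 0) = eth1; td_pre(k, 1) = eth2;
      td_pre(k, 2) = ew1;  td_pre(k, 3) = ew2; td_pre(k, 4) = ephi;

      double w1p, w2p;
      collide(w, eth1, ew1, ew2, w1p, w2p);
      th1 = -eth1; th2 = -eth2; w1 = w1p; w2 = w2p;
      phi = (mode == 0) ? wrap2pi(phi0) : wrap2pi(ephi - M_PI);
      disp += 2.0 * w.l * std::fabs(std::sin(eth1));
      t = tev;

      td_times[k] = t;
      td_post(k, 0) = th1; td_post(k, 1) = th2;
      td_post(k, 2) = w1;  td_post(k, 3) = w2; td_post(k, 4) = phi;
      eps_step[k] = eps_acc;
      eps_acc = 0.0;
      const double tau = (k == 0) ? t : t - td_times[k - 1];
      if (tau_tol > 0.0) {
        if (prev_tau > 0.0 && std::fabs(tau - prev_tau) < tau_tol)
          ++conv_count;
        else
          conv_count = 0;
        prev_tau = tau;
      }
      ++k;
      last_td = t;
      ++iter;
      if (noisy && noise_mode == 2) {
        hold1 = xi * g1.norm();
        hold2 = xi * g2.norm();
      }
      if (tau_tol > 0.0 && conv_count >= tau_consec) { converged = true; break; }
      continue;
    }

    th1 = th1n; th2 = th2n; w1 = w1n; w2 = w2n;
    phi = wrap2pi(phi + omega * dt);
    t += dt;
    ++iter;

    if (!std::isfinite(th1) || !std::isfinite(w1) || !std::isfinite(w2))
      stop("non-finite state at t = %f", t);
    if (std::fabs(th1) > fall_theta) { fell = true; why = "theta1 exceeded fall threshold"; break; }
    if (std::fabs(w1) > fall_omega) { fell = true; why = "angular velocity exceeded fall threshold"; break; }
    if (t - last_td > fall_timeout) { fell = true; why = "no touchdown within timeout"; break; }
  }

  List out = List::create(
      _["td_times"] = td_times[Range(0, std::max(k - 1, 0))],
      _["td_pre"] = td_pre, _["td_post"] = td_post,
      _["eps_step"] = eps_step, _["n_touchdowns"] = k,
      _["hip_displacement"] = disp, _["fell"] = fell,
      _["fall_reason"] = why,
      _["final_state"] = NumericVector::create(th1, th2, w1, w2),
      _["final_phi"] = phi, _["final_time"] = t,
      _["converged"] = converged);
  if (record) {
    const R_xlen_t nrow = traj.size() / 8;
    NumericMatrix tm(nrow, 8);
    for (R_xlen_t i = 0; i < nrow; ++i)
      for (int j = 0; j < 8; ++j) tm(i, j) = traj[i * 8 + j];
    colnames(tm) = CharacterVector::create("t", "theta1", "theta2", "dtheta1",
                                           "dtheta2", "phi", "u1", "u2");
    out["trajectory"] = tm;
  }
  return out;
}

// Gaussian draws from the trial noise stream, exposed for reproducibility
// tests of the generator itself.
//' @noRd
// [[Rcpp::export(name = "cg_gauss_stream_cpp")]]
NumericVector cg_gauss_stream_cpp(double seed, int n) {
  GaussStream g(static_cast<uint64_t>(seed));
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g.norm();
  return out;
}
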