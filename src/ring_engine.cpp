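// Time-stepping engine for the stochastic ring network of place cells.
//
// Update order per step (mirrored exactly by the pure-R reference engine in
// simulate.R, including the order of RNG draws: one normal for the OU
// velocity when the motion is stochastic, then N uniforms for the spike
// draws):
//   1. motion update (Euler-Maruyama for the OU velocity), position wrapped
//   2. input evaluated at the new time and position
//   3. forward-Euler update of rates and depression variables
//   4. Bernoulli spike draws from the *updated* rates, p = r * dt
//   5. STDP trace decay, weight increments from the pre-increment traces,
//      trace increments, weight clipping to [0, wmax] (no autapses)

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double I, double alpha) {
  double z = I / alpha;
  if (z > 30.0) return I;
  if (z < -30.0) return alpha * std::exp(z);
  return alpha * std::log1p(std::exp(z));
}

static inline double wrap_pi(double x) {
  // floor-based wrap to [-pi, pi), arithmetic identical to the R helper
  // ((x + pi) %% (2 pi)) - pi so both engines agree bitwise
  double a = x + M_PI;
  double y = a - std::floor(a / (2.0 * M_PI)) * (2.0 * M_PI);
  return y - M_PI;
}

// [[Rcpp::export(name = ".ring_engine_cpp")]]
List ring_engine_cpp(int nsteps, double t0, double dt,
                     NumericMatrix W, double wI, double wmax,
                     double tau, double alpha, bool linear_phi,
                     NumericVector r, NumericVector x,
                     double tau_x, double U0,
                     NumericVector centers, LogicalVector tuned,
                     bool place_field_on,
                     double I0, double IPF, double Itheta, double f,
                     double untuned_I0,
                     int motion_kind, // 0 constant, 1 ou
                     double v_const, double v0, double sigma_v, double tau_v,
                     int sigma_scaling, // 0 sigma/tau*sqrt(dt), 1 sigma*sqrt(dt/tau)
                     double pos0, double v1_0,
                     bool plast_on, bool triplet,
                     double A2p, double tau_p, double A2m, double tau_m,
                     double A3p, double tau_y, double A3m, double tau_x3,
                     NumericVector tr_r1, NumericVector tr_o1,
                     NumericVector tr_r2, NumericVector tr_o2,
                     int record_every, int snapshot_every,
                     bool record_spikes) {
  const int N = W.nrow();
  NumericMatrix Wl = clone(W);
  NumericVector rl = clone(r), xl = clone(x);
  NumericVector r1 = clone(tr_r1), o1 = clone(tr_o1);
  NumericVector r2 = clone(tr_r2), o2 = clone(tr_o2);

  const double ep = std::exp(-dt / tau_p);
  const double em = std::exp(-dt / tau_m);
  const double ey = triplet ? std::exp(-dt / tau_y) : 0.0;
  const double ex = triplet ? std::exp(-dt / tau_x3) : 0.0;
  const double ou_noise = (sigma_scaling == 0)
      ? sigma_v / tau_v * std::sqrt(dt)
      : sigma_v * std::sqrt(dt / tau_v);

  int n_rec = (record_every > 0) ? nsteps / record_every : 0;
  NumericVector rec_t(n_rec), rec_pos(n_rec), rec_vel(n_rec), rec_lfp(n_rec);
  NumericMatrix rec_r(n_rec, N), rec_x(n_rec, N);
  int n_snap = (snapshot_every > 0) ? nsteps / snapshot_every : 0;
  List snapshots(n_snap);
  NumericVector snap_t(n_snap);

  std::vector<int> spk_id;
  std::vector<double> spk_t;

  NumericVector drive(N), xr(N);
  std::vector<int> spikers;
  spikers.reserve(N);

  double pos = pos0, v1 = v1_0;
  int clip_warn = 0;
  int i_rec = 0, i_snap = 0;

  for (int step = 1; step <= nsteps; ++step) {
    double t = t0 + step * dt;

    // 1. motion
    double vel;
    if (motion_kind == 1) {
      double eta = R::norm_rand();
      v1 += dt * (-v1 / tau_v) + ou_noise * eta;
      vel = v0 + v1;
    } else {
      vel = v_const;
    }
    pos = wrap_pi(pos + vel * dt);

    // 2. input + 3. Euler update of rates and depression
    double theta_mod = place_field_on
        ? 1.0 + Itheta * std::cos(2.0 * M_PI * f * t) : 0.0;
    for (int j = 0; j < N; ++j) xr[j] = xl[j] * rl[j];
    double sum_xr = 0.0;
    for (int j = 0; j < N; ++j) sum_xr += xr[j];
    // W %*% xr accumulated column-major (stride-1 access of W's storage)
    const double* wp = REAL(Wl);
    for (int i = 0; i < N; ++i) drive[i] = 0.0;
    for (int j = 0; j < N; ++j) {
      const double xrj = xr[j];
      const double* col = wp + (size_t)j * N;
      for (int i = 0; i < N; ++i) drive[i] += col[i] * xrj;
    }
    double lfp = 0.0;
    for (int i = 0; i < N; ++i) {
      double Ii;
      if (place_field_on) {
        Ii = tuned[i]
            ? I0 + IPF * std::cos(centers[i] - pos) * theta_mod
            : untuned_I0;
      } else {
        Ii = I0;
      }
      drive[i] = (drive[i] - wI * sum_xr) / N + Ii;
      lfp += drive[i];
    }
    lfp /= N;
    for (int i = 0; i < N; ++i) {
      double phi = linear_phi ? drive[i] : softplus(drive[i], alpha);
      double r_new = rl[i] + dt / tau * (-rl[i] + phi);
      double x_new = xl[i] + dt * ((1.0 - xl[i]) / tau_x - U0 * xl[i] * rl[i]);
      if (!std::isfinite(r_new) || !std::isfinite(x_new)) {
        stop("non-finite network state at t = %f (neuron %d)", t, i + 1);
      }
      rl[i] = r_new;
      xl[i] = x_new;
    }

    // 4. spike draws from the updated rates (always N uniforms, fixed order)
    spikers.clear();
    for (int i = 0; i < N; ++i) {
      double p = rl[i] * dt;
      if (p > 1.0) { p = 1.0; ++clip_warn; }
      double u = R::unif_rand();
      if (u < p) {
        spikers.push_back(i);
        if (record_spikes) { spk_id.push_back(i + 1); spk_t.push_back(t); }
      }
    }

    // 5. plasticity
    if (plast_on) {
      for (int i = 0; i < N; ++i) { r1[i] *= ep; o1[i] *= em; }
      if (triplet) for (int i = 0; i < N; ++i) { r2[i] *= ex; o2[i] *= ey; }
      if (!spikers.empty()) {
        // accumulate increments from pre-increment traces, then clip
        for (size_t k = 0; k < spikers.size(); ++k) {
          int i = spikers[k]; // postsynaptic spike: potentiate row i
          double amp = triplet ? (A2p + A3p * o2[i]) : A2p;
          for (int j = 0; j < N; ++j) {
            if (j != i) Wl(i, j) += amp * r1[j];
          }
        }
        for (size_t k = 0; k < spikers.size(); ++k) {
          int j = spikers[k]; // presynaptic spike: depress column j
          double amp = triplet ? (A2m + A3m * r2[j]) : A2m;
          for (int i = 0; i < N; ++i) {
            if (i != j) Wl(i, j) -= amp * o1[i];
          }
        }
        for (size_t k = 0; k < spikers.size(); ++k) {
          int s = spikers[k];
          r1[s] += 1.0; o1[s] += 1.0;
          if (triplet) { r2[s] += 1.0; o2[s] += 1.0; }
        }
        // only row i (post spike) and column j (pre spike) entries changed,
        // so clipping those is equivalent to clipping the full matrix
        for (size_t k = 0; k < spikers.size(); ++k) {
          int s = spikers[k];
          for (int j = 0; j < N; ++j) {
            if (Wl(s, j) < 0.0) Wl(s, j) = 0.0;
            else if (Wl(s, j) > wmax) Wl(s, j) = wmax;
            if (Wl(j, s) < 0.0) Wl(j, s) = 0.0;
            else if (Wl(j, s) > wmax) Wl(j, s) = wmax;
          }
        }
      }
    }

    if (record_every > 0 && step % record_every == 0) {
      rec_t[i_rec] = t; rec_pos[i_rec] = pos; rec_vel[i_rec] = vel;
      rec_lfp[i_rec] = lfp;
      for (int i = 0; i < N; ++i) { rec_r(i_rec, i) = rl[i]; rec_x(i_rec, i) = xl[i]; }
      ++i_rec;
    }
    if (snapshot_every > 0 && step % snapshot_every == 0) {
      snapshots[i_snap] = clone(Wl);
      snap_t[i_snap] = t;
      ++i_snap;
    }
  }

  return List::create(
    _["time"] = rec_t, _["rates"] = rec_r, _["depression"] = rec_x,
    _["position"] = rec_pos, _["velocity"] = rec_vel, _["lfp"] = rec_lfp,
    _["W"] = Wl, _["snapshots"] = snapshots, _["snapshot_times"] = snap_t,
    _["r"] = rl, _["x"] = xl, _["pos"] = pos, _["v1"] = v1,
    _["t_end"] = t0 + nsteps * dt,
    _["traces"] = List::create(_["r1"] = r1, _["o1"] = o1,
                               _["r2"] = r2, _["o2"] = o2),
    _["spike_id"] = wrap(spk_id), _["spike_time"] = wrap(spk_t),
    _["n_rate_clips"] = clip_warn);
}
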