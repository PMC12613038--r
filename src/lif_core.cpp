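#include <Rcpp.h>
using namespace Rcpp;

// Recurrent excitatory LIF network with rate-based Hebbian plasticity.
//
// Discretization (forward Euler, dt in ms):
//   u <- u + dt/tau_m * (u_rest - u) + inputs
// where inputs are instantaneous voltage jumps: recurrent spikes from the
// previous step add w_ij, and external/noise events add their configured
// jump (the spike time constant tau_s is far below dt, so pulses are
// charge-preserving impulses).  A neuron with u >= theta spikes and
// resets to u_rest within the step.
//
// Rates: nu <- nu * (1 - dt/tau_nu), +1 at a spike.  The rate threshold
// <nu> is the trailing boxcar mean of nu over the last t_w (excluding the
// current step).  Hebbian update on existing connections only:
//   dw = beta * d_i * d_j * (1 - [d_i<0][d_j<0]) * dt/dt_ref,  d = nu - <nu>
// clipped to [w_min, w_max].  beta is quoted as the per-step gain at the
// reference step dt_ref = 0.1 ms; scaling with dt keeps the drift per
// unit time invariant under step refinement.
//
// RNG: uses R's RNG via unif_rand(); per step the draw order is one
// uniform per neuron (noise) then one per stimulated target in ascending
// index order, so a pure-R implementation with the same seed reproduces
// the trajectory exactly.

// [[Rcpp::export]]
List lif_run_cpp(NumericMatrix W0, LogicalMatrix mask,
                 List neuron, List plast,
                 IntegerVector stim_id_per_step, List stim_targets,
                 NumericVector stim_rate_hz, NumericVector stim_jump_mv,
                 double noise_rate_hz, double noise_jump_mv,
                 double dt, bool plasticity_on,
                 int checkpoint_step, double const_drive_mv) {
  const int N = W0.nrow();
  const int n_steps = stim_id_per_step.size();
  NumericMatrix W = clone(W0);

  const double tau_m = as<double>(neuron["tau_m"]);
  const double u_rest = as<double>(neuron["u_rest"]);
  const double theta = as<double>(neuron["theta"]);

  const double beta = as<double>(plast["beta"]);
  const double tau_nu = as<double>(plast["tau_nu"]);
  const double t_w = as<double>(plast["t_w"]);
  const double w_min = as<double>(plast["w_min"]);
  const double w_max = as<double>(plast["w_max"]);

  const double p_noise = noise_rate_hz * dt * 1e-3;
  const double leak = dt / tau_m;
  const double rho = 1.0 - dt / tau_nu;
  const int wsteps = std::max(1, (int)std::lround(t_w / dt));

  // connection list over the mask
  std::vector<int> ci, cj;
  ci.reserve(N * N / 3);
  cj.reserve(N * N / 3);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (mask(i, j) && i != j) { ci.push_back(i); cj.push_back(j); }
  const int n_con = ci.size();

  std::vector<double> u(N, u_rest), nu(N, 0.0), nubar(N, 0.0), d(N, 0.0);
  std::vector<double> input(N, 0.0);
  std::vector<double> buf((size_t)wsteps * N, 0.0);
  std::vector<double> bufsum(N, 0.0);
  int buf_count = 0, buf_head = 0;
  std::vector<int> spiked_prev, spiked_now;
  spiked_prev.reserve(N);
  spiked_now.reserve(N);

  std::vector<int> out_step, out_neuron;
  NumericMatrix W_checkpoint;
  bool have_checkpoint = false;

  for (int s = 0; s < n_steps; ++s) {
    std::fill(input.begin(), input.end(), 0.0);
    // recurrent input from last step's spikes
    for (size_t k = 0; k < spiked_prev.size(); ++k) {
      int i = spiked_prev[k];
      for (int j = 0; j < N; ++j) input[j] += W(i, j);
    }
    // noise events: one uniform per neuron, in index order
    for (int j = 0; j < N; ++j)
      if (unif_rand() < p_noise) input[j] += noise_jump_mv;
    // stimulation events for the active stimulus
    int sid = stim_id_per_step[s];
    if (sid > 0) {
      IntegerVector tg = stim_targets[sid - 1];
      double p_stim = stim_rate_hz[sid - 1] * dt * 1e-3;
      double jump = stim_jump_mv[sid - 1];
      for (int k = 0; k < tg.size(); ++k)
        if (unif_rand() < p_stim) input[tg[k] - 1] += jump;
    }

    spiked_now.clear();
    for (int j = 0; j < N; ++j) {
      u[j] += leak * (u_rest - u[j] + const_drive_mv) + input[j];
      if (!R_finite(u[j])) stop("non-finite membrane potential at step %d", s + 1);
      if (u[j] >= theta) {
        u[j] = u_rest;
        spiked_now.push_back(j);
        out_step.push_back(s + 1);
        out_neuron.push_back(j + 1);
      }
    }

    // rate filter and trailing-average threshold
    for (int j = 0; j < N; ++j) nu[j] *= rho;
    for (size_t k = 0; k < spiked_now.size(); ++k) nu[spiked_now[k]] += 1.0;
    int denom = std::min(buf_count, wsteps);
    for (int j = 0; j < N; ++j) {
      nubar[j] = denom > 0 ? bufsum[j] / denom : 0.0;
      d[j] = nu[j] - nubar[j];
    }

    if (plasticity_on) {
      const double eta = beta * (dt / 0.04);  // dt_ref = 0.04 ms
      for (int c = 0; c < n_con; ++c) {
        double di = d[ci[c]], dj = d[cj[c]];
        if (di < 0 && dj < 0) continue;  // Heaviside gate: joint sub-threshold -> nothing
        double w = W(ci[c], cj[c]) + eta * di * dj;
        W(ci[c], cj[c]) = w < w_min ? w_min : (w > w_max ? w_max : w);
      }
    }

    // push nu into the boxcar buffer
    for (int j = 0; j < N; ++j) {
      double old = buf[(size_t)buf_head * N + j];
      buf[(size_t)buf_head * N + j] = nu[j];
      bufsum[j] += nu[j] - (buf_count >= wsteps ? old : 0.0);
    }
    buf_head = (buf_head + 1) % wsteps;
    if (buf_count < wsteps) ++buf_count;

    spiked_prev.swap(spiked_now);

    if (checkpoint_step > 0 && s + 1 == checkpoint_step) {
      W_checkpoint = clone(W);
      have_checkpoint = true;
    }
  }

  List out = List::create(
    _["W"] = W,
    _["spike_step"] = wrap(out_step),
    _["spike_neuron"] = wrap(out_neuron),
    _["u_final"] = wrap(u),
    _["nu_final"] = wrap(nu));
  if (have_checkpoint) out["W_checkpoint"] = W_checkpoint;
  return out;
}
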