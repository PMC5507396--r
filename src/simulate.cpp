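#include <Rcpp.h>
using namespace Rcpp;

// Transfer-function evaluation, mirroring the R-side definitions.
// kind: 0 = threshold_linear, 1 = threshold_powerlaw, 2 = exponential
static inline double eval_phi(int kind, double alpha, double p, double x) {
  switch (kind) {
  case 0: return x > 0.0 ? alpha * x : 0.0;
  case 1: return x > 0.0 ? alpha * std::pow(x, p) : 0.0;
  default: return alpha * std::exp(x);
  }
}

// Discrete-time simulation of the conditionally Poisson network.
//
// The alpha kernel g(t) = (t/tau^2) exp(-t/tau) is realized exactly as a
// cascade of two first-order stages with kernel exp(-t/tau)/tau each
// (their convolution is g). Per presynaptic neuron j we keep the cascade
// states s1_j, s2_j; the membrane inputs u = W s2 and the intermediate
// w = W s1 are propagated directly so each step costs O(N) plus O(N) per
// spike (sparse column updates), instead of an N x N matrix product:
//   s1' = a s1,  s2' = a (s2 + c s1),   a = exp(-dt/tau), c = dt/tau
//   =>  u' = a (u + c w),  w' = a w + (spikes_j / tau) W[, j].
// Rates use input accumulated from spikes strictly before the current
// step (Ito convention): counts are drawn first, state updated after.
// Counts are Poisson with mean r_i dt, drawn from R's RNG so R-side
// set.seed() controls reproducibility.
//
// Returns spike times/ids plus divergence metadata; the run stops at the
// first step where any rate exceeds rate_cap.
// [[Rcpp::export]]
List simulate_network_cpp(NumericMatrix W, NumericVector lambda,
                          IntegerVector kind, NumericVector alpha,
                          NumericVector p, double tau, double dt,
                          int n_steps, double rate_cap) {
  const int N = W.nrow();
  std::vector<double> u(N, 0.0), w(N, 0.0);
  std::vector<double> times;
  std::vector<int> ids;
  const double a = std::exp(-dt / tau);
  const double c = dt / tau;
  bool diverged = false;
  double div_time = NA_REAL;

  for (int step = 0; step < n_steps; ++step) {
    double t_now = step * dt;
    // rates from pre-step input
    for (int i = 0; i < N; ++i) {
      double r = eval_phi(kind[i], alpha[i], p[i], u[i] + lambda[i]);
      if (ISNAN(r))
        stop("NaN rate for neuron %d at step %d", i + 1, step + 1);
      if (r > rate_cap) {
        diverged = true;
        div_time = t_now;
        break;
      }
      int n_sp = (int) R::rpois(r * dt);
      if (n_sp > 0) {
        for (int k = 0; k < n_sp; ++k) {
          times.push_back(t_now);
          ids.push_back(i + 1);
        }
        // spikes enter stage 1 after this step's rates were computed
        double inc = n_sp / tau;
        for (int m = 0; m < N; ++m) w[m] += inc * W(m, i);
      }
    }
    if (diverged) break;
    for (int m = 0; m < N; ++m) {
      u[m] = a * (u[m] + c * w[m]);
      w[m] *= a;
    }
  }
  return List::create(_["time"] = times, _["neuron"] = ids,
                      _["diverged"] = diverged,
                      _["divergence_time"] = div_time);
}

// Deterministic synaptic-input trace for a prescribed spike train, using
// the identical state-space update as the simulator. Used to verify that
// the two-stage exponential cascade reproduces the alpha kernel.
// spike_step: 1-based step index of each spike; spike_neuron: 1-based id.
// [[Rcpp::export]]
NumericMatrix synaptic_input_trace_cpp(NumericMatrix W,
                                       IntegerVector spike_step,
                                       IntegerVector spike_neuron,
                                       double tau, double dt, int n_steps) {
  const int N = W.nrow();
  std::vector<double> u(N, 0.0), w(N, 0.0);
  NumericMatrix out(n_steps, N);
  const double a = std::exp(-dt / tau);
  const double c = dt / tau;
  int k = 0;
  for (int step = 0; step < n_steps; ++step) {
    for (int m = 0; m < N; ++m) out(step, m) = u[m];
    while (k < spike_step.size() && spike_step[k] == step + 1) {
      int j = spike_neuron[k] - 1;
      for (int m = 0; m < N; ++m) w[m] += W(m, j) / tau;
      ++k;
    }
    for (int m = 0; m < N; ++m) {
      u[m] = a * (u[m] + c * w[m]);
      w[m] *= a;
    }
  }
  return out;
}
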