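# Small fixture builders shared across tests. All fixtures are built in
# code; seeds are fixed where randomness is involved.

# single linearly self-exciting unit: rate = eps * (g * dN/dt) + lambda
scalar_linear_net <- function(eps = 0.5, lambda = 0.1, tau = 10) {
  network_model(matrix(eps, 1, 1), filter = synaptic_filter(tau),
                transfer = transfer_function("threshold_linear", alpha = 1),
                baseline = lambda)
}

# single quadratically self-exciting unit with positive operating point
scalar_quad_net <- function(w = 0.4, lambda = 0.2, alpha = 0.1, tau = 10) {
  network_model(matrix(w, 1, 1), filter = synaptic_filter(tau),
                transfer = transfer_function("threshold_powerlaw",
                                             alpha = alpha, p = 2),
                baseline = lambda)
}

# 2-neuron quadratic toy: self-exciting unit driving a second neuron
toy_quad_2 <- function(w_self = 0.3, w_ff = 0.5, lambda = 0.25) {
  W <- matrix(c(w_self, w_ff, 0, 0), 2, 2)
  network_model(W, transfer = transfer_function("threshold_powerlaw",
                                                alpha = 0.1, p = 2),
                baseline = lambda)
}

# 3-neuron mixed toy: E-E-I triangle with quadratic transfer, all inputs
# positive at the operating point so phi2 > 0 everywhere
toy_quad_3 <- function(scale = 1) {
  W <- scale * matrix(c(0.2, 0.4, 0.3,
                        0.3, 0.0, 0.2,
                        -0.2, -0.3, 0.0), 3, 3)
  network_model(W, cell_type = c("E", "E", "I"),
                transfer = transfer_function("threshold_powerlaw",
                                             alpha = 0.1, p = 2),
                baseline = c(0.4, 0.35, 0.3))
}

# reduced-size quadratic E-I random network for unit tests
small_er_quad <- function(W_EE = 0.4, seed = 7) {
  make_er_ei_network(
    ei_network_params(N_E = 40, N_I = 8, W_EE = W_EE, seed = seed),
    transfer = transfer_function("threshold_powerlaw", alpha = 0.1, p = 2),
    baseline = 0.1)
}

# hand-built spike_data: homogeneous Poisson trains (no simulator involved)
poisson_spike_data <- function(rates, T = 1e4, burn_in = 0, seed = 1) {
  set.seed(seed)
  ev <- purrr::map_dfr(seq_along(rates), function(i) {
    n <- stats::rpois(1, rates[i] * T)
    tibble::tibble(time = sort(stats::runif(n, 0, T)), neuron = i)
  })
  ev <- ev[order(ev$time), ]
  structure(list(events = ev, n_neurons = length(rates), T = T,
                 T_effective = T, burn_in = burn_in, diverged = FALSE,
                 divergence_time = NA_real_, dt = 0.1, seed = seed),
            class = "spike_data")
}
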