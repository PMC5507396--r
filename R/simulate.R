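#' Simulation configuration
#'
#' @param T Duration, ms.
#' @param dt Time step, ms (default 0.1; halving it should change
#'   stationary rate estimates by well under the Monte-Carlo error).
#' @param seed RNG seed.
#' @param burn_in Initial transient discarded by the estimators, ms
#'   (default 10 filter time constants).
#' @param rate_cap Divergence sentinel: the run stops, and is flagged
#'   diverged, at the first step where any instantaneous rate exceeds this
#'   value (ms^-1). Statistics are then taken over the pre-divergence
#'   window.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(T = 1e4, dt = 0.1, seed = 1L, burn_in = 100,
                       rate_cap = 1e3) {
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (T <= burn_in || burn_in < 0) stop("need T > burn_in >= 0", call. = FALSE)
  structure(list(T = T, dt = dt, seed = as.integer(seed),
                 burn_in = burn_in, rate_cap = rate_cap),
            class = "sim_config")
}

new_spike_data <- function(events, n_neurons, T, burn_in, diverged,
                           divergence_time, dt, seed) {
  structure(list(events = events, n_neurons = n_neurons, T = T,
                 T_effective = if (diverged) divergence_time else T,
                 burn_in = burn_in, diverged = diverged,
                 divergence_time = if (diverged) divergence_time else NA_real_,
                 dt = dt, seed = seed),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("<spike_data> %d events, %d neurons, T = %g ms%s\n",
              nrow(x$events), x$n_neurons, x$T,
              if (x$diverged) sprintf(" (DIVERGED at %g ms)", x$divergence_time)
              else ""))
  invisible(x)
}

transfer_codes <- function(net) {
  kinds <- vapply(net$transfer, `[[`, "", "kind")
  list(kind = match(kinds, c("threshold_linear", "threshold_powerlaw",
                             "exponential")) - 1L,
       alpha = vapply(net$transfer, `[[`, 0, "alpha"),
       p = vapply(net$transfer, function(tf) tf$p %||% 1, 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the conditionally Poisson spiking network
#'
#' Draws an exact (up to time discretization) sample path of the network:
#' at each step of size `dt` every neuron emits a Poisson-distributed
#' number of spikes with mean \eqn{r_i(t)\,dt}, where the rate is the
#' transfer function of the synaptically filtered input accumulated from
#' spikes strictly before the current step (Ito convention). The shared
#' alpha kernel is realized exactly as a cascade of two exponential
#' stages, so the per-step cost is linear in network size. A run whose
#' instantaneous rate exceeds the configured cap stops there and is
#' flagged diverged.
#'
#' @param net A [network_model()].
#' @param cfg A [sim_config()].
#'
#' @return A `spike_data` object: `events` is a tibble with columns
#'   `time` (ms) and `neuron` (1-based), plus duration, burn-in and
#'   divergence metadata.
#' @examples
#' net <- network_model(matrix(0, 1, 1),
#'                      transfer = transfer_function("threshold_linear", alpha = 0.1),
#'                      baseline = 10)
#' sim <- simulate_network(net, sim_config(T = 1000, seed = 1))
#' @export
simulate_network <- function(net, cfg = sim_config()) {
  stopifnot(inherits(net, "network_model"), inherits(cfg, "sim_config"))
  tc <- transfer_codes(net)
  set.seed(cfg$seed)
  res <- simulate_network_cpp(net$W, net$baseline, tc$kind, tc$alpha, tc$p,
                              net$filter$tau, cfg$dt,
                              as.integer(round(cfg$T / cfg$dt)), cfg$rate_cap)
  events <- tibble::tibble(time = res$time, neuron = as.integer(res$neuron))
  if (res$diverged) events <- events[events$time < res$divergence_time, ]
  new_spike_data(events, net$N, cfg$T, cfg$burn_in,
                 res$diverged, res$divergence_time, cfg$dt, cfg$seed)
}

#' Binned spike counts
#'
#' Integer count matrix over `[burn_in, T_effective)` with the given bin
#' width; rows are bins, columns neurons.
#'
#' @param spikes A `spike_data` object.
#' @param bin Bin width, ms (must be >= the simulation step).
#' @return Integer matrix `n_bins x n_neurons`.
#' @export
bin_spike_counts <- function(spikes, bin = 1) {
  stopifnot(inherits(spikes, "spike_data"))
  if (bin < spikes$dt) stop("`bin` must be at least the simulation step", call. = FALSE)
  t0 <- spikes$burn_in
  t1 <- spikes$T_effective
  n_bins <- floor((t1 - t0) / bin)
  if (n_bins < 1) stop("window shorter than one bin", call. = FALSE)
  counts <- matrix(0L, n_bins, spikes$n_neurons)
  ev <- spikes$events
  keep <- ev$time >= t0 & ev$time < t0 + n_bins * bin
  if (any(keep)) {
    b <- floor((ev$time[keep] - t0) / bin) + 1
    tab <- table(factor(b, levels = seq_len(n_bins)),
                 factor(ev$neuron[keep], levels = seq_len(spikes$n_neurons)))
    counts <- matrix(as.integer(tab), n_bins, spikes$n_neurons)
  }
  counts
}

#' Fano factors of binned spike counts
#'
#' Variance-to-mean ratio per neuron; 1 for Poisson counts, and for a
#' self-exciting unit with branching ratio \eqn{\epsilon} it approaches
#' \eqn{1/(1-\epsilon)^2} at large bins.
#'
#' @param counts A count matrix from [bin_spike_counts()].
#' @return Numeric vector of per-neuron Fano factors (NaN for silent
#'   neurons).
#' @export
fano_factor <- function(counts) {
  apply(counts, 2, function(x) stats::var(x) / mean(x))
}

#' Impulse response of the simulator's synaptic state
#'
#' Drives the simulator's exact two-stage synaptic state with a prescribed
#' spike train and returns the resulting membrane-input traces; with a
#' single spike this reproduces [filter_kernel()] scaled by the weight, up
#' to O(dt) time discretization.
#'
#' @param net A [network_model()].
#' @param spike_times,spike_neurons Prescribed spikes (times in ms,
#'   1-based neuron ids).
#' @param T,dt Trace duration and step, ms.
#' @return A tibble with columns `time` and `input_1`, ..., `input_N`.
#' @export
synaptic_input_trace <- function(net, spike_times, spike_neurons, T, dt = 0.1) {
  stopifnot(inherits(net, "network_model"))
  ord <- order(spike_times)
  steps <- as.integer(floor(spike_times[ord] / dt)) + 1L
  tr <- synaptic_input_trace_cpp(net$W, steps, as.integer(spike_neurons[ord]),
                                 net$filter$tau, dt, as.integer(round(T / dt)))
  colnames(tr) <- paste0("input_", seq_len(net$N))
  dplyr::bind_cols(tibble::tibble(time = dt * (seq_len(nrow(tr)) - 1L)),
                   tibble::as_tibble(tr))
}

#' Write / read spike events as delimited text with a JSON sidecar
#'
#' Events go to a two-column tab-separated file (`time_ms`, `neuron_id`);
#' seed, step, duration and divergence metadata go to `<path>.json`.
#'
#' @param spikes A `spike_data` object.
#' @param path Event-file path.
#' @export
write_spike_events <- function(spikes, path) {
  utils::write.table(
    data.frame(time_ms = spikes$events$time, neuron_id = spikes$events$neuron),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- spikes[c("n_neurons", "T", "T_effective", "burn_in", "diverged",
                   "divergence_time", "dt", "seed")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
read_spike_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new_spike_data(tibble::tibble(time = ev$time_ms,
                                neuron = as.integer(ev$neuron_id)),
                 meta$n_neurons, meta$T, meta$burn_in, meta$diverged,
                 if (isTRUE(meta$diverged)) meta$divergence_time else NA_real_,
                 meta$dt, meta$seed)
}
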