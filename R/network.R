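#' Parameters for an excitatory-inhibitory random network
#'
#' Defaults follow the standard study conditions used throughout the
#' experiments: 200 excitatory and 40 inhibitory neurons, E-E connection
#' probability 0.2 and 0.5 for the other blocks, and weight ratios
#' (W_EE, W_EI, W_IE, W_II)/W_EE = (1, -4, 0.4, -4), under which the mean
#' net inhibitory input weight onto a neuron is twice the mean net
#' excitatory input weight.
#'
#' @param N_E,N_I Numbers of excitatory and inhibitory neurons.
#' @param p_EE,p_EI,p_IE,p_II Connection probabilities in `[0, 1]`;
#'   `p_XY` is the probability of a connection from a type-Y neuron onto a
#'   type-X neuron.
#' @param W_EE Base excitatory-excitatory synaptic weight, mV.
#' @param weight_ratios Length-4 vector scaling (W_EE, W_EI, W_IE, W_II)
#'   relative to `W_EE`; first entry must be 1, entries 2 and 4 must be
#'   non-positive (inhibitory columns), entry 3 non-negative.
#' @param seed RNG seed used when the network is generated.
#'
#' @return An object of class `ei_network_params`.
#' @export
ei_network_params <- function(N_E = 200, N_I = 40,
                              p_EE = 0.2, p_EI = 0.5, p_IE = 0.5, p_II = 0.5,
                              W_EE = 0.025,
                              weight_ratios = c(1, -4, 0.4, -4),
                              seed = 1L) {
  probs <- c(p_EE = p_EE, p_EI = p_EI, p_IE = p_IE, p_II = p_II)
  if (any(probs < 0 | probs > 1)) stop("connection probabilities must lie in [0, 1]", call. = FALSE)
  if (N_E < 1 || N_I < 1) stop("N_E and N_I must be >= 1", call. = FALSE)
  if (length(weight_ratios) != 4 || weight_ratios[1] != 1 ||
      weight_ratios[2] > 0 || weight_ratios[4] > 0 || weight_ratios[3] < 0)
    stop("`weight_ratios` must be (1, <=0, >=0, <=0)", call. = FALSE)
  structure(list(N_E = as.integer(N_E), N_I = as.integer(N_I),
                 p_EE = p_EE, p_EI = p_EI, p_IE = p_IE, p_II = p_II,
                 W_EE = W_EE, weight_ratios = weight_ratios,
                 seed = as.integer(seed)),
            class = "ei_network_params")
}

#' Network model container
#'
#' Bundles a synaptic weight matrix with the shared synaptic filter,
#' per-neuron transfer functions and baseline drives. The conditional
#' intensity of neuron i is
#' \eqn{r_i(t) = \phi_i\big(\sum_j W_{ij} (g * dN_j/dt)(t) + \lambda_i\big)},
#' with `W[i, j]` the weight of the connection from neuron j onto neuron i.
#'
#' @param W N x N weight matrix in mV (rows postsynaptic). The diagonal
#'   need not be zero; the standard generators produce autapse-free
#'   matrices obeying Dale's law.
#' @param cell_type Character vector of `"E"`/`"I"` labels, length N.
#' @param filter A [synaptic_filter()].
#' @param transfer A single [transfer_function()] shared by all neurons, or
#'   a list of length N.
#' @param baseline Baseline drives \eqn{\lambda_i} in mV; scalar or length N.
#'
#' @return An object of class `network_model`.
#' @export
network_model <- function(W, cell_type = NULL, filter = synaptic_filter(),
                          transfer = transfer_function("threshold_powerlaw"),
                          baseline = 0.1) {
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("`W` must be square", call. = FALSE)
  N <- nrow(W)
  if (is.null(cell_type)) cell_type <- rep("E", N)
  if (length(cell_type) != N || !all(cell_type %in% c("E", "I")))
    stop("`cell_type` must be length-N E/I labels", call. = FALSE)
  if (inherits(transfer, "transfer_function")) transfer <- rep(list(transfer), N)
  if (length(transfer) != N || !all(vapply(transfer, inherits, TRUE, "transfer_function")))
    stop("`transfer` must be one transfer_function or a list of N", call. = FALSE)
  baseline <- rep_len(as.numeric(baseline), N)
  structure(list(W = W, cell_type = cell_type, filter = filter,
                 transfer = transfer, baseline = baseline, N = N),
            class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> N = %d (%d E, %d I), %s filter tau = %g ms\n",
              x$N, sum(x$cell_type == "E"), sum(x$cell_type == "I"),
              x$filter$kind, x$filter$tau))
  kinds <- unique(vapply(x$transfer, `[[`, "", "kind"))
  cat(sprintf("  transfer: %s; baseline range [%g, %g] mV\n",
              paste(kinds, collapse = ", "), min(x$baseline), max(x$baseline)))
  invisible(x)
}

type_weights <- function(params) {
  w <- params$W_EE * params$weight_ratios
  names(w) <- c("EE", "EI", "IE", "II")
  w
}

#' Generate an Erdos-Renyi excitatory-inhibitory network
#'
#' Each ordered off-diagonal pair (i, j) is connected independently with
#' probability `p_{type(i), type(j)}`; a present connection from an E neuron
#' carries the (positive) type weight and from an I neuron the (negative)
#' type weight, so the matrix obeys Dale's law by construction. Autapses
#' are excluded (zero diagonal).
#'
#' @param params An [ei_network_params()].
#' @param filter,transfer,baseline Passed to [network_model()]. `baseline`
#'   may be a named vector `c(E = ..., I = ...)` to give the two populations
#'   different drives.
#'
#' @return A [network_model()] with neurons ordered E first, then I.
#' @examples
#' net <- make_er_ei_network(ei_network_params(N_E = 20, N_I = 4, seed = 1))
#' @export
make_er_ei_network <- function(params,
                               filter = synaptic_filter(),
                               transfer = transfer_function("threshold_powerlaw"),
                               baseline = 0.1) {
  stopifnot(inherits(params, "ei_network_params"))
  set.seed(params$seed)
  N_E <- params$N_E; N_I <- params$N_I; N <- N_E + N_I
  cell_type <- rep(c("E", "I"), c(N_E, N_I))
  w <- type_weights(params)
  P <- matrix(0, N, N); Wv <- matrix(0, N, N)
  eidx <- seq_len(N_E); iidx <- N_E + seq_len(N_I)
  P[eidx, eidx] <- params$p_EE; Wv[eidx, eidx] <- w["EE"]
  P[eidx, iidx] <- params$p_EI; Wv[eidx, iidx] <- w["EI"]
  P[iidx, eidx] <- params$p_IE; Wv[iidx, eidx] <- w["IE"]
  P[iidx, iidx] <- params$p_II; Wv[iidx, iidx] <- w["II"]
  A <- matrix(stats::runif(N * N) < P, N, N)
  diag(A) <- FALSE
  W <- A * Wv
  network_model(W, cell_type, filter, transfer,
                baseline_by_type(baseline, cell_type))
}

baseline_by_type <- function(baseline, cell_type) {
  if (!is.null(names(baseline)) && all(c("E", "I") %in% names(baseline)))
    unname(baseline[cell_type])
  else baseline
}

#' Write / read a dense weight matrix as delimited text
#'
#' Rows are postsynaptic neurons; values are tab-separated, no header.
#'
#' @param W Weight matrix.
#' @param path File path.
#' @export
write_weight_matrix <- function(W, path) {
  utils::write.table(as.matrix(W), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write / read cell-type labels as two-column delimited text
#'
#' Columns are the 1-based neuron index and the E/I label.
#'
#' @param cell_type Character vector of `"E"`/`"I"`.
#' @param path File path.
#' @export
write_cell_types <- function(cell_type, path) {
  utils::write.table(data.frame(index = seq_along(cell_type), type = cell_type),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_types
#' @export
read_cell_types <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("integer", "character"))
  df$type[order(df$index)]
}
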