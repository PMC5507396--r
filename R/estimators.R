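#' Estimate per-neuron firing rates with block-bootstrap errors
#'
#' Rates are spike counts divided by the usable window
#' `[burn_in, T_effective)`; for diverged runs this is the pre-divergence
#' window, and the divergence flag is propagated. Standard errors come
#' from the dispersion of rates over disjoint time blocks.
#'
#' @param spikes A `spike_data` object.
#' @param n_blocks Number of disjoint blocks for the standard error.
#' @return A tibble with columns `neuron`, `rate` (ms^-1), `se`, and a
#'   `diverged` attribute-carrying column.
#' @export
estimate_rates <- function(spikes, n_blocks = 20L) {
  stopifnot(inherits(spikes, "spike_data"))
  t0 <- spikes$burn_in; t1 <- spikes$T_effective
  if (t1 <= t0) stop("no usable window after burn-in", call. = FALSE)
  Tw <- t1 - t0
  ev <- spikes$events[spikes$events$time >= t0 & spikes$events$time < t1, ]
  counts <- tabulate(ev$neuron, nbins = spikes$n_neurons)
  blk <- pmin(floor((ev$time - t0) / (Tw / n_blocks)) + 1, n_blocks)
  bc <- matrix(0, n_blocks, spikes$n_neurons)
  if (nrow(ev) > 0) {
    tab <- table(factor(blk, levels = seq_len(n_blocks)),
                 factor(ev$neuron, levels = seq_len(spikes$n_neurons)))
    bc <- matrix(as.numeric(tab), n_blocks, spikes$n_neurons)
  }
  block_rates <- bc / (Tw / n_blocks)
  tibble::tibble(
    neuron = seq_len(spikes$n_neurons),
    rate = counts / Tw,
    se = apply(block_rates, 2, stats::sd) / sqrt(n_blocks),
    diverged = spikes$diverged)
}

summed_binned_train <- function(spikes, subset, bin) {
  counts <- bin_spike_counts(spikes, bin)
  rowSums(counts[, subset, drop = FALSE])
}

# all-lag integral of the autocovariance of one binned train, Bartlett
# truncation at max_lag; returns units of ms^-1 (counts^2 per ms)
integrated_acov <- function(x, bin, max_lag) {
  L <- min(length(x) - 1L, floor(max_lag / bin))
  ac <- stats::acf(x, lag.max = L, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  (ac[1] + 2 * sum(ac[-1])) / bin
}

integrated_ccov <- function(x, y, bin, max_lag) {
  L <- min(length(x) - 1L, floor(max_lag / bin))
  cc <- stats::ccf(x, y, lag.max = L, type = "covariance", plot = FALSE,
                   demean = TRUE)$acf[, 1, 1]
  sum(cc) / bin
}

#' Integrated autocovariance of a summed population spike train
#'
#' Empirical counterpart of [integrated_population_variance()]: the summed
#' spike train of the subset is binned, its autocovariance estimated over
#' lags up to `max_lag`, and summed times the bin width (the zero-lag bin
#' carries the point-process variance contribution). The standard error
#' comes from recomputing the estimate on disjoint time blocks.
#'
#' @param spikes A `spike_data` object.
#' @param subset Neuron indices (default all).
#' @param bin Bin width, ms.
#' @param max_lag Truncation lag of the autocovariance sum, ms; should be
#'   much larger than the synaptic time constant.
#' @param n_blocks Number of disjoint blocks for the standard error.
#' @return A tibble with columns `estimate` (ms^-1), `se`, `bin`,
#'   `max_lag`, `T_used`.
#' @export
estimate_integrated_population_autocov <- function(spikes, subset = NULL,
                                                   bin = 2, max_lag = 500,
                                                   n_blocks = 20L) {
  stopifnot(inherits(spikes, "spike_data"))
  if (is.null(subset)) subset <- seq_len(spikes$n_neurons)
  Tw <- spikes$T_effective - spikes$burn_in
  if (Tw < 10 * max_lag)
    warning("usable window < 10 * max_lag; expect a wide standard error",
            call. = FALSE)
  x <- summed_binned_train(spikes, subset, bin)
  est <- integrated_acov(x, bin, max_lag)
  nb <- max(2L, min(n_blocks, floor(length(x) * bin / (4 * max_lag))))
  splits <- split(x, cut(seq_along(x), nb, labels = FALSE))
  bvals <- vapply(splits, integrated_acov, numeric(1), bin = bin,
                  max_lag = max_lag)
  tibble::tibble(estimate = est, se = stats::sd(bvals) / sqrt(nb),
                 bin = bin, max_lag = max_lag, T_used = Tw)
}

#' Integrated cross-covariances for chosen neuron pairs
#'
#' All-lag integral of the empirical cross-covariance function for each
#' requested pair; the integrated quantity is symmetric in the pair order.
#'
#' @param spikes A `spike_data` object.
#' @param pairs Two-column matrix (or data frame) of neuron index pairs.
#' @param bin,max_lag,n_blocks As in
#'   [estimate_integrated_population_autocov()].
#' @return A tibble with columns `i`, `j`, `estimate` (ms^-1), `se`.
#' @export
estimate_integrated_cross_cov <- function(spikes, pairs, bin = 2,
                                          max_lag = 500, n_blocks = 20L) {
  stopifnot(inherits(spikes, "spike_data"))
  pairs <- as.matrix(pairs)
  counts <- bin_spike_counts(spikes, bin)
  nb <- max(2L, min(n_blocks, floor(nrow(counts) * bin / (4 * max_lag))))
  grp <- cut(seq_len(nrow(counts)), nb, labels = FALSE)
  purrr::map_dfr(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    est <- integrated_ccov(counts[, i], counts[, j], bin, max_lag)
    bvals <- vapply(seq_len(nb), function(b) {
      sel <- grp == b
      integrated_ccov(counts[sel, i], counts[sel, j], bin, max_lag)
    }, numeric(1))
    tibble::tibble(i = i, j = j, estimate = est,
                   se = stats::sd(bvals) / sqrt(nb))
  })
}

#' Count-variance estimate of the integrated autocovariance (cross-check)
#'
#' Variance of the summed-train counts in long windows divided by the
#' window length converges to the same all-lag integral as the
#' lag-windowed estimator; provided as an independent cross-check.
#'
#' @param spikes A `spike_data` object.
#' @param subset Neuron indices (default all).
#' @param window Window length, ms.
#' @return Scalar estimate, ms^-1.
#' @export
count_variance_autocov <- function(spikes, subset = NULL, window = 1000) {
  if (is.null(subset)) subset <- seq_len(spikes$n_neurons)
  x <- summed_binned_train(spikes, subset, window)
  stats::var(x) / window
}

#' Export estimates as a delimited table
#'
#' @param estimates A tibble of estimates (any of the estimator outputs).
#' @param path File path; tab-separated with a header.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.table(estimates, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
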