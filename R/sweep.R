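#' Configuration for a synaptic-weight sweep experiment
#'
#' Describes one of the standard experiments: scale all synaptic weights
#' proportionally (the E-E weight is the sweep variable), and at each
#' weight compute tree-level and one-loop predictions for the E-population
#' rates, the integrated population autocovariance, and stability, and
#' estimate the same observables from a simulation.
#'
#' @param ensemble `"er"` (Erdos-Renyi) or `"heavytail"` (copula-coupled
#'   power-law degrees with lognormal E-E weights; the sweep variable is
#'   then the mean E-E weight, attainable means being >= exp(-1/2) under
#'   the equal location/scale convention).
#' @param W_EE_grid Increasing grid of E-E weights (mV).
#' @param transfer A [transfer_function()] shared by all neurons.
#' @param baseline Baseline drive(s), mV; named `c(E = , I = )` or scalar.
#' @param params An [ei_network_params()] (its `W_EE` is overridden by the
#'   grid).
#' @param degree_spec A [degree_spec()] for the heavy-tailed ensemble.
#' @param sim A [sim_config()] used at every grid point (its seed is
#'   advanced per point).
#' @param grid_n,omega_max Frequency-grid resolution used for the theory.
#' @param network_seed Seed for network generation.
#' @param subset Population whose summed-train variance is reported:
#'   `"E"`, `"I"` or `"all"`.
#'
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(ensemble = c("er", "heavytail"),
                         W_EE_grid = seq(0.025, 0.2, by = 0.025),
                         transfer = transfer_function("threshold_powerlaw"),
                         baseline = 0.1,
                         params = ei_network_params(),
                         degree_spec = NULL,
                         sim = sim_config(T = 2e4),
                         grid_n = 2^10 + 1, omega_max = NULL,
                         network_seed = 1L,
                         subset = "E") {
  ensemble <- match.arg(ensemble)
  if (length(W_EE_grid) < 1 || is.unsorted(W_EE_grid, strictly = TRUE))
    stop("`W_EE_grid` must be nonempty and strictly increasing", call. = FALSE)
  structure(list(ensemble = ensemble, W_EE_grid = W_EE_grid,
                 transfer = transfer, baseline = baseline, params = params,
                 degree_spec = degree_spec, sim = sim, grid_n = grid_n,
                 omega_max = omega_max, network_seed = as.integer(network_seed),
                 subset = subset),
            class = "sweep_config")
}

sweep_network <- function(cfg, W_EE) {
  p <- cfg$params
  p$W_EE <- W_EE
  p$seed <- cfg$network_seed
  if (cfg$ensemble == "er") {
    make_er_ei_network(p, transfer = cfg$transfer, baseline = cfg$baseline)
  } else {
    make_heavytail_network(p, spec = cfg$degree_spec,
                           lognorm_location = lognorm_location_for_mean(W_EE),
                           transfer = cfg$transfer, baseline = cfg$baseline)
  }
}

subset_indices <- function(net, subset) {
  switch(subset,
         E = which(net$cell_type == "E"),
         I = which(net$cell_type == "I"),
         all = seq_len(net$N),
         stop("unknown subset", call. = FALSE))
}

#' Run a synaptic-weight sweep
#'
#' For each weight on the grid: generate the network, solve the mean
#' field, and, while the tree-level radius is below 1, compute the
#' tree-level and one-loop predictions for the mean E rate, the integrated
#' autocovariance of the summed population train, and the stability
#' measures; then simulate and estimate the same observables. Theory
#' columns are NA wherever the tree-level theory does not exist
#' (non-converged mean field or radius >= 1); simulation is always
#' attempted and divergence recorded. Per-point failures are caught,
#' logged as messages, and marked, and the sweep continues.
#'
#' @param cfg A [sweep_config()].
#' @param progress Emit a message per grid point.
#'
#' @return A `sweep_result` tibble, one row per weight, with columns
#'   `W_EE`, `rate_tree`, `rate_one_loop`, `rate_sim`, `rate_sim_se`,
#'   `var_tree`, `var_one_loop`, `var_sim`, `var_sim_se`, `radius_tree`,
#'   `radius_one_loop`, `diverged`, `mf_converged`.
#' @export
run_sweep <- function(cfg, progress = FALSE) {
  stopifnot(inherits(cfg, "sweep_config"))
  rows <- purrr::map(seq_along(cfg$W_EE_grid), function(k) {
    W_EE <- cfg$W_EE_grid[k]
    if (progress) message(sprintf("sweep point %d/%d: W_EE = %g",
                                  k, length(cfg$W_EE_grid), W_EE))
    row <- tibble::tibble(
      W_EE = W_EE, rate_tree = NA_real_, rate_one_loop = NA_real_,
      rate_sim = NA_real_, rate_sim_se = NA_real_,
      var_tree = NA_real_, var_one_loop = NA_real_,
      var_sim = NA_real_, var_sim_se = NA_real_,
      radius_tree = NA_real_, radius_one_loop = NA_real_,
      diverged = NA, mf_converged = NA)
    net <- sweep_network(cfg, W_EE)
    sub <- subset_indices(net, cfg$subset)
    mf <- solve_mean_field(net)
    row$mf_converged <- mf$converged
    if (mf$converged) {
      row$radius_tree <- stability_spectral_radius(net, mf)
      if (row$radius_tree < 1) {
        th <- tryCatch({
          grid <- frequency_grid(omega_max = cfg$omega_max, n = cfg$grid_n,
                                 tau = net$filter$tau)
          fr <- propagator(net, mf, grid, store = "F")
          r1 <- one_loop_rate(fr, mf, net)
          C0 <- tree_integrated_covariance(fr, mf)
          C1 <- one_loop_two_point(fr, mf, net)
          list(rate_tree = mean(mf$rbar[sub]),
               rate_one_loop = mean((mf$rbar + r1)[sub]),
               var_tree = sum(C0[sub, sub]),
               var_one_loop = sum((C0 + C1)[sub, sub]),
               radius_one_loop = corrected_stability(net, mf, fr))
        }, error = function(e) {
          message(sprintf("theory failed at W_EE = %g: %s", W_EE,
                          conditionMessage(e)))
          NULL
        })
        if (!is.null(th)) {
          row$rate_tree <- th$rate_tree
          row$rate_one_loop <- th$rate_one_loop
          row$var_tree <- th$var_tree
          row$var_one_loop <- th$var_one_loop
          row$radius_one_loop <- th$radius_one_loop
        }
      }
    }
    sim_out <- tryCatch({
      scfg <- cfg$sim
      scfg$seed <- cfg$sim$seed + k
      sim <- simulate_network(net, scfg)
      rates <- estimate_rates(sim)
      pv <- estimate_integrated_population_autocov(sim, subset = sub)
      list(rate = mean(rates$rate[sub]),
           rate_se = sqrt(sum(rates$se[sub]^2)) / length(sub),
           var = pv$estimate, var_se = pv$se, diverged = sim$diverged)
    }, error = function(e) {
      message(sprintf("simulation failed at W_EE = %g: %s", W_EE,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(sim_out)) {
      row$rate_sim <- sim_out$rate
      row$rate_sim_se <- sim_out$rate_se
      row$var_sim <- sim_out$var
      row$var_sim_se <- sim_out$var_se
      row$diverged <- sim_out$diverged
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("sweep_result", class(out))
  attr(out, "config") <- cfg
  out
}

#' Tidy a sweep result into long observable/source form
#'
#' @param x A `sweep_result`.
#' @param ... Unused.
#' @return A long tibble with columns `W_EE`, `observable`
#'   (rate/variance/radius), `source` (tree/one_loop/sim), `value`, `se`.
#' @export
tidy.sweep_result <- function(x, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(x)[c("W_EE", "rate_tree", "rate_one_loop", "rate_sim",
                           "var_tree", "var_one_loop", "var_sim",
                           "radius_tree", "radius_one_loop")],
    -"W_EE", names_to = c("observable", "source"),
    names_pattern = "(rate|var|radius)_(.*)", values_to = "value")
  se <- tidyr::pivot_longer(
    tibble::as_tibble(x)[c("W_EE", "rate_sim_se", "var_sim_se")],
    -"W_EE", names_to = "observable", names_pattern = "(rate|var)_sim_se",
    values_to = "se")
  se$source <- "sim"
  dplyr::left_join(long, se, by = c("W_EE", "observable", "source"))
}

#' Plot a sweep result
#'
#' Three faceted panels against the E-E weight: mean E rate, integrated
#' population autocovariance, and the stability measures; lines are
#' tree-level and one-loop theory, dots simulation.
#'
#' @param object A `sweep_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export autoplot
#' @export
autoplot.sweep_result <- function(object, ...) {
  long <- tidy(object)
  lines <- long[long$source != "sim", ]
  dots <- long[long$source == "sim", ]
  ggplot2::ggplot(lines, ggplot2::aes(x = .data$W_EE, y = .data$value,
                                      colour = .data$source)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dots) +
    ggplot2::geom_errorbar(
      data = dots,
      ggplot2::aes(ymin = .data$value - .data$se,
                   ymax = .data$value + .data$se), width = 0) +
    ggplot2::facet_wrap(~.data$observable, scales = "free_y") +
    ggplot2::labs(x = "E-E synaptic weight (mV)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Raster plot of simulated spikes
#'
#' @param object A `spike_data` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spike_data <- function(object, ...) {
  ggplot2::ggplot(object$events,
                  ggplot2::aes(x = .data$time, y = .data$neuron)) +
    ggplot2::geom_point(shape = ".", alpha = 0.6) +
    ggplot2::labs(x = "time (ms)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Export a sweep result table
#'
#' @param x A `sweep_result`.
#' @param path Tab-separated output path; a `<path>.json` sidecar records
#'   the sweep configuration summary.
#' @export
write_sweep_result <- function(x, path) {
  utils::write.table(tibble::as_tibble(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- attr(x, "config")
  if (!is.null(cfg)) {
    meta <- list(ensemble = cfg$ensemble, W_EE_grid = cfg$W_EE_grid,
                 transfer = cfg$transfer$kind, alpha = cfg$transfer$alpha,
                 p = cfg$transfer$p, baseline = cfg$baseline,
                 T = cfg$sim$T, dt = cfg$sim$dt, sim_seed = cfg$sim$seed,
                 network_seed = cfg$network_seed, grid_n = cfg$grid_n)
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
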