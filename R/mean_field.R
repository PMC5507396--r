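#' Solve the stationary mean-field rate equations
#'
#' Finds the self-consistent stationary rates
#' \eqn{\bar r_i = \phi_i\big((W \bar r)_i + \lambda_i\big)} by damped
#' Picard (fixed-point) iteration; since the synaptic kernel integrates to
#' 1, the stationary convolution \eqn{(g * \bar r)} reduces to \eqn{\bar r}.
#' Iteration starts from the uncoupled rates \eqn{r = \phi(\lambda)}; when
#' several fixed points exist (possible for the exponential transfer) the
#' branch reached from this low-rate start is the one reported.
#' Non-convergence (including overflow to NaN/Inf, read as the absence of a
#' stable mean-field branch) is reported through the `converged` flag
#' rather than as an error.
#'
#' @param net A [network_model()].
#' @param tol Convergence tolerance on the sup-norm rate update.
#' @param max_iter Maximum number of iterations.
#' @param damping Damping factor in (0, 1]; the update mixes the Picard
#'   map into the current iterate with this weight.
#'
#' @return An object of class `mean_field_solution` with elements `rbar`
#'   (stationary rates, ms^-1), `input` (stationary membrane inputs, mV),
#'   `phi1`, `phi2` (transfer derivatives at the operating point),
#'   `converged`, `residual`, and `iterations`.
#' @examples
#' net <- network_model(matrix(0.5, 1, 1), filter = synaptic_filter(),
#'                      transfer = transfer_function("threshold_linear", alpha = 1),
#'                      baseline = 0.1)
#' solve_mean_field(net)$rbar  # 0.1 / (1 - 0.5) = 0.2
#' @export
solve_mean_field <- function(net, tol = 1e-12, max_iter = 1000L, damping = 0.5) {
  stopifnot(inherits(net, "network_model"))
  phi_all <- function(x, order) {
    vapply(seq_len(net$N),
           function(i) transfer_eval(net$transfer[[i]], x[i], order),
           numeric(1))
  }
  r <- phi_all(net$baseline, 0L)
  converged <- FALSE
  residual <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    x <- drop(net$W %*% r) + net$baseline
    r_new <- (1 - damping) * r + damping * phi_all(x, 0L)
    if (any(!is.finite(r_new))) {
      r <- r_new
      residual <- Inf
      break
    }
    residual <- max(abs(r_new - r))
    r <- r_new
    if (residual < tol) { converged <- TRUE; break }
  }
  finite <- all(is.finite(r))
  x <- if (finite) drop(net$W %*% r) + net$baseline else rep(NA_real_, net$N)
  structure(list(
    rbar = if (finite) r else rep(NA_real_, net$N),
    input = x,
    phi1 = if (finite) phi_all(x, 1L) else rep(NA_real_, net$N),
    phi2 = if (finite) phi_all(x, 2L) else rep(NA_real_, net$N),
    converged = converged && finite,
    residual = residual,
    iterations = it
  ), class = "mean_field_solution")
}

#' @export
print.mean_field_solution <- function(x, ...) {
  cat(sprintf("<mean_field_solution> %s in %d iterations (residual %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  if (x$converged)
    cat(sprintf("  rates: mean %.4g ms^-1 (range %.4g to %.4g)\n",
                mean(x$rbar), min(x$rbar), max(x$rbar)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a mean-field solution into one row per neuron
#'
#' @param x A `mean_field_solution`.
#' @param ... Unused.
#' @return A tibble with columns `neuron`, `rate`, `input`, `phi1`, `phi2`.
#' @export
tidy.mean_field_solution <- function(x, ...) {
  tibble::tibble(neuron = seq_along(x$rbar), rate = x$rbar,
                 input = x$input, phi1 = x$phi1, phi2 = x$phi2)
}

#' One-row summary of a mean-field solution
#'
#' @param x A `mean_field_solution`.
#' @param ... Unused.
#' @export
glance.mean_field_solution <- function(x, ...) {
  tibble::tibble(converged = x$converged, iterations = x$iterations,
                 residual = x$residual, mean_rate = mean(x$rbar))
}

stability_matrix <- function(net, mf) diag(mf$phi1, net$N) %*% net$W

spectral_radius <- function(M) {
  if (all(M == 0)) return(0)
  max(Mod(eigen(M, only.values = TRUE)$values))
}

#' Tree-level stability measure of the mean-field rates
#'
#' Spectral radius of the stability matrix
#' \eqn{\Psi = \mathrm{diag}(\phi^{(1)}) W}. Because the shared synaptic
#' kernel is a monotone low-pass filter with \eqn{|g(\omega)| \le g(0) = 1},
#' the frequency-dependent radius \eqn{\rho(\Psi g(\omega))} is maximized
#' at \eqn{\omega = 0}, so this single number is the stability measure;
#' the mean-field rates lose linear stability when it reaches 1.
#'
#' @param net A [network_model()].
#' @param mf A converged [solve_mean_field()] solution.
#' @return Nonnegative scalar.
#' @export
stability_spectral_radius <- function(net, mf) {
  stopifnot(inherits(net, "network_model"), inherits(mf, "mean_field_solution"))
  if (!mf$converged) stop("mean-field solution did not converge", call. = FALSE)
  spectral_radius(stability_matrix(net, mf))
}

#' Frequency-resolved stability scan (cross-check utility)
#'
#' Returns \eqn{\rho(\Psi)\,|g(\omega)|} on a frequency grid; for the
#' scalar-kernel model this is exactly the spectral radius of the
#' frequency-dependent stability matrix, and its maximum is the
#' [stability_spectral_radius()] value at \eqn{\omega = 0}.
#'
#' @param net,mf As in [stability_spectral_radius()].
#' @param omega Frequency grid (rad/ms).
#' @return A tibble with columns `omega` and `radius`.
#' @export
stability_radius_scan <- function(net, mf, omega = seq(0, 2, length.out = 101)) {
  rho0 <- stability_spectral_radius(net, mf)
  tibble::tibble(omega = omega,
                 radius = rho0 * Mod(filter_transfer(net$filter, omega)))
}
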