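#' Symmetric angular-frequency grid
#'
#' Discretization of angular frequency used by the propagator and the
#' loop integrals. The grid is symmetric about 0 and contains 0; with the
#' default cutoff `omega_max = 20 / tau` the synaptic transfer has fallen
#' to |g| ~ 2.5e-3 at the edge, so the loop integrands (which decay at
#' least as fast as |g|^2) carry negligible tail mass.
#'
#' @param omega_max Cutoff, rad/ms. Default `20 / tau`.
#' @param n Number of grid points (forced odd so 0 is on the grid).
#' @param tau Filter time constant used for the default cutoff.
#'
#' @return An object of class `frequency_grid` with fields `omega`,
#'   `d_omega`, `omega_max`, `n`.
#' @export
frequency_grid <- function(omega_max = NULL, n = 2^12 + 1, tau = 10) {
  if (is.null(omega_max)) omega_max <- 20 / tau
  n <- as.integer(n)
  if (n %% 2L == 0L) n <- n + 1L
  omega <- seq(-omega_max, omega_max, length.out = n)
  structure(list(omega = omega, d_omega = omega[2] - omega[1],
                 omega_max = omega_max, n = n),
            class = "frequency_grid")
}

#' @export
print.frequency_grid <- function(x, ...) {
  cat(sprintf("<frequency_grid> %d points on [%g, %g] rad/ms (d_omega = %.3g)\n",
              x$n, -x$omega_max, x$omega_max, x$d_omega))
  invisible(x)
}

#' Tree-level propagator on a frequency grid
#'
#' Computes the linear-response propagator
#' \eqn{\Delta(\omega) = (I - \mathrm{diag}(\phi^{(1)})\, W\, g(\omega))^{-1}}
#' and the loop kernel \eqn{F(\omega) = g(\omega)\, W\, \Delta(\omega)}
#' (the frequency-domain form of \eqn{\sum_l g_{jl} * \Delta_{lk}}), along
#' with the loop-integral matrix
#' \eqn{P_{jk} = \frac{1}{2\pi}\int |F_{jk}(\omega)|^2 d\omega} that every
#' one-loop quantity reuses. Conjugate symmetry
#' \eqn{\Delta(-\omega) = \overline{\Delta(\omega)}} is exploited: only the
#' nonnegative half of the grid is computed and stored.
#'
#' @param net A [network_model()].
#' @param mf A converged [solve_mean_field()] solution with tree-level
#'   spectral radius below 1.
#' @param grid A [frequency_grid()]; defaults to `frequency_grid(tau = net$filter$tau)`.
#' @param store Which frequency-resolved arrays to keep: any of
#'   `"delta"`, `"F"`. Storing both costs `2 * (n/2) * N^2` complex values;
#'   large-network sweeps store only `"F"` (needed by [gamma1()]).
#'
#' @return An object of class `frequency_response`.
#' @export
propagator <- function(net, mf, grid = NULL, store = c("delta", "F")) {
  stopifnot(inherits(net, "network_model"), inherits(mf, "mean_field_solution"))
  if (!mf$converged) stop("mean-field solution did not converge", call. = FALSE)
  if (is.null(grid)) grid <- frequency_grid(tau = net$filter$tau)
  store <- intersect(store, c("delta", "F"))
  N <- net$N
  B <- stability_matrix(net, mf)
  radius <- spectral_radius(B)
  if (radius >= 1)
    stop(sprintf(
      "tree-level spectral radius %.4f >= 1: beyond the mean-field stability boundary",
      radius), call. = FALSE)
  g_all <- filter_transfer(net$filter, grid$omega)
  pos <- which(grid$omega >= 0)        # ascending, starts at omega = 0
  n_pos <- length(pos)
  I_N <- diag(1, N)
  delta_half <- if ("delta" %in% store) array(NA_complex_, c(n_pos, N, N))
  F_half <- if ("F" %in% store) array(NA_complex_, c(n_pos, N, N))
  P <- matrix(0, N, N)
  tail_lo <- grid$omega[pos] > 0.9 * grid$omega_max
  tail_mass <- matrix(0, N, N)
  delta0 <- NULL
  for (m in seq_len(n_pos)) {
    g <- g_all[pos[m]]
    D <- tryCatch(solve(I_N - g * B),
                  error = function(e)
                    stop(sprintf("propagator singular at omega = %.4g rad/ms",
                                 grid$omega[pos[m]]), call. = FALSE))
    Fm <- g * (net$W %*% D)
    if (!is.null(delta_half)) delta_half[m, , ] <- D
    if (!is.null(F_half)) F_half[m, , ] <- Fm
    w <- if (m == 1L) 1 else 2        # omega = 0 counted once
    aF2 <- Mod(Fm)^2
    P <- P + w * aF2
    if (tail_lo[m]) tail_mass <- tail_mass + w * aF2
    if (m == 1L) delta0 <- Re(D)
  }
  P <- P * grid$d_omega / (2 * pi)
  tail_mass <- tail_mass * grid$d_omega / (2 * pi)
  tail_frac <- if (any(P > 0)) max(tail_mass[P > 0] / P[P > 0]) else 0
  structure(list(grid = grid, g_omega = g_all, pos = pos,
                 delta = delta_half, F = F_half,
                 delta0 = delta0, F0 = Re(net$W %*% delta0),
                 P = P, tail_frac = tail_frac, radius = radius, N = N),
            class = "frequency_response")
}

#' @export
print.frequency_response <- function(x, ...) {
  cat(sprintf("<frequency_response> N = %d, %d frequencies, tree radius %.4f\n",
              x$N, x$grid$n, x$radius))
  cat(sprintf("  loop-kernel tail mass fraction: %.2e\n", x$tail_frac))
  invisible(x)
}

# reconstruct a full-grid frequency-resolved array from the stored half,
# using conjugate symmetry X(-omega) = Conj(X(omega))
full_grid_array <- function(fr, what = c("delta", "F")) {
  what <- match.arg(what)
  half <- fr[[what]]
  if (is.null(half))
    stop(sprintf("'%s' was not stored; rerun propagator() with store = \"%s\"",
                 what, what), call. = FALSE)
  M <- fr$grid$n
  N <- fr$N
  out <- array(NA_complex_, c(M, N, N))
  out[fr$pos, , ] <- half
  neg <- rev(seq_len(min(fr$pos) - 1L))
  for (m in seq_along(neg)) out[neg[m], , ] <- Conj(half[m + 1L, , ])
  out
}

#' Tree-level cross-spectral matrices
#'
#' The second spike-train cumulant in the frequency domain at tree level:
#' \eqn{C(\omega) = \Delta(\omega)\,\mathrm{diag}(\bar r)\,\Delta(\omega)^H},
#' a Hermitian positive-semidefinite matrix at each grid frequency. With no
#' coupling this reduces to the flat Poisson spectrum
#' \eqn{C(\omega) = \mathrm{diag}(\bar r)}.
#'
#' @param fr A [propagator()] result with `"delta"` stored.
#' @param mf The matching mean-field solution.
#'
#' @return A complex array `[n_omega, N, N]` over the full symmetric grid.
#' @export
tree_cross_spectrum <- function(fr, mf) {
  stopifnot(inherits(fr, "frequency_response"))
  delta <- full_grid_array(fr, "delta")
  N <- fr$N
  R <- diag(mf$rbar, N)
  out <- array(NA_complex_, dim(delta))
  for (m in seq_len(dim(delta)[1])) {
    D <- matrix(delta[m, , ], N, N)
    out[m, , ] <- D %*% R %*% Conj(t(D))
  }
  out
}

#' Integrated (zero-frequency) tree-level covariance matrix
#'
#' \eqn{C(0) = \Delta(0)\,\mathrm{diag}(\bar r)\,\Delta(0)^T}: the all-lag
#' integral of the pairwise covariance functions, including the diagonal
#' Poisson delta contribution.
#'
#' @param fr A [propagator()] result.
#' @param mf The matching mean-field solution.
#' @return Real symmetric N x N matrix, ms^-1.
#' @export
tree_integrated_covariance <- function(fr, mf) {
  D0 <- fr$delta0
  D0 %*% diag(mf$rbar, fr$N) %*% t(D0)
}

#' Integrated autocovariance of a summed population spike train
#'
#' Tree-level prediction for the all-lag integral of the autocovariance of
#' the summed spike train of a subset of neurons:
#' \eqn{a^T C(0) a = \sum_{i,j \in \mathrm{subset}} C_{ij}(0)}.
#'
#' @param fr A [propagator()] result.
#' @param mf The matching mean-field solution.
#' @param subset Integer indices of the population (default: all neurons).
#' @return Scalar, ms^-1.
#' @export
integrated_population_variance <- function(fr, mf, subset = NULL) {
  if (is.null(subset)) subset <- seq_len(fr$N)
  C0 <- tree_integrated_covariance(fr, mf)
  sum(C0[subset, subset])
}

#' Integrated tree-level third cumulant tensor
#'
#' The all-lag integral (zero-frequency bispectrum) of the third joint
#' spike-train cumulant at tree level. Two diagram families contribute: a
#' source feeding all three measured neurons directly through propagators,
#' \eqn{\sum_k \Delta_{ik}(0)\Delta_{jk}(0)\Delta_{lk}(0)\,\bar r_k}, and a
#' cascade in which the source feeds one leg directly while a branching
#' internal neuron (gain \eqn{\phi^{(1)}}) relays the filtered input to the
#' other two, summed over the three assignments of the lone leg. The
#' result is symmetric in its three indices, and with no coupling it
#' reduces to the Poisson third cumulant (the rate on the triple diagonal).
#'
#' Only the fully integrated tensor is exposed, and only for small
#' networks (N <= 20): lag-resolved third cumulants are out of scope.
#'
#' @param fr A [propagator()] result.
#' @param mf The matching mean-field solution.
#' @param net The network model.
#' @return A real N x N x N array.
#' @export
tree_third_cumulant_integrated <- function(fr, mf, net) {
  N <- fr$N
  if (N > 20)
    stop(paste("integrated third cumulants are restricted to N <= 20;",
               "frequency-resolved evaluation at network scale is out of scope"),
         call. = FALSE)
  D0 <- fr$delta0
  # cascade kernel: M[k, l] = [F(0) diag(rbar) t(Delta(0))]_{kl}
  Mcas <- fr$F0 %*% diag(mf$rbar, N) %*% t(D0)
  K <- array(0, c(N, N, N))
  for (k in seq_len(N)) {
    dk <- D0[, k]
    K <- K + outer(outer(dk, dk), dk) * mf$rbar[k]        # direct source term
    phi1M <- mf$phi1[k] * Mcas[k, ]
    dd <- outer(dk, dk)
    K <- K + outer(dd, phi1M)                             # lone leg = 3rd index
    K <- K + aperm(outer(dd, phi1M), c(1, 3, 2))          # lone leg = 2nd index
    K <- K + aperm(outer(dd, phi1M), c(3, 1, 2))          # lone leg = 1st index
  }
  K
}

#' Time-domain kernel of a stored frequency response (diagnostic)
#'
#' Inverse-FFT reconstruction of the smooth part of a propagator or loop
#' kernel entry on a uniform time grid. Intended for plotting and
#' diagnostics; all production quantities are computed in the frequency
#' domain.
#'
#' @param fr A [propagator()] result with the requested array stored.
#' @param i,j Matrix entry.
#' @param what `"delta"` (smooth part, i.e. minus the delta spike at 0) or
#'   `"F"`.
#' @return A tibble with columns `t` (ms) and `value`.
#' @export
time_kernel <- function(fr, i = 1, j = 1, what = c("F", "delta")) {
  what <- match.arg(what)
  X <- full_grid_array(fr, what)[, i, j]
  if (what == "delta") X <- X - as.numeric(i == j)   # remove delta-function part
  M <- fr$grid$n
  d_omega <- fr$grid$d_omega
  # omega ordered -max..max; shift to FFT order before transforming
  K <- (M - 1L) %/% 2L
  Xs <- c(X[(K + 1L):M], X[1:K])
  x_t <- Re(stats::fft(Xs, inverse = TRUE)) * d_omega / (2 * pi)
  dt <- 2 * pi / (M * d_omega)
  tibble::tibble(t = dt * (seq_len(M) - 1L), value = x_t)
}
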