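#' One-loop correction to the stationary firing rates
#'
#' First fluctuation correction to the mean-field rates: pairwise-correlated
#' input, filtered through the squared loop kernel, drives extra rate
#' through the curvature \eqn{\phi^{(2)}} of the transfer function. In the
#' stationary state the correction reduces to
#' \deqn{r_1 = \Delta(0)\, v, \qquad
#'       v_j = \tfrac{1}{2}\phi_j^{(2)} \sum_k P_{jk}\, \bar r_k,}
#' with \eqn{P_{jk} = \frac{1}{2\pi}\int |F_{jk}(\omega)|^2\, d\omega} the
#' integrated squared loop kernel. It vanishes identically when
#' \eqn{\phi^{(2)} = 0} at the operating point (e.g. threshold-linear
#' transfer with positive input).
#'
#' @param fr A [propagator()] result (tree radius < 1).
#' @param mf The matching mean-field solution.
#' @param net The network model.
#' @param max_tail Maximum tolerated fraction of the loop integral carried
#'   by the top 10% of the frequency band; above this the cutoff is deemed
#'   too small and an error asks for a larger `omega_max`.
#'
#' @return Per-neuron rate corrections, ms^-1.
#' @export
one_loop_rate <- function(fr, mf, net, max_tail = 0.01) {
  check_loop_inputs(fr, mf, net, max_tail)
  v <- 0.5 * mf$phi2 * drop(fr$P %*% mf$rbar)
  drop(fr$delta0 %*% v)
}

check_loop_inputs <- function(fr, mf, net, max_tail) {
  stopifnot(inherits(fr, "frequency_response"),
            inherits(mf, "mean_field_solution"),
            inherits(net, "network_model"))
  if (fr$radius >= 1)
    stop("tree-level radius >= 1: loop corrections undefined", call. = FALSE)
  if (any(mf$phi2 != 0) && fr$tail_frac > max_tail)
    stop(sprintf(paste("frequency cutoff too small: %.2g of the loop integral",
                       "lies in the top decade of the band; increase omega_max"),
                 fr$tail_frac), call. = FALSE)
  invisible(TRUE)
}

#' One-loop correction to the integrated covariance matrix
#'
#' First fluctuation correction to the integrated (all-lag) pairwise
#' covariance matrix \eqn{C(0)}, accounting for the influence of
#' tree-level triplet correlations on pairwise correlations. Five diagrams
#' contribute at zero total frequency; writing
#' \eqn{Q = \mathrm{diag}(\phi^{(2)}/2)\, P} they evaluate to
#' \deqn{C_1(0) = \Delta_0 \big[\mathrm{diag}(Q \bar r)\big] \Delta_0^T
#'   + \big(\Delta_0 A \Delta_0^T\big) + \big(\Delta_0 A \Delta_0^T\big)^T,}
#' \deqn{A = Q\,\mathrm{diag}(\bar r)
#'   + Q\,\mathrm{diag}(\phi^{(1)})\, F(0)\, \mathrm{diag}(\bar r),}
#' where the first piece of A is the loop inserted directly between the
#' two measured legs and the second is the extended chain with a
#' branching-gain relay. Only the integrated correction is exposed; this
#' is the quantity entering the population-variance observable.
#'
#' @inheritParams one_loop_rate
#' @return Real symmetric N x N matrix, ms^-1.
#' @export
one_loop_two_point <- function(fr, mf, net, max_tail = 0.01) {
  check_loop_inputs(fr, mf, net, max_tail)
  N <- fr$N
  D0 <- fr$delta0
  Q <- diag(0.5 * mf$phi2, N) %*% fr$P
  term1 <- D0 %*% diag(drop(Q %*% mf$rbar), N) %*% t(D0)
  A <- Q %*% diag(mf$rbar, N) +
    Q %*% diag(mf$phi1, N) %*% fr$F0 %*% diag(mf$rbar, N)
  S <- D0 %*% A %*% t(D0)
  term1 + S + t(S)
}

#' One-loop correction to the inverse propagator
#'
#' The proper-vertex correction \eqn{\Gamma_1(\omega)}: the loop obtained
#' by amputating the external propagator legs of the one-loop propagator
#' correction. In the frequency domain,
#' \deqn{\Gamma_{1,jm}(\omega) = \tfrac{1}{2}\phi_j^{(2)}
#'   \sum_k (F_{jk} \star F_{jk})(\omega)\; \phi_k^{(1)} W_{km}\, g(\omega),}
#' where \eqn{(F \star F)(\omega) = \frac{1}{2\pi}\int F(\omega')
#' F(\omega - \omega')\, d\omega'} is the frequency self-convolution of the
#' loop kernel (the transform of \eqn{F(t)^2}), evaluated here by
#' zero-padded FFT along the stored grid. \eqn{-\Gamma_1} corrects the
#' inverse propagator, so the one-loop propagator correction is
#' \eqn{\Delta_1 = \bar\Delta\, \Gamma_1\, \bar\Delta}.
#'
#' @inheritParams one_loop_rate
#' @param omega_eval Frequencies at which to return \eqn{\Gamma_1}; must be
#'   points of the stored grid (values are matched to the nearest grid
#'   point). Default: 0.
#'
#' @return A complex array `[length(omega_eval), N, N]`, or an N x N matrix
#'   if a single frequency is requested.
#' @export
gamma1 <- function(fr, mf, net, omega_eval = 0, max_tail = 0.01) {
  check_loop_inputs(fr, mf, net, max_tail)
  N <- fr$N
  H <- loop_self_convolution(fr, omega_eval)
  g_eval <- filter_transfer(net$filter, omega_eval)
  phi2h <- 0.5 * mf$phi2
  R <- diag(mf$phi1, N) %*% net$W
  out <- array(NA_complex_, c(length(omega_eval), N, N))
  for (m in seq_along(omega_eval)) {
    Hm <- matrix(H[m, , ], N, N)
    out[m, , ] <- (phi2h * Hm) %*% R * g_eval[m]
  }
  if (length(omega_eval) == 1L) matrix(out[1, , ], N, N) else out
}

# (F_jk * F_jk)(omega_eval) for all j, k via zero-padded FFT along the
# full symmetric grid; omega_eval snapped to grid points. The full-grid
# columns are rebuilt from the stored nonnegative half by conjugate
# symmetry, in blocks of pair-columns to bound transient memory.
loop_self_convolution <- function(fr, omega_eval) {
  if (is.null(fr$F))
    stop("loop kernel not stored; rerun propagator() with store = \"F\"",
         call. = FALSE)
  M <- fr$grid$n
  K <- (M - 1L) %/% 2L
  n_pos <- length(fr$pos)
  idx_eval <- vapply(omega_eval,
                     function(w) which.min(abs(fr$grid$omega - w)), integer(1))
  if (max(abs(fr$grid$omega[idx_eval] - omega_eval)) > fr$grid$d_omega)
    stop("`omega_eval` must lie on the stored frequency grid", call. = FALSE)
  L <- stats::nextn(2L * M - 1L, 2)
  N <- fr$N
  Fh <- matrix(fr$F, nrow = n_pos)              # columns are (j,k) pairs
  n_pair <- ncol(Fh)
  sel <- idx_eval + K                           # linear-convolution row index
  H <- matrix(NA_complex_, length(idx_eval), n_pair)
  block <- max(1L, min(n_pair, 2048L))
  for (start in seq(1L, n_pair, by = block)) {
    cols <- start:min(start + block - 1L, n_pair)
    full <- rbind(Conj(Fh[n_pos:2, cols, drop = FALSE]),
                  Fh[, cols, drop = FALSE],
                  matrix(0, L - M, length(cols)))
    Fhat <- stats::mvfft(full)
    conv <- stats::mvfft(Fhat * Fhat, inverse = TRUE) / L
    H[, cols] <- conv[sel, , drop = FALSE]
  }
  array(H * fr$grid$d_omega / (2 * pi), c(length(idx_eval), N, N))
}

#' One-loop propagator correction at zero frequency
#'
#' \eqn{\Delta_1(0) = \Delta(0)\, \Gamma_1(0)\, \Delta(0)}, the truncation
#' of the propagator's loop expansion at one loop.
#'
#' @inheritParams one_loop_rate
#' @return Real N x N matrix.
#' @export
one_loop_propagator_correction <- function(fr, mf, net) {
  G1 <- gamma1(fr, mf, net, omega_eval = 0)
  Re(fr$delta0 %*% G1 %*% fr$delta0)
}

#' One-loop stability measure
#'
#' Maximum over a set of evaluation frequencies of the spectral radius of
#' the corrected stability matrix
#' \eqn{\mathrm{diag}(\phi^{(1)})\, W\, g(\omega) + \Gamma_1(\omega)}.
#' The rates are deemed one-loop unstable when this measure reaches 1
#' (equivalently, the corrected inverse propagator
#' \eqn{I - \mathrm{diag}(\phi^{(1)}) W g - \Gamma_1} becomes singular).
#' The tree-level part peaks at \eqn{\omega = 0} but \eqn{\Gamma_1(\omega)}
#' need not, so a frequency scan is kept; by conjugate symmetry only
#' \eqn{\omega \ge 0} is evaluated. With linear transfer
#' (\eqn{\phi^{(2)} = 0}) this reduces exactly to the tree-level radius.
#'
#' @inheritParams one_loop_rate
#' @param omega_eval Frequencies scanned; default a 65-point decimation of
#'   the nonnegative half of the stored grid.
#' @return Scalar stability measure.
#' @export
corrected_stability <- function(net, mf, fr, omega_eval = NULL, max_tail = 0.01) {
  check_loop_inputs(fr, mf, net, max_tail)
  if (all(mf$phi2 == 0)) return(fr$radius)
  if (is.null(omega_eval)) {
    wpos <- fr$grid$omega[fr$pos]
    omega_eval <- wpos[unique(round(seq(1, length(wpos), length.out = 65)))]
  }
  B <- stability_matrix(net, mf)
  G1 <- gamma1(fr, mf, net, omega_eval = omega_eval)
  if (length(omega_eval) == 1L) G1 <- array(G1, c(1L, fr$N, fr$N))
  g_eval <- filter_transfer(net$filter, omega_eval)
  radii <- vapply(seq_along(omega_eval), function(m) {
    spectral_radius(B * g_eval[m] + matrix(G1[m, , ], fr$N, fr$N))
  }, numeric(1))
  max(radii)
}
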