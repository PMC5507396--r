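# Independent time-domain oracle for tree-level and one-loop quantities.
#
# Route: the linearized network response is a 2N-state linear system (two
# exponential cascade stages per neuron, with rate feedback through
# diag(phi1) W), so the smooth part of the propagator and the loop kernel
# are exact matrix-exponential kernels. All loop integrals are then direct
# Riemann/trapezoid quadratures of those time-domain kernels -- no
# frequency grids, matrix inversions, or FFTs shared with the package
# implementation.

expm_pade <- function(A) {
  # scaling-and-squaring with a Taylor series; adequate for the small,
  # well-scaled matrices used in the oracle
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-16))) + 4L)
  As <- A / 2^s
  E <- diag(1, nrow(A))
  term <- diag(1, nrow(A))
  for (k in 1:20) {
    term <- term %*% As / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  E
}

# Exact time-domain kernels on a uniform grid:
#   F(t)  = W (g * Delta)(t)   (loop kernel)
#   H(t)  = phi1 * F(t)        (smooth part of the propagator)
oracle_kernels <- function(net, mf, dt = NULL, T_w = NULL) {
  N <- net$N
  tau <- net$filter$tau
  if (is.null(dt)) dt <- 0.01 * tau
  if (is.null(T_w)) T_w <- 80 * tau
  n_t <- as.integer(round(T_w / dt)) + 1L
  I_N <- diag(1, N)
  Z <- matrix(0, N, N)
  A0 <- rbind(cbind(-I_N / tau, Z), cbind(I_N / tau, -I_N / tau))
  # rate feedback: perturbed rates phi1 * W * s2 re-enter stage 1
  A_cl <- A0
  A_cl[1:N, (N + 1):(2 * N)] <- A_cl[1:N, (N + 1):(2 * N)] +
    diag(mf$phi1, N) %*% net$W / tau
  E_dt <- expm_pade(A_cl * dt)
  Fk <- array(0, c(n_t, N, N))
  E <- diag(1, 2 * N)
  for (m in seq_len(n_t)) {
    Fk[m, , ] <- net$W %*% E[(N + 1):(2 * N), 1:N, drop = FALSE] / tau
    E <- E %*% E_dt
  }
  Hk <- array(0, c(n_t, N, N))
  for (m in seq_len(n_t)) Hk[m, , ] <- diag(mf$phi1, N) %*% Fk[m, , ]
  list(t = dt * (seq_len(n_t) - 1L), dt = dt, F = Fk, H = Hk, N = N)
}

trapz_weights <- function(n, dt) {
  w <- rep(dt, n)
  w[c(1, n)] <- dt / 2
  w
}

# integral over lag of a [n_t, N, N] kernel array (optionally elementwise
# transformed first)
oracle_int <- function(ker, dt, f = identity) {
  n_t <- dim(ker)[1]
  w <- trapz_weights(n_t, dt)
  out <- matrix(0, dim(ker)[2], dim(ker)[3])
  for (m in seq_len(n_t)) out <- out + w[m] * f(matrix(ker[m, , ], dim(ker)[2]))
  out
}

# All oracle quantities used by the tests, from one kernel tabulation.
oracle_loop_quantities <- function(net, mf, dt = NULL, T_w = NULL) {
  ok <- oracle_kernels(net, mf, dt, T_w)
  N <- ok$N
  intF <- oracle_int(ok$F, ok$dt)                     # integral of F(t)
  intH <- oracle_int(ok$H, ok$dt)
  P <- oracle_int(ok$F, ok$dt, function(M) M^2)       # integral of F(t)^2
  intDelta <- diag(1, N) + intH                       # includes the delta part
  Q <- diag(0.5 * mf$phi2, N) %*% P
  r1 <- drop(intDelta %*% (Q %*% mf$rbar))
  # one-loop propagator correction, integrated:
  #   Delta . (phi2/2 F^2) . phi1 (g*Delta) with (g*Delta) = F / W-row...
  # network form: int Delta * Gamma1 * int Delta with
  #   Gamma1(0) = diag(phi2/2) P diag(phi1) W  (g(0) = 1)
  G1 <- Q %*% diag(mf$phi1, N) %*% net$W
  D1 <- intDelta %*% G1 %*% intDelta
  # five-term integrated one-loop two-point correction
  term1 <- intDelta %*% diag(drop(Q %*% mf$rbar), N) %*% t(intDelta)
  A <- Q %*% diag(mf$rbar, N) +
    Q %*% diag(mf$phi1, N) %*% intF %*% diag(mf$rbar, N)
  S <- intDelta %*% A %*% t(intDelta)
  C1 <- term1 + S + t(S)
  # integrated tree second and third cumulants
  C0 <- intDelta %*% diag(mf$rbar, N) %*% t(intDelta)
  K3 <- array(0, c(N, N, N))
  Mcas <- intF %*% diag(mf$rbar, N) %*% t(intDelta)
  ID <- intDelta
  for (i in seq_len(N)) for (j in seq_len(N)) for (l in seq_len(N)) {
    v <- 0
    for (k in seq_len(N)) {
      v <- v + ID[i, k] * ID[j, k] * ID[l, k] * mf$rbar[k] +
        mf$phi1[k] * (Mcas[k, l] * ID[i, k] * ID[j, k] +
                      Mcas[k, j] * ID[i, k] * ID[l, k] +
                      Mcas[k, i] * ID[j, k] * ID[l, k])
    }
    K3[i, j, l] <- v
  }
  list(P = P, r1 = r1, gamma1_0 = G1, delta1_0 = D1, C1 = C1,
       C0 = C0, K3 = K3, intDelta = intDelta, intF = intF, kernels = ok)
}

# Fully literal lattice oracle for a single neuron: kernels become
# Toeplitz operator matrices on a time grid and the one-loop formulas are
# evaluated as nested discrete integrals over the internal times, with one
# measurement time fixed mid-window and the other integrated out.
# Validates the stationary factorization used by both the implementation
# and the factorized oracle above.
oracle_scalar_lattice <- function(net, mf, dt = 0.25, T_w = 350) {
  stopifnot(net$N == 1)
  ok <- oracle_kernels(net, mf, dt = dt, T_w = T_w)
  n_t <- length(ok$t)
  lag <- outer(seq_len(n_t), seq_len(n_t), "-")      # row - col, in steps
  kermat <- function(v) {
    M <- matrix(0, n_t, n_t)
    pos <- lag >= 0
    M[pos] <- v[lag[pos] + 1L]
    M
  }
  D <- kermat(c(ok$H[, 1, 1])) + diag(1 / dt, n_t)   # Delta(t, t')
  Fm <- kermat(c(ok$F[, 1, 1]))
  F2 <- Fm^2
  rbar <- mf$rbar
  q2 <- 0.5 * mf$phi2
  phi1 <- mf$phi1
  mid <- as.integer(round(n_t / 2))
  dmid <- D[mid, ]                                   # Delta(x, t'), x fixed
  colD <- colSums(D) * dt                            # int dy Delta(y, s)
  # one-loop rate: iint dt1 dt2 Delta(x, t1) (phi2/2) F(t1, t2)^2 rbar
  r1 <- drop(dmid %*% F2 %*% rep(1, n_t)) * q2 * rbar * dt^2
  # the five integrated one-loop two-point terms (x fixed, y integrated):
  loop_vec <- drop(F2 %*% rep(1, n_t)) * dt          # int dt'' F(t',t'')^2
  T1 <- sum(dmid * colD * q2 * loop_vec) * rbar * dt
  T2 <- drop(dmid %*% F2 %*% colD) * q2 * rbar * dt^2
  T3 <- drop(colD %*% F2 %*% dmid) * q2 * rbar * dt^2
  T4 <- drop(dmid %*% F2 %*% Fm %*% colD) * q2 * phi1 * rbar * dt^3
  T5 <- drop(colD %*% F2 %*% Fm %*% dmid) * q2 * phi1 * rbar * dt^3
  list(r1 = r1, C1 = T1 + T2 + T3 + T4 + T5)
}
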