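test_that("uncoupled propagator is the identity at every frequency", {
  net <- network_model(matrix(0, 2, 2), baseline = 1)
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf, frequency_grid(n = 65))
  delta <- hawkesloops:::full_grid_array(fr, "delta")
  for (m in c(1, 20, 33, 65))
    expect_equal(matrix(delta[m, , ], 2, 2), diag(2) + 0i)
  expect_equal(fr$P, matrix(0, 2, 2))
})

test_that("scalar propagator sums the geometric series", {
  net <- scalar_linear_net(eps = 0.5)
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf)
  expect_equal(drop(fr$delta0), 2, tolerance = 1e-12)
  # Neumann partial sums converge to the propagator at several frequencies
  grid <- fr$grid
  for (w in c(0, 0.05, 0.2)) {
    g <- filter_transfer(net$filter, w)
    target <- 1 / (1 - 0.5 * g)
    partial <- sum((0.5 * g)^(0:60))
    expect_equal(partial, target, tolerance = 1e-8)
  }
})

test_that("Neumann series of the matrix kernel converges to the propagator", {
  net <- toy_quad_3()
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf, frequency_grid(n = 129))
  B <- diag(mf$phi1, 3) %*% net$W
  delta <- hawkesloops:::full_grid_array(fr, "delta")
  for (m in c(40, 65, 100)) {
    g <- fr$g_omega[m]
    S <- diag(3) + 0i; Tn <- diag(3) + 0i
    for (k in 1:200) { Tn <- Tn %*% (g * B); S <- S + Tn }
    expect_equal(matrix(delta[m, , ], 3, 3), S, tolerance = 1e-8)
  }
})

test_that("propagator refuses operating points beyond the stability boundary", {
  net <- scalar_linear_net(eps = 1.2)
  mf <- solve_mean_field(net, max_iter = 50)   # rates run away linearly
  expect_false(mf$converged)
  expect_error(propagator(net, mf), "converge")
  # inhibitory self-coupling: the mean field converges but the stability
  # radius exceeds 1, so the linear-response expansion is refused
  net2 <- network_model(matrix(-1.5, 1, 1),
                        transfer = transfer_function("threshold_linear",
                                                     alpha = 1),
                        baseline = 0.1)
  mf2 <- solve_mean_field(net2)
  expect_true(mf2$converged)
  expect_error(propagator(net2, mf2), "stability boundary")
})

test_that("cross-spectrum is Hermitian PSD and Poisson in the uncoupled limit", {
  net <- network_model(matrix(0, 3, 3), baseline = c(1, 2, 3),
                       transfer = transfer_function("threshold_linear",
                                                    alpha = 0.1))
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf, frequency_grid(n = 33))
  C <- tree_cross_spectrum(fr, mf)
  for (m in seq_len(dim(C)[1]))
    expect_equal(matrix(C[m, , ], 3, 3), diag(mf$rbar) + 0i)
  # coupled case: Hermitian PSD at every grid point
  net2 <- toy_quad_3()
  mf2 <- solve_mean_field(net2)
  fr2 <- propagator(net2, mf2, frequency_grid(n = 33))
  C2 <- tree_cross_spectrum(fr2, mf2)
  for (m in seq_len(dim(C2)[1])) {
    M <- matrix(C2[m, , ], 3, 3)
    expect_equal(M, Conj(t(M)), tolerance = 1e-12)
    expect_gte(min(Re(eigen(M, only.values = TRUE)$values)), -1e-12)
  }
})

test_that("scalar integrated autocovariance matches the Hawkes closed form", {
  net <- scalar_linear_net(eps = 0.5, lambda = 0.1)
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf)
  expect_equal(integrated_population_variance(fr, mf), 0.8, tolerance = 1e-10)
  # and the quadrature oracle built from the exponential-form propagator
  orc <- oracle_loop_quantities(net, mf)
  expect_equal(drop(orc$C0), 0.8, tolerance = 1e-4)
})

test_that("population variance is the subset sum of the covariance matrix", {
  net <- toy_quad_3()
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf)
  C0 <- tree_integrated_covariance(fr, mf)
  expect_equal(integrated_population_variance(fr, mf, 1:2), sum(C0[1:2, 1:2]))
  expect_equal(integrated_population_variance(fr, mf), sum(C0))
})

test_that("integrated covariance agrees with the time-domain oracle", {
  net <- toy_quad_3()
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf)
  orc <- oracle_loop_quantities(net, mf)
  expect_equal(tree_integrated_covariance(fr, mf), orc$C0, tolerance = 1e-4)
})

test_that("third cumulant tensor is symmetric and matches its oracles", {
  net <- toy_quad_3()
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf)
  K <- tree_third_cumulant_integrated(fr, mf, net)
  for (p in list(c(1, 3, 2), c(2, 1, 3), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2)))
    expect_equal(K, aperm(K, p), tolerance = 1e-12)
  orc <- oracle_loop_quantities(net, mf)
  expect_equal(K, orc$K3, tolerance = 1e-3)
  # scalar case against the exponential-propagator quadrature oracle
  net1 <- scalar_linear_net(eps = 0.5, lambda = 0.1)
  mf1 <- solve_mean_field(net1)
  fr1 <- propagator(net1, mf1)
  K1 <- tree_third_cumulant_integrated(fr1, mf1, net1)
  # analytic: Delta0 = 2, int F = eps * Delta0 = 1, rbar = 0.2:
  # K = Delta0^3 r + 3 Delta0^2 (int F) r Delta0 = 1.6 + 4.8
  expect_equal(drop(K1), 6.4, tolerance = 1e-10)
  orc1 <- oracle_loop_quantities(net1, mf1, dt = 0.02, T_w = 1200)
  expect_equal(drop(orc1$K3), drop(K1), tolerance = 1e-6)
})

test_that("Poisson limit: cumulants collapse to the rate as weights vanish", {
  for (s in c(1e-3, 1e-5)) {
    net <- toy_quad_3(scale = s)
    mf <- solve_mean_field(net)
    fr <- propagator(net, mf, frequency_grid(n = 129))
    C0 <- tree_integrated_covariance(fr, mf)
    expect_equal(C0, diag(mf$rbar), tolerance = 10 * s)
    K <- tree_third_cumulant_integrated(fr, mf, net)
    Kpois <- array(0, c(3, 3, 3))
    for (i in 1:3) Kpois[i, i, i] <- mf$rbar[i]
    expect_equal(K, Kpois, tolerance = 10 * s)
  }
})

test_that("third cumulant refuses large networks", {
  net <- make_er_ei_network(ei_network_params(N_E = 30, N_I = 5, W_EE = 0.01,
                                              seed = 1))
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf, frequency_grid(n = 65))
  expect_error(tree_third_cumulant_integrated(fr, mf, net), "N <= 20")
})

test_that("doubling grid size and cutoff changes C(0) by < 0.5%", {
  net <- toy_quad_3()
  mf <- solve_mean_field(net)
  f1 <- propagator(net, mf, frequency_grid(omega_max = 2, n = 2^12 + 1))
  f2 <- propagator(net, mf, frequency_grid(omega_max = 4, n = 2^13 + 1))
  c1 <- tree_integrated_covariance(f1, mf)
  c2 <- tree_integrated_covariance(f2, mf)
  expect_lt(max(abs(c1 - c2)) / max(abs(c2)), 0.005)
  # the loop integrals, which do use the grid, also converge
  expect_lt(max(abs(f1$P - f2$P)) / max(f2$P), 0.005)
})

test_that("time-kernel utility reconstructs the alpha-filtered response", {
  net <- scalar_linear_net(eps = 0.5)
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf, frequency_grid(omega_max = 10, n = 2^13 + 1))
  tk <- time_kernel(fr, 1, 1, what = "F")
  orc <- oracle_kernels(net, mf, dt = 0.05, T_w = 300)
  interp <- stats::approx(tk$t, tk$value, xout = orc$t)$y
  expect_lt(max(abs(interp - orc$F[, 1, 1])), 1e-3)
})
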