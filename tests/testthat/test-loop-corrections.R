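test_that("all loop corrections vanish identically for linear transfer", {
  net <- make_er_ei_network(
    ei_network_params(N_E = 30, N_I = 6, W_EE = 0.05, seed = 2),
    transfer = transfer_function("threshold_linear", alpha = 0.1),
    baseline = 0.1)
  mf <- solve_mean_field(net)
  expect_true(all(mf$phi2 == 0))
  fr <- propagator(net, mf, frequency_grid(n = 257), store = "F")
  expect_equal(one_loop_rate(fr, mf, net), rep(0, 36))
  expect_equal(one_loop_two_point(fr, mf, net), matrix(0, 36, 36))
  expect_equal(gamma1(fr, mf, net), matrix(0 + 0i, 36, 36))
  expect_equal(corrected_stability(net, mf, fr), fr$radius)
})

test_that("scalar one-loop rate matches analytic and lattice quadratures", {
  net <- scalar_quad_net(w = 0.4, lambda = 0.2)
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf, frequency_grid(omega_max = 10, n = 2^14 + 1))
  r1 <- one_loop_rate(fr, mf, net)
  # analytic scalar loop integral from the exponential-form propagator:
  # H(t) = (sqrt(b)/2 tau) (e^{-(1-sqrt b)t/tau} - e^{-(1+sqrt b)t/tau})
  b <- mf$phi1 * 0.4
  a1 <- (1 - sqrt(b)) / 10; a2 <- (1 + sqrt(b)) / 10
  intH2 <- (b / 400) * (1 / (2 * a1) + 1 / (2 * a2) - 2 / (a1 + a2))
  r1_an <- (1 / (1 - b)) * (mf$phi2 / 2) * (intH2 / mf$phi1^2) * mf$rbar
  expect_equal(r1, r1_an, tolerance = 1e-5)
  # literal nested-lattice quadrature of the double time integral
  lat <- oracle_scalar_lattice(net, mf)
  expect_equal(r1, lat$r1, tolerance = 1e-3)
})

test_that("network one-loop quantities match the time-domain oracle", {
  for (net in list(toy_quad_2(), toy_quad_3())) {
    mf <- solve_mean_field(net)
    fr <- propagator(net, mf, frequency_grid(omega_max = 10, n = 2^14 + 1))
    orc <- oracle_loop_quantities(net, mf, dt = 0.05)
    expect_equal(fr$P, orc$P, tolerance = 1e-4)
    r1 <- one_loop_rate(fr, mf, net)
    expect_equal(r1, orc$r1, tolerance = 1e-3)
    C1 <- one_loop_two_point(fr, mf, net)
    expect_equal(C1, orc$C1, tolerance = 1e-3)
    G1 <- gamma1(fr, mf, net, omega_eval = 0)
    expect_equal(Re(G1), orc$gamma1_0, tolerance = 1e-3)
    expect_lt(max(abs(Im(G1))), 1e-10)
    D1 <- one_loop_propagator_correction(fr, mf, net)
    expect_equal(D1, orc$delta1_0, tolerance = 1e-3)
  }
})

test_that("scalar two-point correction matches the literal lattice oracle", {
  net <- scalar_quad_net(w = 0.35, lambda = 0.25)
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf, frequency_grid(omega_max = 10, n = 2^14 + 1))
  C1 <- one_loop_two_point(fr, mf, net)
  lat <- oracle_scalar_lattice(net, mf, dt = 0.2, T_w = 400)
  expect_equal(drop(C1), lat$C1, tolerance = 2e-3)
})

test_that("propagator correction obeys the proper-vertex factorization", {
  net <- toy_quad_3()
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf)
  D1 <- one_loop_propagator_correction(fr, mf, net)
  G1 <- gamma1(fr, mf, net, omega_eval = 0)
  expect_equal(D1, Re(fr$delta0 %*% G1 %*% fr$delta0), tolerance = 1e-12)
})

test_that("one-loop rate scales quadratically with a global weight scale", {
  # the loop kernel F carries one factor of W, so |F|^2 and hence the
  # correction scale as the square of a weak global weight scale
  scales <- 0.02 * 2^(0:4)
  r1s <- vapply(scales, function(s) {
    net <- scalar_quad_net(w = s, lambda = 0.2)
    mf <- solve_mean_field(net)
    fr <- propagator(net, mf)
    one_loop_rate(fr, mf, net)
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(r1s) ~ log(scales)))[2]
  expect_lt(abs(slope - 2), 0.1)
})

test_that("mean one-loop rate correction is positive in the quadratic E-I design", {
  net <- small_er_quad(W_EE = 0.8)
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf, frequency_grid(n = 2^10 + 1), store = "F")
  r1 <- one_loop_rate(fr, mf, net)
  e <- which(net$cell_type == "E")
  expect_gt(mean(r1[e]), 0)
  expect_gt(mean(r1[-e]), 0)
})

test_that("corrected stability exceeds the tree radius for quadratic networks", {
  net <- small_er_quad(W_EE = 0.8)
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf, frequency_grid(n = 2^10 + 1), store = "F")
  cs <- corrected_stability(net, mf, fr)
  expect_gt(cs, fr$radius)
  expect_true(is.finite(cs))
})

test_that("one-loop corrections stay small for the exponential design", {
  # balanced weight ratios so the net input weight onto each neuron is 0
  net <- make_er_ei_network(
    ei_network_params(W_EE = 0.5, weight_ratios = c(1, -2, 0.4, -2), seed = 5),
    transfer = transfer_function("exponential", alpha = 0.1),
    baseline = -1.5)
  mf <- solve_mean_field(net)
  expect_true(mf$converged)
  fr <- propagator(net, mf, frequency_grid(n = 2^9 + 1), store = "F")
  r1 <- one_loop_rate(fr, mf, net)
  expect_lt(mean(abs(r1)) / mean(mf$rbar), 0.15)
})

test_that("cutoff-sensitivity guard fires on an undersized frequency band", {
  net <- scalar_quad_net()
  mf <- solve_mean_field(net)
  fr <- propagator(net, mf, frequency_grid(omega_max = 0.05, n = 257))
  expect_error(one_loop_rate(fr, mf, net), "omega_max")
})
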