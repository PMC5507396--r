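test_that("ER generator matches block probabilities and Dale's law", {
  params <- ei_network_params(W_EE = 0.025, seed = 42)
  net <- make_er_ei_network(params)
  expect_equal(dim(net$W), c(240, 240))
  expect_true(all(diag(net$W) == 0))
  e <- which(net$cell_type == "E"); i <- which(net$cell_type == "I")
  expect_true(all(net$W[, e] >= 0))
  expect_true(all(net$W[, i] <= 0))
  # E-E edge count within 3 binomial SD of p * N_E * (N_E - 1)
  n_ee <- sum(net$W[e, e] != 0)
  mu <- 0.2 * 200 * 199
  sd3 <- 3 * sqrt(mu * 0.8)
  expect_lt(abs(n_ee - mu), sd3)
  # weights take the four prescribed values
  expect_equal(sort(unique(as.vector(net$W))),
               sort(unique(c(0, 0.025, -0.1, 0.025 * 0.4, -0.1))))
})

test_that("zero connection probabilities give an empty matrix", {
  params <- ei_network_params(N_E = 10, N_I = 5, p_EE = 0, p_EI = 0,
                              p_IE = 0, p_II = 0)
  expect_true(all(make_er_ei_network(params)$W == 0))
})

test_that("net inhibitory input weight is about twice the excitatory", {
  net <- make_er_ei_network(ei_network_params(W_EE = 0.1, seed = 3))
  exc <- rowSums(pmax(net$W, 0))
  inh <- rowSums(pmax(-net$W, 0))
  # expectation: (0.5 * 40 * 0.4) / (0.2 * 200 * 0.1) = 2 for E targets
  expect_equal(mean(inh) / mean(exc), 2, tolerance = 0.05)
})

test_that("degree marginals follow the truncated power law", {
  spec <- degree_spec(gamma2 = -1.5, L1 = 0, L2 = 200, rho = 0.8)
  deg <- sample_powerlaw_copula_degrees(spec, 1e4, seed = 11)
  # KS distance of each marginal against the target discrete CDF
  for (d in list(deg$in_degree, deg$out_degree)) {
    ecdf_d <- stats::ecdf(d)(spec$support)
    expect_lt(max(abs(ecdf_d - spec$cdf)), 0.05)
  }
  # log-log tail slope close to gamma2 (fit over the first decade, where
  # counts are large)
  tab <- table(factor(deg$out_degree, levels = 1:200))
  sel <- 1:10
  fit <- stats::lm(log(as.numeric(tab[sel])) ~ log(sel))
  expect_lt(abs(stats::coef(fit)[2] - (-1.5)), 0.15)
})

test_that("copula correlation controls the degree rank correlation", {
  spec0 <- degree_spec(rho = 0)
  d0 <- sample_powerlaw_copula_degrees(spec0, 1e4, seed = 5)
  rho0 <- stats::cor(d0$in_degree, d0$out_degree, method = "spearman")
  expect_lt(abs(rho0), 0.05)
  spec8 <- degree_spec(rho = 0.8)
  d8 <- sample_powerlaw_copula_degrees(spec8, 1e4, seed = 6)
  rho8 <- stats::cor(d8$in_degree, d8$out_degree, method = "spearman")
  # continuous-margin Gaussian-copula Spearman, (6/pi) asin(rho/2), is
  # attenuated here by the heavy ties of the discrete marginal; the exact
  # tied value is rho_S = 12 E[Fm(X) Fm(Y)] - 3 with Fm the mid-CDF,
  # computed by direct quadrature over the latent bivariate normal
  cdf <- spec8$cdf
  Fm <- cdf - spec8$pmf / 2                   # mid-distribution function
  cuts <- stats::qnorm(c(0, cdf))             # latent-normal cut points
  s <- sqrt(1 - 0.8^2)
  z <- seq(-6, 6, length.out = 4001)
  dz <- z[2] - z[1]
  cond <- outer(z, cuts[-1], function(zz, cc) stats::pnorm((cc - 0.8 * zz) / s)) -
    outer(z, cuts[-length(cuts)], function(zz, cc) stats::pnorm((cc - 0.8 * zz) / s))
  Eg_given_z <- drop(cond %*% Fm)
  a_of_z <- findInterval(z, cuts, rightmost.closed = TRUE)
  EFG <- sum(stats::dnorm(z) * Fm[a_of_z] * Eg_given_z) * dz
  rho_target <- 12 * EFG - 3
  expect_lt(abs(rho_target - (6 / pi) * asin(0.4)), 0.1)  # mild attenuation
  expect_lt(abs(rho8 - rho_target), 0.05)
})

test_that("two-piece degree distribution is continuous at the knee", {
  spec <- degree_spec(gamma1 = 0.8, gamma2 = -1.5, L1 = 20, L2 = 200)
  p <- spec$pmf
  # ratio across the knee follows the falling branch, not a jump
  expect_equal(p[20] / p[21], (20 / 21)^(-1.5), tolerance = 1e-10)
  expect_equal(sum(p), 1)
})

test_that("heavy-tailed generator biases edges by target degrees", {
  params <- ei_network_params(W_EE = 0.8, seed = 21)
  net <- suppressWarnings(make_heavytail_network(params, lognorm_location = 0.3))
  e <- seq_len(200)
  expect_true(all(diag(net$W) == 0))
  expect_true(all(net$W[, e] >= 0))
  realized_in <- rowSums(net$W[e, e] != 0)
  target_in <- attr(net, "target_in_degree")
  expect_gt(stats::cor(realized_in, target_in, method = "spearman"), 0.5)
  # edge count within 3 binomial SD of the clipped-probability expectation
  # (the degree bias pushes many pair likelihoods past 1 at these cutoffs,
  # and those are clipped, with the count recorded on the network)
  lik <- outer(target_in, attr(net, "target_out_degree"))
  diag(lik) <- 0
  prob <- pmin(0.2 * 200 * 199 / sum(lik) * lik, 1)
  expect_gt(attr(net, "clipped"), 0)
  n_ee <- sum(net$W[e, e] != 0)
  mu <- sum(prob)
  expect_lt(abs(n_ee - mu), 3 * sqrt(sum(prob * (1 - prob))) + 3)
})

test_that("equal target degrees reduce the heavy-tail sampler to ER", {
  # a degenerate spec whose support is a single degree value
  spec <- degree_spec(gamma2 = -1.5, L1 = 0, L2 = 1, rho = 0)
  params <- ei_network_params(N_E = 100, N_I = 5, W_EE = 0.5, seed = 9)
  net <- make_heavytail_network(params, spec = spec, lognorm_location = 0.2)
  e <- seq_len(100)
  n_ee <- sum(net$W[e, e] != 0)
  mu <- 0.2 * 100 * 99
  expect_lt(abs(n_ee - mu), 3 * sqrt(mu * 0.8))
})

test_that("lognormal weights have the advertised location and mean", {
  mu <- lognorm_location_for_mean(1.125)
  expect_equal(exp(mu + mu^2 / 2), 1.125, tolerance = 1e-9)
  params <- ei_network_params(W_EE = 1.125, seed = 13)
  net <- suppressWarnings(make_heavytail_network(params, lognorm_location = mu))
  m <- attr(net, "realized_mean_ee")
  expect_equal(m, 1.125, tolerance = 0.15)  # sampling variability
  expect_error(lognorm_location_for_mean(0.9), "cannot")
})

test_that("weight matrices and cell types round-trip through text files", {
  net <- make_er_ei_network(ei_network_params(N_E = 10, N_I = 3, seed = 2))
  f <- tempfile(); g <- tempfile()
  write_weight_matrix(net$W, f)
  write_cell_types(net$cell_type, g)
  expect_equal(read_weight_matrix(f), net$W, ignore_attr = TRUE)
  expect_equal(read_cell_types(g), net$cell_type)
})
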