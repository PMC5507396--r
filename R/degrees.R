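#' Truncated two-piece power-law degree distribution
#'
#' Marginal distribution of in- and out-degrees for the heavy-tailed
#' network ensemble: \eqn{p(d) \propto C_1 d^{\gamma_1}} for
#' \eqn{1 \le d \le L_1} and \eqn{C_2 d^{\gamma_2}} for
#' \eqn{L_1 < d \le L_2}, with the constants chosen so the two branches
#' meet continuously at \eqn{L_1} and the probabilities sum to one.
#' Degrees are integers; when `L1 = 0` the rising branch is empty and the
#' support is the pure falling power law on `{1, ..., L2}` (the only
#' normalizable reading, since \eqn{d^{\gamma_2}} with negative
#' \eqn{\gamma_2} is singular at 0).
#'
#' @param gamma1,gamma2 Rising and falling exponents (defaults 0.8, -1.5).
#' @param L1,L2 Integer cutoffs, `L1 <= L2`.
#' @param rho Correlation of the Gaussian copula coupling in- and
#'   out-degrees, in (-1, 1).
#'
#' @return An object of class `degree_spec` with the support and pmf.
#' @export
degree_spec <- function(gamma1 = 0.8, gamma2 = -1.5, L1 = 0, L2 = 200,
                        rho = 0.8) {
  if (L1 > L2) stop("`L1` must be <= `L2`", call. = FALSE)
  if (L2 < 1) stop("empty degree support", call. = FALSE)
  if (abs(rho) >= 1) stop("`rho` must lie in (-1, 1)", call. = FALSE)
  d <- seq_len(L2)
  if (L1 >= 1) {
    # continuity at L1: C1 * L1^gamma1 = C2 * L1^gamma2
    C1 <- L1^(gamma2 - gamma1)
    p <- ifelse(d <= L1, C1 * d^gamma1, d^gamma2)
  } else {
    p <- d^gamma2
  }
  p <- p / sum(p)
  structure(list(gamma1 = gamma1, gamma2 = gamma2, L1 = L1, L2 = L2,
                 rho = rho, support = d, pmf = p, cdf = cumsum(p)),
            class = "degree_spec")
}

#' @export
print.degree_spec <- function(x, ...) {
  cat(sprintf("<degree_spec> d^%g up to L1 = %d, d^%g up to L2 = %d, copula rho = %g\n",
              x$gamma1, x$L1, x$gamma2, x$L2, x$rho))
  invisible(x)
}

#' Sample copula-coupled in/out degree pairs
#'
#' Draws `n` (in, out) degree pairs whose marginals follow the truncated
#' power law of `spec` and whose dependence is a Gaussian copula with
#' latent correlation `rho`: a bivariate standard normal is sampled,
#' mapped to uniforms, and inverted through the discrete degree CDF. For a
#' Gaussian copula the implied Spearman rank correlation (before
#' discretization ties) is \eqn{(6/\pi)\,\mathrm{asin}(\rho/2)}.
#'
#' @param spec A [degree_spec()].
#' @param n Number of pairs.
#' @param seed Optional RNG seed.
#'
#' @return A tibble with integer columns `in_degree`, `out_degree`.
#' @export
sample_powerlaw_copula_degrees <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "degree_spec"))
  if (!is.null(seed)) set.seed(seed)
  rho <- spec$rho
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  q <- function(u) spec$support[findInterval(u, c(0, spec$cdf),
                                             rightmost.closed = TRUE)]
  tibble::tibble(in_degree = q(stats::pnorm(z1)),
                 out_degree = q(stats::pnorm(z2)))
}

#' Generate a heavy-tailed E-I network
#'
#' Builds the same block structure as [make_er_ei_network()] but replaces
#' the E-to-E block: target in/out degree pairs are drawn from the
#' copula-coupled truncated power law, each ordered E pair (i <- j) is
#' connected independently with probability proportional to
#' `in_i * out_j` (normalized so the expected E-E connection count matches
#' `p_EE * N_E * (N_E - 1)`, probabilities clipped at 1 with a recorded
#' count), and present E-E weights are drawn i.i.d. lognormal with equal
#' location and scale parameters `mu = sigma = lognorm_location` on the
#' natural-log scale. The other three blocks keep their delta-distributed
#' type weights.
#'
#' @param params An [ei_network_params()].
#' @param spec A [degree_spec()]; defaults to the standard ensemble with
#'   `L2 = N_E`.
#' @param lognorm_location Location (= scale) parameter of the lognormal
#'   E-E weight distribution. See [lognorm_location_for_mean()] to target a
#'   mean weight.
#' @param filter,transfer,baseline As in [make_er_ei_network()].
#'
#' @return A [network_model()] with attributes `clipped` (number of edge
#'   probabilities clipped at 1) and `realized_mean_ee` (mean of the
#'   sampled E-E weights).
#' @export
make_heavytail_network <- function(params, spec = NULL,
                                   lognorm_location = 0.5,
                                   filter = synaptic_filter(),
                                   transfer = transfer_function("threshold_powerlaw"),
                                   baseline = 0.1) {
  stopifnot(inherits(params, "ei_network_params"))
  if (is.null(spec)) spec <- degree_spec(L2 = params$N_E)
  net <- make_er_ei_network(params, filter, transfer, baseline)
  N_E <- params$N_E
  deg <- sample_powerlaw_copula_degrees(spec, N_E)
  # edge likelihoods: P(i <- j) = q * in_i * out_j, i != j
  lik <- outer(deg$in_degree, deg$out_degree)
  diag(lik) <- 0
  q <- params$p_EE * N_E * (N_E - 1) / sum(lik)
  prob <- q * lik
  clipped <- sum(prob > 1)
  if (clipped > 0) {
    warning(sprintf("%d edge probabilities clipped at 1", clipped), call. = FALSE)
    prob[prob > 1] <- 1
  }
  A <- matrix(stats::runif(N_E * N_E) < prob, N_E, N_E)
  if (lognorm_location < 0)
    stop("`lognorm_location` must be nonnegative (it is also the scale)",
         call. = FALSE)
  mu <- lognorm_location
  Wee <- matrix(0, N_E, N_E)
  Wee[A] <- stats::rlnorm(sum(A), meanlog = mu, sdlog = mu)
  eidx <- seq_len(N_E)
  net$W[eidx, eidx] <- Wee
  attr(net, "clipped") <- clipped
  attr(net, "realized_mean_ee") <- if (any(A)) mean(Wee[A]) else NA_real_
  attr(net, "target_in_degree") <- deg$in_degree
  attr(net, "target_out_degree") <- deg$out_degree
  net
}

#' Lognormal location parameter for a target mean weight
#'
#' With equal location and scale parameters `mu = sigma`, the lognormal
#' mean is \eqn{\exp(\mu + \mu^2/2)}. The scale must be nonnegative, so
#' `mu >= 0` and the attainable means are `>= 1` (in the weight units
#' used); this inverts the relation on that domain.
#'
#' @param m Target mean weight (mV), at least 1.
#' @return The location parameter `mu`.
#' @export
lognorm_location_for_mean <- function(m) {
  if (any(m < 1))
    stop("with scale = location >= 0 the lognormal mean cannot be below 1",
         call. = FALSE)
  vapply(m, function(mi) stats::uniroot(function(mu) mu + mu^2 / 2 - log(mi),
                                        c(0, 50), tol = 1e-12)$root, numeric(1))
}
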