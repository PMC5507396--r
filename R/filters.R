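#' Synaptic interaction filter
#'
#' All network interactions share a single causal, unit-normalized temporal
#' kernel modelling the postsynaptic potential. The built-in kernel is the
#' alpha function \eqn{g(t) = (t/\tau^2) e^{-t/\tau}} for \eqn{t \ge 0},
#' which integrates to 1 so that synaptic weights (in mV) set the full
#' magnitude of an interaction.
#'
#' @param tau Time constant of the kernel, in ms. Must be positive.
#' @param kind Kernel family. Only `"alpha"` is implemented; the argument
#'   exists so other causal kernels can be added without changing callers.
#'
#' @return An object of class `synaptic_filter`.
#' @examples
#' g <- synaptic_filter(tau = 10)
#' filter_kernel(g, c(0, 10, 20))
#' @export
synaptic_filter <- function(tau = 10, kind = "alpha") {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("`tau` must be a single positive number (ms)", call. = FALSE)
  kind <- match.arg(kind, "alpha")
  structure(list(tau = tau, kind = kind), class = "synaptic_filter")
}

#' @export
print.synaptic_filter <- function(x, ...) {
  cat(sprintf("<synaptic_filter> %s kernel, tau = %g ms\n", x$kind, x$tau))
  invisible(x)
}

#' Evaluate the synaptic kernel in the time domain
#'
#' @param filter A [synaptic_filter()].
#' @param t Times in ms (any finite numeric vector). The kernel is causal:
#'   it is exactly zero for `t < 0`.
#'
#' @return Numeric vector of kernel values, units 1/ms.
#' @export
filter_kernel <- function(filter, t) {
  stopifnot(inherits(filter, "synaptic_filter"))
  if (!is.numeric(t) || any(!is.finite(t)))
    stop("`t` must be finite numeric", call. = FALSE)
  tau <- filter$tau
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (t[pos] / tau^2) * exp(-t[pos] / tau)
  out
}

#' Frequency response of the synaptic kernel
#'
#' Fourier transform of the alpha kernel, \eqn{g(\omega) = 1/(1 + i\omega\tau)^2}.
#' It equals 1 at zero frequency (unit normalization) and its modulus
#' decreases monotonically in \eqn{|\omega|}.
#'
#' @param filter A [synaptic_filter()].
#' @param omega Angular frequencies, in rad/ms.
#'
#' @return Complex vector, conjugate-symmetric in `omega`.
#' @export
filter_transfer <- function(filter, omega) {
  stopifnot(inherits(filter, "synaptic_filter"))
  if (!is.numeric(omega) || any(!is.finite(omega)))
    stop("`omega` must be finite numeric", call. = FALSE)
  1 / (1 + 1i * omega * filter$tau)^2
}

#' Single-neuron transfer function
#'
#' The instantaneous firing rate of a neuron is \eqn{\phi(x)} of its summed
#' membrane input x (mV). Three families are supported:
#' \describe{
#'   \item{`threshold_linear`}{\eqn{\phi(x) = \alpha \lfloor x \rfloor_+}}
#'   \item{`threshold_powerlaw`}{\eqn{\phi(x) = \alpha \lfloor x \rfloor_+^p}}
#'   \item{`exponential`}{\eqn{\phi(x) = \alpha e^x}}
#' }
#' where \eqn{\lfloor x \rfloor_+ = \max(x, 0)}. Gains are in
#' ms^-1 mV^-p. Exact analytic derivatives of order 0, 1, 2 are available
#' through [transfer_eval()]; for the rectified kinds all derivatives are 0
#' for x < 0, and the derivative at exactly x = 0 is defined by the left
#' limit (0), so neurons with non-positive mean-field input drop out of the
#' propagator.
#'
#' @param kind One of `"threshold_linear"`, `"threshold_powerlaw"`,
#'   `"exponential"`.
#' @param alpha Gain, ms^-1 mV^-p. Must be positive.
#' @param p Power-law exponent (used only by `"threshold_powerlaw"`).
#'
#' @return An object of class `transfer_function`.
#' @examples
#' phi <- transfer_function("threshold_powerlaw", alpha = 0.1, p = 2)
#' transfer_eval(phi, 2)     # 0.1 * 2^2 = 0.4 spikes/ms
#' transfer_eval(phi, 2, 1)  # derivative 2 * 0.1 * 2 = 0.4
#' @export
transfer_function <- function(kind = c("threshold_linear", "threshold_powerlaw",
                                       "exponential"),
                              alpha = 0.1, p = 2) {
  kind <- match.arg(kind)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("`alpha` must be a single positive gain", call. = FALSE)
  if (kind == "threshold_powerlaw" &&
      (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 1))
    stop("`p` must be a single exponent >= 1", call. = FALSE)
  structure(list(kind = kind, alpha = alpha,
                 p = if (kind == "threshold_powerlaw") p else NULL),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function> %s, alpha = %g%s\n", x$kind, x$alpha,
              if (!is.null(x$p)) sprintf(", p = %g", x$p) else ""))
  invisible(x)
}

#' Evaluate a transfer function or one of its derivatives
#'
#' @param phi A [transfer_function()].
#' @param x Membrane input, mV (vectorized).
#' @param order Derivative order: 0 (the rate, ms^-1), 1, or 2.
#'
#' @return Numeric vector of \eqn{\phi^{(order)}(x)}.
#' @export
transfer_eval <- function(phi, x, order = 0L) {
  stopifnot(inherits(phi, "transfer_function"))
  if (!order %in% c(0L, 1L, 2L)) stop("`order` must be 0, 1, or 2", call. = FALSE)
  a <- phi$alpha
  switch(phi$kind,
    threshold_linear = {
      xp <- x > 0
      switch(as.character(order),
             "0" = a * pmax(x, 0),
             "1" = a * as.numeric(xp),
             "2" = numeric(length(x)))
    },
    threshold_powerlaw = {
      p <- phi$p
      xp <- pmax(x, 0)
      pos <- x > 0
      out <- numeric(length(x))
      switch(as.character(order),
             "0" = a * xp^p,
             "1" = { out[pos] <- a * p * xp[pos]^(p - 1); out },
             "2" = { out[pos] <- a * p * (p - 1) * xp[pos]^(p - 2); out })
    },
    exponential = a * exp(x),
    stop("unknown transfer kind", call. = FALSE)
  )
}
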