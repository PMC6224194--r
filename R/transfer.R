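#' Softplus neuronal transfer function
#'
#' The firing-rate transfer function \eqn{\phi(I) = \alpha \log(1 + e^{I/\alpha})}
#' mapping input current to a strictly positive rate in Hz. The smoothness
#' parameter `alpha` (Hz) controls how sharply the function bends at zero;
#' \eqn{\phi} is asymptotically linear for large positive inputs and decays
#' exponentially to zero for large negative inputs.
#'
#' Evaluation is numerically stable for large `|I/alpha|` (the linear and
#' exponential asymptotes are used beyond `|I/alpha| > 30`).
#'
#' @param I input drive (any real), vectorized.
#' @param alpha smoothness, Hz; must be positive. Default 1.
#' @return firing rate, Hz (strictly positive).
#' @examples
#' transfer_phi(0)    # log(2)
#' transfer_phi(50)   # ~ 50
#' @export
transfer_phi <- function(I, alpha = 1) {
  if (!is_num(alpha) || alpha <= 0) stop("alpha must be a positive scalar")
  if (any(!is.finite(I))) stop("non-finite input to transfer function")
  z <- I / alpha
  out <- numeric(length(I))
  hi <- z > 30
  lo <- z < -30
  mid <- !hi & !lo
  out[hi] <- I[hi]
  out[lo] <- alpha * exp(z[lo])
  out[mid] <- alpha * log1p(exp(z[mid]))
  out
}

#' Gain (derivative) of the softplus transfer function
#'
#' \eqn{\phi'(I) = 1 / (1 + e^{-I/\alpha})}, the logistic function. The gain at
#' the quiescent operating point multiplies the connectivity modes in the
#' stability analysis.
#'
#' @inheritParams transfer_phi
#' @return derivative of [transfer_phi], dimensionless, in (0, 1).
#' @export
transfer_phi_prime <- function(I, alpha = 1) {
  if (!is_num(alpha) || alpha <= 0) stop("alpha must be a positive scalar")
  if (any(!is.finite(I))) stop("non-finite input to transfer function")
  1 / (1 + exp(-I / alpha))
}
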