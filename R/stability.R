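## Linear stability of the uniform quiescent state of the ring network.
## The first spatial Fourier mode of a perturbation obeys
##   tau * lambda = -(1 - weven * x0 * phi'/2) +/- i * wodd * x0 * phi'/2,
## so the state destabilizes to a traveling wave (replay) once
## weven * x0 * phi' > 2; the odd mode sets the wave frequency.

#' Stability specification of the quiescent state
#'
#' @param w0,weven,wodd connectivity Fourier modes (weight units).
#' @param gain transfer-function gain `phi'` at the quiescent operating point.
#' @param tau rate time constant, seconds.
#' @param x0 depression fixed-point value in (0, 1]; 1 when depression is
#'   disabled.
#' @return an object of class `stability_spec`.
#' @export
stability_spec <- function(w0 = 0, weven = 0, wodd = 0, gain = 1,
                           tau = 0.010, x0 = 1) {
  check_that(
    "gain must be > 0" = is_num(gain) && gain > 0,
    "tau must be > 0" = is_num(tau) && tau > 0,
    "x0 must lie in (0, 1]" = is_num(x0) && x0 > 0 && x0 <= 1
  )
  structure(list(w0 = w0, weven = weven, wodd = wodd, gain = gain,
                 tau = tau, x0 = x0), class = "stability_spec")
}

#' Eigenvalues of the first spatial mode
#'
#' Complex pair governing cosine/sine perturbations of the uniform state:
#' \deqn{\lambda = \left[-(1 - w_{even} x_0 \phi'/2) \pm i\, w_{odd} x_0
#' \phi'/2\right]/\tau.}
#' Instability iff `Re lambda > 0`; the traveling-wave frequency is
#' `omega = wodd * x0 * phi' / (2 tau)` rad/s.
#'
#' @param spec a [stability_spec()].
#' @return list with the complex `lambda` pair, `unstable` flag and wave
#'   frequency `omega` (rad/s).
#' @export
eigenvalues_spatial_mode <- function(spec) {
  stopifnot(inherits(spec, "stability_spec"))
  g <- spec$gain * spec$x0
  re <- -(1 - spec$weven * g / 2) / spec$tau
  im <- spec$wodd * g / 2 / spec$tau
  list(lambda = complex(real = c(re, re), imaginary = c(im, -im)),
       unstable = re > 0,
       omega = im)
}

#' Critical even-mode amplitude
#'
#' The even connectivity mode at which the quiescent state loses stability:
#' `2 / (gain * x0)`. Depression (`x0 < 1`) weakens the effective recurrence
#' and raises the threshold.
#'
#' @param gain transfer gain at the operating point, > 0.
#' @param x0 depression fixed point in (0, 1].
#' @return threshold value of `weven` (weight units).
#' @export
critical_even_mode <- function(gain, x0 = 1) {
  stopifnot(is_num(gain), is_num(x0), gain * x0 > 0)
  2 / (gain * x0)
}

#' Numeric Jacobian threshold on the discretized ring
#'
#' Independent numeric verification of the analytic instability threshold:
#' builds the linear ring with connectivity
#' `(1/N) (w0 + weven cos(dtheta) + wodd sin(dtheta))`, forms the Jacobian
#' `(-I + gain * G) / tau`, and bisects on `weven` for the point where the
#' largest real part of the eigenvalues crosses zero.
#'
#' @param N ring size (>= 16).
#' @param w0,wodd fixed modes during the bisection.
#' @param gain transfer gain.
#' @param tau rate time constant, seconds.
#' @param lower,upper bisection bracket for `weven`.
#' @param tol bisection tolerance.
#' @return list with `threshold`, the bracket used and the residual real part
#'   at the threshold.
#' @export
jacobian_threshold_oracle <- function(N = 100, w0 = 0, wodd = 0, gain = 1,
                                      tau = 0.010, lower = 0.5, upper = 4,
                                      tol = 1e-6) {
  stopifnot(N >= 16)
  th <- seq(-pi, pi, length.out = N + 1)[1:N]
  dth <- outer(th, th, "-")
  max_re <- function(weven) {
    G <- (w0 + weven * cos(dth) + wodd * sin(dth)) / N
    J <- (-diag(N) + gain * G) / tau
    max(Re(eigen(J, only.values = TRUE)$values))
  }
  f_lo <- max_re(lower)
  f_hi <- max_re(upper)
  if (f_lo > 0 || f_hi < 0) stop("bisection bracket does not straddle the threshold")
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (max_re(mid) > 0) hi <- mid else lo <- mid
  }
  thr <- (lo + hi) / 2
  list(threshold = thr, bracket = c(lower, upper), residual = max_re(thr))
}

#' Quiescent operating point of the nonlinear network
#'
#' Solves the uniform fixed point of the softplus network without place-field
#' input: `r0 = phi(wbar * x0(r0) * r0 + I0)` with `wbar = w0 - wI` the mean
#' effective coupling and `x0(r0) = 1/(1 + tau_x U0 r0)` the depression fixed
#' point, then evaluates the gain `phi'` at the operating input. This is the
#' gain entering the replay-instability threshold: during quiescence it
#' depends only on the (constant) mean input.
#'
#' @param w0 mean recurrent weight (raw, before subtracting `wI`).
#' @param params a [network_params()] (supplies `wI`, `alpha`).
#' @param I0 baseline drive during quiescence, Hz.
#' @param dep a [depression_params()] or `NULL` to disable depression.
#' @return list with `r0` (Hz), `x0`, `drive` (operating input), `gain`.
#' @export
quiescent_operating_point <- function(w0, params, I0, dep = NULL) {
  stopifnot(inherits(params, "network_params"))
  wbar <- w0 - params$wI
  g <- if (is.null(dep)) 0 else dep$tau_x * dep$U0
  fun <- function(r) {
    x <- 1 / (1 + g * r)
    transfer_phi(wbar * x * r + I0, params$alpha) - r
  }
  upper <- max(transfer_phi(I0, params$alpha), 1)
  while (fun(upper) > 0 && upper < 1e9) upper <- upper * 2
  r0 <- uniroot(fun, c(0, upper), tol = 1e-12)$root
  x0 <- 1 / (1 + g * r0)
  drive <- wbar * x0 * r0 + I0
  list(r0 = r0, x0 = x0, drive = drive,
       gain = transfer_phi_prime(drive, params$alpha))
}
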