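#' Network parameters
#'
#' Container for the firing-rate network: `N` place cells with rate time
#' constant `tau`, softplus smoothness `alpha`, a global inhibitory offset `wI`
#' subtracted from every recurrent weight, hard weight bounds `[0, wmax]`, a
#' uniform initial weight `w_init`, and the Euler step `dt`.
#'
#' Defaults are the standard simulation values: `tau` = 10 ms, `N` = 100,
#' `alpha` = 1 Hz, `wI` = 65, `wmax` = 80, `w_init` = 40, `dt` = 1 ms.
#'
#' @param N number of neurons (>= 2).
#' @param tau rate time constant, seconds.
#' @param alpha transfer-function smoothness, Hz.
#' @param wI global inhibitory offset (weight units).
#' @param wmax upper weight bound.
#' @param w_init initial weight, in `[0, wmax]`.
#' @param dt integration step, seconds; must be much smaller than `tau`.
#' @return an object of class `network_params`.
#' @export
network_params <- function(N = 100, tau = 0.010, alpha = 1, wI = 65,
                           wmax = 80, w_init = 40, dt = 0.001) {
  check_that(
    "N must be an integer >= 2" = is_num(N) && N >= 2 && N == round(N),
    "tau must be > 0" = is_num(tau) && tau > 0,
    "alpha must be > 0" = is_num(alpha) && alpha > 0,
    "wI must be finite" = is_num(wI),
    "wmax must be > 0" = is_num(wmax) && wmax > 0,
    "w_init must lie in [0, wmax]" = is_num(w_init) && w_init >= 0 && w_init <= wmax,
    "dt must be > 0 and << tau" = is_num(dt) && dt > 0 && dt <= tau / 2
  )
  structure(list(N = as.integer(N), tau = tau, alpha = alpha, wI = wI,
                 wmax = wmax, w_init = w_init, dt = dt),
            class = "network_params")
}

#' Place-field input configuration
#'
#' External drive to cell `i`:
#' \deqn{I_i(t) = I_0 + I_{PF} \cos(\theta_i - X(t)) (1 + I_{theta} \cos(2\pi f t))}
#' when `place_field_on`, else the constant baseline `I0` alone. `Itheta` is
#' the (dimensionless) depth of the multiplicative theta modulation and `f` its
#' frequency in Hz. Defaults: `I0` = 3 Hz, `IPF` = 25 Hz, `Itheta` = 1,
#' `f` = 8 Hz.
#'
#' @param I0 baseline drive, Hz.
#' @param IPF place-field amplitude, Hz.
#' @param Itheta modulation depth, dimensionless, >= 0.
#' @param f modulation frequency, Hz, >= 0.
#' @param place_field_on logical; `FALSE` gives constant input `I0`.
#' @return an object of class `input_config`.
#' @export
input_config <- function(I0 = 3, IPF = 25, Itheta = 1, f = 8,
                         place_field_on = TRUE) {
  check_that(
    "I0 must be finite" = is_num(I0),
    "IPF must be finite" = is_num(IPF),
    "Itheta must be >= 0" = is_num(Itheta) && Itheta >= 0,
    "f must be >= 0" = is_num(f) && f >= 0,
    "place_field_on must be logical" = is.logical(place_field_on) && length(place_field_on) == 1L
  )
  structure(list(I0 = I0, IPF = IPF, Itheta = Itheta, f = f,
                 place_field_on = place_field_on),
            class = "input_config")
}

#' Virtual-animal motion model
#'
#' Either constant angular velocity (`kind = "constant"`) or a biased
#' Ornstein-Uhlenbeck (OU) velocity process (`kind = "ou"`):
#' \eqn{v(t) = v_0 + v_1(t)}, \eqn{\tau_v \dot v_1 = -v_1 + \sigma_v \xi(t)}.
#' Position integrates the velocity and is wrapped to `[-pi, pi)`.
#'
#' The continuum OU equation is discretized as
#' `v1 <- v1 + dt*(-v1/tau_v) + (sigma_v/tau_v)*sqrt(dt)*eta` under the default
#' `sigma_scaling = "sigma_over_tau"`; the alternative convention
#' `"sigma_sqrt_tau"` uses `sigma_v*sqrt(dt/tau_v)*eta`. Defaults: `v0` = 0.5
#' rad/s, `tau_v` = 10 s, `sigma_v` = 2 rad/s.
#'
#' @param kind `"constant"` or `"ou"`.
#' @param v_const fixed velocity, rad/s (kind `"constant"`).
#' @param v0 mean velocity, rad/s (kind `"ou"`).
#' @param sigma_v OU noise amplitude, rad/s.
#' @param tau_v OU time constant, seconds, > 0.
#' @param sigma_scaling noise-scaling convention, see Details.
#' @return an object of class `motion_model`.
#' @export
motion_model <- function(kind = c("ou", "constant"), v_const = 1, v0 = 0.5,
                         sigma_v = 2, tau_v = 10,
                         sigma_scaling = c("sigma_over_tau", "sigma_sqrt_tau")) {
  kind <- match.arg(kind)
  sigma_scaling <- match.arg(sigma_scaling)
  check_that(
    "v_const must be finite" = is_num(v_const),
    "v0 must be finite" = is_num(v0),
    "sigma_v must be >= 0" = is_num(sigma_v) && sigma_v >= 0,
    "tau_v must be > 0" = is_num(tau_v) && tau_v > 0
  )
  structure(list(kind = kind, v_const = v_const, v0 = v0, sigma_v = sigma_v,
                 tau_v = tau_v, sigma_scaling = sigma_scaling),
            class = "motion_model")
}

#' Short-term synaptic depression parameters
#'
#' Each neuron carries a depression variable
#' \eqn{\dot x_i = (1 - x_i)/\tau_x - U_0 x_i r_i} gating its outgoing
#' synapses. `U0 = 0` disables depression (x stays at 1). Defaults:
#' `tau_x` = 800 ms, `U0` = 0.0008.
#'
#' @param tau_x recovery time constant, seconds, > 0.
#' @param U0 per-spike utilization rate, >= 0.
#' @return an object of class `depression_params`.
#' @export
depression_params <- function(tau_x = 0.8, U0 = 0.0008) {
  check_that(
    "tau_x must be > 0" = is_num(tau_x) && tau_x > 0,
    "U0 must be >= 0" = is_num(U0) && U0 >= 0
  )
  structure(list(tau_x = tau_x, U0 = U0), class = "depression_params")
}
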