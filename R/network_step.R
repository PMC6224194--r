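## Single-step operations of the ring network, exposed for unit testing and
## composition; simulate_ring() runs the same updates in a compiled loop.

#' Advance the virtual animal by one time step
#'
#' For OU motion, an Euler-Maruyama update of the velocity fluctuation
#' followed by a position update; for constant motion a linear advance.
#' Position is wrapped to `[-pi, pi)`.
#'
#' Consumes exactly one standard normal draw from the R RNG when
#' `model$kind == "ou"`.
#'
#' @param position current angle, rad.
#' @param v1 current OU velocity fluctuation, rad/s (ignored for constant
#'   motion).
#' @param model a [motion_model()].
#' @param dt time step, seconds.
#' @return list with `position`, `velocity` (total), `v1`.
#' @export
step_motion <- function(position, v1, model, dt) {
  stopifnot(inherits(model, "motion_model"), dt > 0)
  if (model$kind == "ou") {
    noise <- if (model$sigma_scaling == "sigma_over_tau") {
      model$sigma_v / model$tau_v * sqrt(dt)
    } else {
      model$sigma_v * sqrt(dt / model$tau_v)
    }
    v1 <- v1 + dt * (-v1 / model$tau_v) + noise * rnorm(1)
    vel <- model$v0 + v1
  } else {
    vel <- model$v_const
  }
  list(position = wrap_angle(position + vel * dt), velocity = vel, v1 = v1)
}

#' Place-field input to all neurons
#'
#' `I_i = I0 + IPF cos(theta_i - X) (1 + Itheta cos(2 pi f t))` for tuned
#' cells when the place-field input is on; untuned cells receive
#' `untuned_I0`; with the place field off all cells receive `I0`.
#'
#' @param input an [input_config()].
#' @param centers place-field centers, rad.
#' @param position animal angle, rad.
#' @param t absolute time, seconds (phase of the theta modulation).
#' @param tuned logical mask of tuned cells.
#' @param untuned_I0 baseline for untuned cells, Hz.
#' @return input vector, Hz.
#' @export
place_field_input <- function(input, centers, position, t,
                              tuned = rep(TRUE, length(centers)),
                              untuned_I0 = 0) {
  stopifnot(inherits(input, "input_config"))
  if (!input$place_field_on) {
    return(rep(input$I0, length(centers)))
  }
  mod <- 1 + input$Itheta * cos(2 * pi * input$f * t)
  I <- ifelse(tuned,
              input$I0 + input$IPF * cos(centers - position) * mod,
              untuned_I0)
  I
}

#' One forward-Euler step of the rate and depression dynamics
#'
#' Updates `tau r' = -r + phi((1/N) sum_j (w_ij - wI) x_j r_j + I_i)` and
#' `x' = (1 - x)/tau_x - U0 x r` with explicit Euler. Returns the drive
#' (argument of phi) as well, whose network average is the model's LFP proxy.
#'
#' @param r rate vector, Hz.
#' @param x depression vector.
#' @param W weight matrix (post-by-pre).
#' @param I input vector, Hz.
#' @param params a [network_params()].
#' @param dep a [depression_params()].
#' @param linear_phi use the identity transfer (theory-validation mode).
#' @return list with updated `r`, `x` and the `drive` vector.
#' @export
step_network <- function(r, x, W, I, params, dep, linear_phi = FALSE) {
  stopifnot(inherits(params, "network_params"),
            inherits(dep, "depression_params"))
  if (any(!is.finite(r)) || any(!is.finite(x))) {
    stop("non-finite network state")
  }
  N <- params$N
  xr <- x * r
  drive <- as.vector(W %*% xr - params$wI * sum(xr)) / N + I
  phi <- if (linear_phi) drive else transfer_phi(drive, params$alpha)
  r_new <- r + params$dt / params$tau * (-r + phi)
  x_new <- x + params$dt * ((1 - x) / dep$tau_x - dep$U0 * x * r)
  list(r = r_new, x = x_new, drive = drive)
}

#' Bernoulli spike draws from instantaneous rates
#'
#' Each neuron spikes independently with probability `r * dt` (clipped at 1
#' with a warning when violated). Consumes exactly `length(r)` uniform draws.
#'
#' @param r rate vector, Hz.
#' @param dt time step, seconds.
#' @return integer 0/1 vector of spikes.
#' @export
generate_spikes <- function(r, dt) {
  p <- r * dt
  if (any(p > 1)) {
    warning(sum(p > 1), " neuron(s) with r*dt > 1; probabilities clipped")
    p <- pmin(p, 1)
  }
  as.integer(runif(length(r)) < p)
}

#' Network-averaged input current (model LFP proxy)
#'
#' The mean over neurons of the argument of the transfer function at each
#' recorded step; for simulation output this column is recorded directly, and
#' this helper recomputes it from saved rates, depression and weights.
#'
#' @param rates bins-by-neurons matrix of rates, Hz.
#' @param depression matching depression matrix.
#' @param W weight matrix.
#' @param I bins-by-neurons matrix (or vector) of inputs, Hz.
#' @param params a [network_params()].
#' @return numeric vector, one value per time bin.
#' @export
network_lfp <- function(rates, depression, W, I, params) {
  stopifnot(nrow(rates) >= 1, all(dim(rates) == dim(depression)))
  if (is.vector(I)) I <- matrix(I, nrow(rates), length(I), byrow = TRUE)
  N <- params$N
  vapply(seq_len(nrow(rates)), function(k) {
    xr <- depression[k, ] * rates[k, ]
    drive <- (as.vector(W %*% xr) - params$wI * sum(xr)) / N + I[k, ]
    mean(drive)
  }, numeric(1))
}
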