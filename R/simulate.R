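#' Simulate the plastic ring network of place cells
#'
#' Integrates the stochastic firing-rate network: softplus (or linear) rate
#' dynamics with global inhibition, short-term synaptic depression,
#' theta-modulated place-field input on a moving virtual animal, Poisson spike
#' generation, and online STDP (pairwise or triplet) shaping the recurrent
#' weights. The compiled engine (`engine = "cpp"`, default) and the pure-R
#' reference engine (`engine = "r"`) perform identical updates in identical
#' RNG order; for the same seed their trajectories agree to floating-point
#' rounding (summation order in the recurrent drive differs between BLAS and
#' the compiled loop).
#'
#' Update order per step: motion, input (at the new time/position), Euler
#' update of rates/depression, spike draws from the updated rates, plasticity.
#'
#' @param params a [network_params()].
#' @param input an [input_config()].
#' @param motion a [motion_model()].
#' @param dep a [depression_params()].
#' @param rule a plasticity rule, or `NULL` to freeze the weights.
#' @param duration simulated time, seconds.
#' @param centers place-field centers (default: uniform grid over
#'   `[-pi, pi)`).
#' @param tuned logical mask of tuned cells (untuned cells receive
#'   `untuned_I0`).
#' @param untuned_I0 baseline drive of untuned cells, Hz.
#' @param W initial weight matrix (default: constant `w_init`).
#' @param state optional continuation state (the `state` element of a previous
#'   run) carrying rates, depression, traces, position and time.
#' @param record_every record the state every this many steps (0 = none).
#' @param snapshot_every weight snapshot cadence in steps (0 = none).
#' @param record_spikes collect spike events (neuron id, time).
#' @param linear_phi use the identity transfer function (theory-validation
#'   mode).
#' @param seed optional integer; when given, `set.seed(seed)` is called.
#' @param engine `"cpp"` or `"r"`.
#' @return an object of class `ring_sim`: recorded `time`, `rates`,
#'   `depression` (bins-by-neurons), `position`, `velocity`, `lfp`, final
#'   weight matrix `W`, `snapshots` + `snapshot_times`, `spikes` data frame,
#'   a continuation `state`, and the configuration used.
#' @export
simulate_ring <- function(params = network_params(),
                          input = input_config(),
                          motion = motion_model(),
                          dep = depression_params(),
                          rule = plasticity_preset("pair"),
                          duration = 1,
                          centers = NULL,
                          tuned = NULL,
                          untuned_I0 = 0,
                          W = NULL,
                          state = NULL,
                          record_every = 10L,
                          snapshot_every = 0L,
                          record_spikes = FALSE,
                          linear_phi = FALSE,
                          seed = NULL,
                          engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "network_params"),
            inherits(input, "input_config"),
            inherits(motion, "motion_model"),
            inherits(dep, "depression_params"))
  if (!is.null(seed)) set.seed(seed)
  N <- params$N
  if (is.null(centers)) centers <- seq(-pi, pi, length.out = N + 1)[1:N]
  stopifnot(length(centers) == N)
  if (is.null(tuned)) tuned <- rep(TRUE, N)
  if (is.null(W)) W <- matrix(params$w_init, N, N)
  stopifnot(all(dim(W) == N), all(W >= 0), all(W <= params$wmax))

  plast_on <- !is.null(rule)
  triplet <- plast_on && inherits(rule, "triplet_rule")
  if (!plast_on) rule <- pair_rule() # placeholder parameters, unused

  if (is.null(state)) {
    state <- list(r = rep(transfer_phi(input$I0, params$alpha), N),
                  x = rep(1, N),
                  traces = new_trace_state(N, triplet = TRUE),
                  position = 0, v1 = 0, t = 0)
  }
  nsteps <- round(duration / params$dt)

  eng_args <- list(
    nsteps = as.integer(nsteps), t0 = state$t, dt = params$dt,
    W = W, wI = params$wI, wmax = params$wmax,
    tau = params$tau, alpha = params$alpha, linear_phi = linear_phi,
    r = state$r, x = state$x, tau_x = dep$tau_x, U0 = dep$U0,
    centers = centers, tuned = tuned, place_field_on = input$place_field_on,
    I0 = input$I0, IPF = input$IPF, Itheta = input$Itheta, f = input$f,
    untuned_I0 = untuned_I0,
    motion_kind = if (motion$kind == "ou") 1L else 0L,
    v_const = motion$v_const, v0 = motion$v0, sigma_v = motion$sigma_v,
    tau_v = motion$tau_v,
    sigma_scaling = if (motion$sigma_scaling == "sigma_over_tau") 0L else 1L,
    pos0 = state$position, v1_0 = state$v1,
    plast_on = plast_on, triplet = triplet,
    A2p = rule$A_plus, tau_p = rule$tau_plus,
    A2m = rule$A_minus, tau_m = rule$tau_minus,
    A3p = if (triplet) rule$A3_plus else 0,
    tau_y = if (triplet) rule$tau_y else 1,
    A3m = if (triplet) rule$A3_minus else 0,
    tau_x3 = if (triplet) rule$tau_x3 else 1,
    tr_r1 = state$traces$r1, tr_o1 = state$traces$o1,
    tr_r2 = state$traces$r2 %||% numeric(N),
    tr_o2 = state$traces$o2 %||% numeric(N),
    record_every = as.integer(record_every),
    snapshot_every = as.integer(snapshot_every),
    record_spikes = record_spikes)

  out <- if (engine == "cpp") {
    do.call(.ring_engine_cpp, eng_args)
  } else {
    do.call(ring_engine_r, eng_args)
  }
  if (out$n_rate_clips > 0) {
    warning(out$n_rate_clips, " spike probabilities r*dt > 1 were clipped")
  }
  res <- list(
    time = out$time,
    rates = out$rates, depression = out$depression,
    position = out$position, velocity = out$velocity, lfp = out$lfp,
    W = out$W, snapshots = out$snapshots, snapshot_times = out$snapshot_times,
    spikes = data.frame(neuron_id = out$spike_id, time_s = out$spike_time),
    state = list(r = out$r, x = out$x,
                 traces = structure(out$traces, class = "trace_state"),
                 position = out$pos, v1 = out$v1, t = out$t_end),
    centers = centers, tuned = tuned,
    params = params, input = input, motion = motion, dep = dep,
    rule = if (plast_on) rule else NULL,
    linear_phi = linear_phi, engine = engine, seed = seed
  )
  class(res) <- "ring_sim"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Pure-R reference engine; must stay in lockstep with src/ring_engine.cpp
## (same update rules *and* same RNG draw order).
ring_engine_r <- function(nsteps, t0, dt, W, wI, wmax, tau, alpha, linear_phi,
                          r, x, tau_x, U0, centers, tuned, place_field_on,
                          I0, IPF, Itheta, f, untuned_I0,
                          motion_kind, v_const, v0, sigma_v, tau_v,
                          sigma_scaling, pos0, v1_0, plast_on, triplet,
                          A2p, tau_p, A2m, tau_m, A3p, tau_y, A3m, tau_x3,
                          tr_r1, tr_o1, tr_r2, tr_o2,
                          record_every, snapshot_every, record_spikes) {
  N <- nrow(W)
  W <- W + 0 # force copy
  ep <- exp(-dt / tau_p); em <- exp(-dt / tau_m)
  ey <- if (triplet) exp(-dt / tau_y) else 0
  ex <- if (triplet) exp(-dt / tau_x3) else 0
  ou_noise <- if (sigma_scaling == 0) sigma_v / tau_v * sqrt(dt) else
    sigma_v * sqrt(dt / tau_v)
  n_rec <- if (record_every > 0) nsteps %/% record_every else 0
  rec_t <- rec_pos <- rec_vel <- rec_lfp <- numeric(n_rec)
  rec_r <- matrix(0, n_rec, N); rec_x <- matrix(0, n_rec, N)
  n_snap <- if (snapshot_every > 0) nsteps %/% snapshot_every else 0
  snapshots <- vector("list", n_snap); snap_t <- numeric(n_snap)
  spk_id <- integer(0); spk_t <- numeric(0)
  pos <- pos0; v1 <- v1_0
  clip_warn <- 0L; i_rec <- 0L; i_snap <- 0L
  r1 <- tr_r1; o1 <- tr_o1; r2 <- tr_r2; o2 <- tr_o2

  for (step in seq_len(nsteps)) {
    t <- t0 + step * dt
    if (motion_kind == 1) {
      v1 <- v1 + dt * (-v1 / tau_v) + ou_noise * rnorm(1)
      vel <- v0 + v1
    } else {
      vel <- v_const
    }
    pos <- wrap_angle(pos + vel * dt)

    xr <- x * r
    if (place_field_on) {
      mod <- 1 + Itheta * cos(2 * pi * f * t)
      I <- ifelse(tuned, I0 + IPF * cos(centers - pos) * mod, untuned_I0)
    } else {
      I <- rep(I0, N)
    }
    drive <- (as.vector(W %*% xr) - wI * sum(xr)) / N + I
    phi <- if (linear_phi) drive else transfer_phi(drive, alpha)
    r_new <- r + dt / tau * (-r + phi)
    x_new <- x + dt * ((1 - x) / tau_x - U0 * x * r)
    if (any(!is.finite(r_new)) || any(!is.finite(x_new))) {
      stop("non-finite network state at t = ", t)
    }
    r <- r_new; x <- x_new

    p <- r * dt
    over <- p > 1
    if (any(over)) { clip_warn <- clip_warn + sum(over); p[over] <- 1 }
    spikes <- as.integer(runif(N) < p)
    sp <- which(spikes == 1L)
    if (record_spikes && length(sp)) {
      spk_id <- c(spk_id, sp); spk_t <- c(spk_t, rep(t, length(sp)))
    }

    if (plast_on) {
      r1 <- r1 * ep; o1 <- o1 * em
      if (triplet) { r2 <- r2 * ex; o2 <- o2 * ey }
      if (length(sp)) {
        dW <- matrix(0, N, N)
        amp_post <- if (triplet) A2p + A3p * o2[sp] else rep(A2p, length(sp))
        dW[sp, ] <- dW[sp, , drop = FALSE] + outer(amp_post, r1)
        amp_pre <- if (triplet) A2m + A3m * r2[sp] else rep(A2m, length(sp))
        dW[, sp] <- dW[, sp, drop = FALSE] - outer(o1, amp_pre)
        diag(dW) <- 0
        W <- W + dW
        W[W < 0] <- 0
        W[W > wmax] <- wmax
        r1[sp] <- r1[sp] + 1; o1[sp] <- o1[sp] + 1
        if (triplet) { r2[sp] <- r2[sp] + 1; o2[sp] <- o2[sp] + 1 }
      }
    }

    if (record_every > 0 && step %% record_every == 0) {
      i_rec <- i_rec + 1L
      rec_t[i_rec] <- t; rec_pos[i_rec] <- pos; rec_vel[i_rec] <- vel
      rec_lfp[i_rec] <- mean(drive)
      rec_r[i_rec, ] <- r; rec_x[i_rec, ] <- x
    }
    if (snapshot_every > 0 && step %% snapshot_every == 0) {
      i_snap <- i_snap + 1L
      snapshots[[i_snap]] <- W; snap_t[i_snap] <- t
    }
  }
  list(time = rec_t, rates = rec_r, depression = rec_x, position = rec_pos,
       velocity = rec_vel, lfp = rec_lfp, W = W, snapshots = snapshots,
       snapshot_times = snap_t, r = r, x = x, pos = pos, v1 = v1,
       t_end = t0 + nsteps * dt,
       traces = list(r1 = r1, o1 = o1, r2 = r2, o2 = o2),
       spike_id = spk_id, spike_time = spk_t, n_rate_clips = clip_warn)
}

#' @export
print.ring_sim <- function(x, ...) {
  cat(sprintf("ring_sim: N = %d neurons, %.3g s simulated (dt = %g ms, %s engine)\n",
              x$params$N, x$state$t, x$params$dt * 1000, x$engine))
  cat(sprintf("  plasticity: %s; place-field input: %s; %d recorded frames\n",
              if (is.null(x$rule)) "off" else class(x$rule)[1],
              if (x$input$place_field_on) "on" else "off",
              length(x$time)))
  if (length(x$time)) {
    cat(sprintf("  final mean rate %.3g Hz; mean weight %.4g\n",
                mean(x$rates[nrow(x$rates), ]), mean(x$W)))
  }
  invisible(x)
}

#' @export
plot.ring_sim <- function(x, what = c("rates", "lfp", "position"), ...) {
  what <- match.arg(what)
  if (!length(x$time)) stop("nothing recorded: record_every was 0")
  switch(what,
    rates = graphics::image(x$time, seq_len(ncol(x$rates)), x$rates,
                            xlab = "time (s)", ylab = "neuron (place-field order)",
                            main = "firing rates (Hz)", useRaster = TRUE, ...),
    lfp = graphics::plot(x$time, x$lfp, type = "l", xlab = "time (s)",
                         ylab = "network-averaged input", ...),
    position = graphics::plot(x$time, x$position, type = "l", pch = 16,
                              xlab = "time (s)", ylab = "position (rad)", ...)
  )
  invisible(x)
}
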