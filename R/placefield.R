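## Place-field characterization for recording-style data (spike events plus a
## 1D position trace on a periodic track) and the synthetic-recording
## generator used to exercise the pipeline end to end.

#' Occupancy-normalized 1D rate maps from spike events
#'
#' Bins the track `[-pi, pi)` into `n_bins` position bins, accumulates spike
#' counts per cell per bin (each spike assigned the animal's position at the
#' nearest trajectory sample) and divides by the occupancy time. Optional
#' Gaussian smoothing on the periodic bin grid (off by default).
#'
#' @param events data frame with columns `neuron_id`, `time_s`.
#' @param trajectory data frame with columns `time_s` (uniform grid) and
#'   `theta` (rad).
#' @param n_bins number of position bins (default 50).
#' @param smooth_sd Gaussian smoothing SD in bins; 0 disables.
#' @param cell_ids cells to map (default: all ids present in `events`).
#' @return list of class `rate_maps`: `positions` (bin centers), `rate`
#'   (cells-by-bins matrix, Hz), `occupancy` (s), `mean_rate` (Hz per cell,
#'   spikes over total duration), `cell_ids`.
#' @export
rate_map_1d <- function(events, trajectory, n_bins = 50, smooth_sd = 0,
                        cell_ids = NULL) {
  stopifnot(all(c("neuron_id", "time_s") %in% names(events)),
            all(c("time_s", "theta") %in% names(trajectory)),
            n_bins >= 8)
  if (is.null(cell_ids)) cell_ids <- sort(unique(events$neuron_id))
  dt <- diff(trajectory$time_s[1:2])
  duration <- nrow(trajectory) * dt
  bin_of <- function(th) {
    b <- floor((wrap_angle(th) + pi) / (2 * pi) * n_bins) + 1
    pmin(b, n_bins)
  }
  occ <- tabulate(bin_of(trajectory$theta), nbins = n_bins) * dt
  t0 <- trajectory$time_s[1]
  rate <- matrix(0, length(cell_ids), n_bins)
  mean_rate <- numeric(length(cell_ids))
  for (k in seq_along(cell_ids)) {
    ev <- events$time_s[events$neuron_id == cell_ids[k]]
    mean_rate[k] <- length(ev) / duration
    if (!length(ev)) next
    idx <- pmin(pmax(round((ev - t0) / dt) + 1, 1), nrow(trajectory))
    cnt <- tabulate(bin_of(trajectory$theta[idx]), nbins = n_bins)
    rate[k, ] <- ifelse(occ > 0, cnt / occ, 0)
  }
  if (smooth_sd > 0) {
    half <- ceiling(3 * smooth_sd)
    kern <- exp(-((-half):half)^2 / (2 * smooth_sd^2))
    kern <- kern / sum(kern)
    rate <- t(apply(rate, 1, function(r) {
      rr <- c(tail(r, half), r, head(r, half))
      as.vector(stats::filter(rr, kern, sides = 2))[(half + 1):(half + n_bins)]
    }))
  }
  structure(list(positions = seq(-pi, pi, length.out = n_bins + 1)[-1] -
                   pi / n_bins,
                 rate = rate, occupancy = occ, mean_rate = mean_rate,
                 cell_ids = cell_ids),
            class = "rate_maps")
}

#' Two-harmonic cosine fit of a 1D place field
#'
#' Least-squares fit of
#' `r(theta) = r0 + r1 cos(theta - phi1) + r2 cos(2 (theta - phi2))`
#' (equivalently the first two Fourier coefficients plus phases; an FFT on a
#' uniform grid gives identical coefficients). Amplitudes are constrained
#' non-negative, with the phase absorbing the sign. The tuning index
#' `TI = r1 / r0` quantifies spatial selectivity.
#'
#' @param rate rate values over position bins, Hz.
#' @param positions bin centers, rad (uniform grid over the ring).
#' @param mean_rate session-mean firing rate, Hz (stored for cell selection;
#'   defaults to the map mean).
#' @return object of class `placefield_fit` with `r0`, `r1`, `r2`, `phi1`,
#'   `phi2`, `TI`, `mean_rate`. For flat maps (`r1 = 0`) the phase is `NA`.
#' @export
fit_cosine_model <- function(rate, positions, mean_rate = mean(rate)) {
  stopifnot(length(rate) == length(positions), length(rate) >= 8)
  if (all(rate == 0)) stop("all-zero rate map cannot be fit")
  f <- lm(rate ~ cos(positions) + sin(positions) +
            cos(2 * positions) + sin(2 * positions))
  cf <- unname(coef(f))
  r0 <- cf[1]
  r1 <- sqrt(cf[2]^2 + cf[3]^2)
  phi1 <- if (r1 > 1e-12) atan2(cf[3], cf[2]) else NA_real_
  r2 <- sqrt(cf[4]^2 + cf[5]^2)
  phi2 <- if (r2 > 1e-12) atan2(cf[5], cf[4]) / 2 else NA_real_
  structure(list(r0 = r0, r1 = r1, r2 = r2, phi1 = phi1, phi2 = phi2,
                 TI = if (r0 > 0) r1 / r0 else NA_real_,
                 mean_rate = mean_rate),
            class = "placefield_fit")
}

#' @export
print.placefield_fit <- function(x, ...) {
  cat(sprintf("place-field fit: r0 = %.3g, r1 = %.3g (phi1 = %.3f rad), r2 = %.3g; TI = %.3g\n",
              x$r0, x$r1, x$phi1, x$r2, x$TI))
  invisible(x)
}

#' @export
coef.placefield_fit <- function(object, ...) {
  c(r0 = object$r0, r1 = object$r1, r2 = object$r2,
    phi1 = object$phi1, phi2 = object$phi2)
}

#' @export
predict.placefield_fit <- function(object, positions, ...) {
  out <- rep(object$r0, length(positions))
  if (is.finite(object$phi1)) {
    out <- out + object$r1 * cos(positions - object$phi1)
  }
  if (is.finite(object$phi2)) {
    out <- out + object$r2 * cos(2 * (positions - object$phi2))
  }
  out
}

#' Select well-tuned place cells
#'
#' Keeps cells whose tuning index is at least `ti_threshold` (default 1; the
#' lax criterion is 0.5) and whose session-mean rate exceeds `rate_threshold`
#' (default 0.4 Hz).
#'
#' @param fits list of [fit_cosine_model()] results.
#' @param ti_threshold minimum TI.
#' @param rate_threshold minimum mean rate, Hz (strict inequality).
#' @return logical selection mask.
#' @export
select_cells <- function(fits, ti_threshold = 1, rate_threshold = 0.4) {
  vapply(fits, function(f) {
    isTRUE(is.finite(f$TI) && f$TI >= ti_threshold &&
             f$mean_rate > rate_threshold)
  }, logical(1))
}

#' Order cells by place-field phase
#'
#' Stable sort of the selected cells by ascending `phi1` (ties broken by cell
#' index), giving the track ordering used by the SC statistic.
#'
#' @param fits list of [fit_cosine_model()] results.
#' @param selected logical mask (default: all).
#' @return integer vector of indices into `fits`, phase-ordered.
#' @export
phase_ordering <- function(fits, selected = rep(TRUE, length(fits))) {
  idx <- which(selected)
  if (length(idx) < 2) stop("need at least 2 selected cells to order")
  phases <- vapply(fits[idx], function(f) f$phi1, numeric(1))
  if (any(!is.finite(phases))) stop("selected cells must have a defined phase")
  idx[order(phases, idx)]
}

#' Generate a synthetic place-cell recording
#'
#' Emulates a silicon-probe session on a periodic track: a biased random-walk
#' (OU-velocity) trajectory, cosine-tuned rates
#' `r_i(t) = max(0, r0_i + r1_i cos(theta_i - X(t)) (1 + m cos(2 pi f t)))`
#' with cell-specific baselines, amplitudes and uniformly random phases, and
#' Poisson (Bernoulli per step) spike generation. Ground-truth parameters are
#' returned for recovery tests. This generator is synthetic; it emulates the
#' statistical structure of recorded data, not any particular animal.
#'
#' @param n_cells number of cells.
#' @param duration session length, seconds.
#' @param r0_range,r1_range uniform sampling ranges for baseline and tuning
#'   amplitude, Hz.
#' @param m theta-modulation depth.
#' @param f theta frequency, Hz.
#' @param motion a [motion_model()] for the trajectory.
#' @param dt simulation step, seconds.
#' @param seed optional integer seed.
#' @return list of class `synthetic_recording`: `events` (neuron_id, time_s),
#'   `trajectory` (time_s, theta), `truth` (data frame: cell, theta, r0, r1),
#'   and the configuration.
#' @export
synth_recording <- function(n_cells = 50, duration = 2100,
                            r0_range = c(2, 4), r1_range = c(8, 15),
                            m = 1, f = 8,
                            motion = motion_model(),
                            dt = 0.001, seed = NULL) {
  stopifnot(n_cells >= 2, duration > 0)
  if (!is.null(seed)) set.seed(seed)
  nsteps <- round(duration / dt)
  tgrid <- seq_len(nsteps) * dt
  ## trajectory: OU velocity via its exact AR(1) discretization
  if (motion$kind == "ou") {
    a <- 1 - dt / motion$tau_v
    b <- if (motion$sigma_scaling == "sigma_over_tau") {
      motion$sigma_v / motion$tau_v * sqrt(dt)
    } else {
      motion$sigma_v * sqrt(dt / motion$tau_v)
    }
    v1 <- as.vector(stats::filter(b * rnorm(nsteps), a, "recursive"))
    vel <- motion$v0 + v1
  } else {
    vel <- rep(motion$v_const, nsteps)
  }
  X <- wrap_angle(cumsum(vel * dt))
  truth <- data.frame(
    cell = seq_len(n_cells),
    theta = runif(n_cells, -pi, pi),
    r0 = runif(n_cells, r0_range[1], r0_range[2]),
    r1 = runif(n_cells, r1_range[1], r1_range[2])
  )
  mod <- 1 + m * cos(2 * pi * f * tgrid)
  ids <- list()
  times <- list()
  for (i in seq_len(n_cells)) {
    r <- pmax(0, truth$r0[i] + truth$r1[i] * cos(truth$theta[i] - X) * mod)
    spk <- which(runif(nsteps) < r * dt)
    if (length(spk)) {
      ids[[length(ids) + 1]] <- rep(i, length(spk))
      times[[length(times) + 1]] <- tgrid[spk]
    }
  }
  events <- if (length(ids)) {
    data.frame(neuron_id = unlist(ids), time_s = unlist(times))
  } else {
    data.frame(neuron_id = integer(0), time_s = numeric(0))
  }
  events <- events[order(events$time_s), ]
  rownames(events) <- NULL
  structure(list(events = events,
                 trajectory = data.frame(time_s = tgrid, theta = X),
                 truth = truth,
                 config = list(n_cells = n_cells, duration = duration,
                               m = m, f = f, dt = dt, seed = seed)),
            class = "synthetic_recording")
}

#' Bin spike events into a rate matrix
#'
#' @param events data frame with `neuron_id`, `time_s`.
#' @param duration total duration, seconds.
#' @param bin_width bin width, seconds.
#' @param n_cells number of cells (rows); defaults to max id.
#' @return cells-by-bins matrix of spike counts per bin.
#' @export
bin_spikes <- function(events, duration, bin_width, n_cells = NULL) {
  if (is.null(n_cells)) n_cells <- max(events$neuron_id)
  n_bins <- floor(duration / bin_width)
  counts <- matrix(0, n_cells, n_bins)
  b <- pmin(floor(events$time_s / bin_width) + 1, n_bins)
  keep <- events$time_s < n_bins * bin_width
  tab <- table(factor(events$neuron_id[keep], levels = seq_len(n_cells)),
               factor(b[keep], levels = seq_len(n_bins)))
  counts[] <- as.numeric(tab)
  counts
}
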