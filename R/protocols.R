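## Experiment orchestration: global remapping across tracks, training
## schedules with interleaved quiescence probes, and cued replay after
## sparse-coding training.

#' Randomly remapped place-field assignments across tracks
#'
#' For each track, every neuron receives an independent uniform place-field
#' center; when `coding_level < 1` only a random subset of
#' `round(coding_level * N)` neurons is tuned on each track (sparse coding)
#' and untuned cells receive constant input during that track's exploration.
#' Orderings across tracks are uncorrelated (global remapping).
#'
#' @param N number of neurons.
#' @param n_tracks number of tracks.
#' @param coding_level fraction of tuned cells per track, in (0, 1].
#' @return object of class `track_ensemble`: `centers` (n_tracks-by-N),
#'   `tuned` (logical n_tracks-by-N), `n_tracks`, `coding_level`.
#' @export
remap_tracks <- function(N, n_tracks, coding_level = 1) {
  stopifnot(N >= 2, n_tracks >= 0, coding_level > 0, coding_level <= 1)
  n_tuned <- round(coding_level * N)
  if (n_tuned < 2) stop("coding_level * N must be at least 2")
  centers <- matrix(runif(n_tracks * N, -pi, pi), n_tracks, N)
  tuned <- matrix(FALSE, n_tracks, N)
  for (mu in seq_len(n_tracks)) {
    tuned[mu, sample.int(N, n_tuned)] <- TRUE
  }
  structure(list(centers = centers, tuned = tuned, n_tracks = n_tracks,
                 coding_level = coding_level, N = N),
            class = "track_ensemble")
}

#' Track ordering of the tuned cells
#'
#' Indices of the cells tuned on track `mu`, sorted by place-field center:
#' the ordering used by the SC statistic for that track.
#'
#' @param ensemble a [remap_tracks()] result.
#' @param mu track index.
#' @return integer vector of neuron indices.
#' @export
track_ordering <- function(ensemble, mu) {
  stopifnot(inherits(ensemble, "track_ensemble"),
            mu >= 1, mu <= ensemble$n_tracks)
  idx <- which(ensemble$tuned[mu, ])
  idx[order(ensemble$centers[mu, idx])]
}

#' Training schedule
#'
#' Movement blocks of `run_duration` seconds alternate with quiescence probes
#' of `quiescence_duration` seconds (place-field input removed, baseline set
#' to `quiescence_I0`) until `session_length` seconds per track. Defaults:
#' 180 s runs, 3 s probes, 3600 s sessions, probe baseline 3 Hz.
#'
#' @param run_duration movement block, seconds.
#' @param quiescence_duration probe length, seconds.
#' @param session_length per-track session, seconds.
#' @param quiescence_I0 baseline drive during probes, Hz.
#' @return object of class `training_schedule`.
#' @export
training_schedule <- function(run_duration = 180, quiescence_duration = 3,
                              session_length = 3600, quiescence_I0 = 3) {
  stopifnot(run_duration > 0, quiescence_duration > 0, session_length > 0)
  structure(list(run_duration = run_duration,
                 quiescence_duration = quiescence_duration,
                 session_length = session_length,
                 quiescence_I0 = quiescence_I0),
            class = "training_schedule")
}

#' Quiescence probe: spontaneous activity with place-field input removed
#'
#' Continues a simulation for `schedule$quiescence_duration` seconds with the
#' place-field input off and the baseline set to `schedule$quiescence_I0`.
#' Depression-mediated bursting makes the spontaneous activity
#' sharp-wave-like; its SC against a track ordering is evaluated on seconds
#' 2-3 of the probe (the first second is discarded while place-field activity
#' dies away).
#'
#' @param params,motion,dep,rule as in [simulate_ring()].
#' @param W weight matrix at probe onset.
#' @param state continuation state (or `NULL` for a cold start).
#' @param schedule a [training_schedule()].
#' @param sc_ordering optional neuron ordering; when given, the burst SC over
#'   seconds 2-3 (1-s intervals, 20 ms bins) is returned.
#' @param record_every recording cadence in steps.
#' @param ... passed to [simulate_ring()] (e.g. `engine`).
#' @return list with the probe `sim` (a `ring_sim`), and when `sc_ordering`
#'   is given, `sc` (mean over the 1-s intervals) and `sc_by_interval`.
#' @export
quiescence_probe <- function(params, motion, dep, rule, W, state, schedule,
                             sc_ordering = NULL, record_every = 20L, ...) {
  stopifnot(inherits(schedule, "training_schedule"))
  probe_input <- input_config(I0 = schedule$quiescence_I0,
                              place_field_on = FALSE)
  sim <- simulate_ring(params = params, input = probe_input, motion = motion,
                       dep = dep, rule = rule,
                       duration = schedule$quiescence_duration,
                       W = W, state = state, record_every = record_every,
                       ...)
  out <- list(sim = sim)
  if (!is.null(sc_ordering)) {
    t_rel <- sim$time - (sim$state$t - schedule$quiescence_duration)
    scs <- c()
    for (s0 in seq(1, schedule$quiescence_duration - 1)) {
      keep <- t_rel > s0 & t_rel <= s0 + 1
      if (sum(keep) < 4) next
      R <- t(sim$rates[keep, , drop = FALSE])
      sc <- tryCatch(
        suppressWarnings(sequential_correlation(R, sc_ordering)$sc),
        error = function(e) NA_real_)
      scs <- c(scs, sc)
    }
    out$sc_by_interval <- scs
    out$sc <- if (length(scs)) mean(scs, na.rm = TRUE) else NA_real_
  }
  out
}

#' Train the network across a sequence of remapped tracks
#'
#' Runs sequential sessions on the tracks of an ensemble. Within each session,
#' movement blocks alternate with quiescence probes per the schedule. Weights
#' are carried over between tracks; traces and depression variables are reset
#' at track boundaries (only the weight matrix carries memory across
#' environments). Fourier modes of the connectivity (in the current track's
#' ordering, tuned cells only) are recorded at each block boundary, and the
#' burst SC of each probe is recorded against the current track's ordering.
#'
#' @param params,input,motion,dep as in [simulate_ring()].
#' @param rule plasticity rule (possibly [scale_rule()]d for desk-scale runs).
#' @param ensemble a [remap_tracks()] ensemble.
#' @param schedule a [training_schedule()].
#' @param W initial weight matrix (default constant `w_init`).
#' @param untuned_I0 baseline for untuned cells during movement, Hz.
#' @param probe_sc compute burst SC at each probe.
#' @param record_every recording cadence during probes.
#' @param ... passed to [simulate_ring()].
#' @return object of class `training_run`: final `W`, `modes` data frame
#'   (time_s, track, w0, weven, wodd), `probes` data frame (time_s, track,
#'   sc_burst), and the configuration.
#' @export
run_training <- function(params, input, motion, dep, rule, ensemble,
                         schedule = training_schedule(),
                         W = NULL, untuned_I0 = 0, probe_sc = TRUE,
                         record_every = 20L, ...) {
  stopifnot(inherits(ensemble, "track_ensemble"),
            inherits(schedule, "training_schedule"),
            ensemble$N == params$N)
  if (is.null(W)) W <- matrix(params$w_init, params$N, params$N)
  modes <- list()
  probes <- list()
  t_abs <- 0
  if (ensemble$n_tracks == 0) {
    return(structure(list(W = W,
                          modes = data.frame(time_s = numeric(0),
                                             track = integer(0),
                                             w0 = numeric(0),
                                             weven = numeric(0),
                                             wodd = numeric(0)),
                          probes = data.frame(time_s = numeric(0),
                                              track = integer(0),
                                              sc_burst = numeric(0)),
                          ensemble = ensemble, schedule = schedule),
                     class = "training_run"))
  }
  for (mu in seq_len(ensemble$n_tracks)) {
    centers <- ensemble$centers[mu, ]
    tuned <- ensemble$tuned[mu, ]
    ord <- track_ordering(ensemble, mu)
    state <- NULL # traces/depression reset at track boundary
    t_session <- 0
    block <- schedule$run_duration + schedule$quiescence_duration
    record_mode <- function(t) {
      idx <- which(tuned)
      m <- fourier_modes(W[idx, idx, drop = FALSE], centers[idx],
                         ordering_track = mu)
      modes[[length(modes) + 1]] <<- data.frame(
        time_s = t, track = mu, w0 = m$w0, weven = m$weven, wodd = m$wodd)
    }
    record_mode(t_abs)
    while (t_session < schedule$session_length - 1e-9) {
      run_len <- min(schedule$run_duration,
                     schedule$session_length - t_session)
      sim <- simulate_ring(params = params, input = input, motion = motion,
                           dep = dep, rule = rule, duration = run_len,
                           centers = centers, tuned = tuned,
                           untuned_I0 = untuned_I0, W = W, state = state,
                           record_every = 0L, ...)
      W <- sim$W
      state <- sim$state
      t_session <- t_session + run_len
      t_abs <- t_abs + run_len
      record_mode(t_abs)
      if (t_session >= schedule$session_length - 1e-9) break
      pr <- quiescence_probe(params, motion, dep, rule, W, state, schedule,
                             sc_ordering = if (probe_sc) ord else NULL,
                             record_every = record_every, ...)
      W <- pr$sim$W
      state <- pr$sim$state
      t_session <- t_session + schedule$quiescence_duration
      t_abs <- t_abs + schedule$quiescence_duration
      if (probe_sc) {
        probes[[length(probes) + 1]] <- data.frame(
          time_s = t_abs, track = mu, sc_burst = pr$sc)
      }
    }
  }
  structure(list(W = W,
                 modes = do.call(rbind, modes),
                 probes = if (length(probes)) do.call(rbind, probes) else
                   data.frame(time_s = numeric(0), track = integer(0),
                              sc_burst = numeric(0)),
                 ensemble = ensemble, schedule = schedule),
            class = "training_run")
}

#' @export
print.training_run <- function(x, ...) {
  cat(sprintf("training_run: %d track(s), final mean weight %.4g\n",
              x$ensemble$n_tracks, mean(x$W)))
  if (nrow(x$modes)) {
    last <- x$modes[nrow(x$modes), ]
    cat(sprintf("  last modes (track %d ordering): w0 = %.4g, weven = %.4g, wodd = %.4g\n",
                last$track, last$w0, last$weven, last$wodd))
  }
  invisible(x)
}

#' Replay cue
#'
#' A constant drive applied during quiescence: `"global"` stimulates every
#' neuron; `"selective"` stimulates only the cells tuned on `target_track`.
#'
#' @param kind `"global"` or `"selective"`.
#' @param target_track track index (selective cues).
#' @param amplitude drive, Hz.
#' @return object of class `replay_cue`.
#' @export
replay_cue <- function(kind = c("global", "selective"), target_track = 1,
                       amplitude = 3) {
  kind <- match.arg(kind)
  structure(list(kind = kind, target_track = target_track,
                 amplitude = amplitude), class = "replay_cue")
}

#' Cued replay: drive a trained network and score each track's ordering
#'
#' Applies the cue as constant input (no place-field modulation, no
#' plasticity), simulates the evoked epoch and computes the SC of the
#' activity against every stored track's ordering (tuned cells of that track
#' only). Selective cues to the cells of one track retrieve that track's
#' sequence; global cues retrieve the most recently explored tracks. The
#' epoch includes the pattern-formation transient after cue onset (only the
#' first `discard` seconds of input-onset artifact are dropped): at reduced
#' connectivity amplitudes the evoked expression of the stored structure is
#' dominated by this transient, while far above the wave instability it is a
#' sustained traveling wave.
#'
#' @param W trained weight matrix.
#' @param ensemble the [remap_tracks()] ensemble used in training.
#' @param cue a [replay_cue()].
#' @param params,motion,dep as in [simulate_ring()].
#' @param duration evoked epoch length, seconds.
#' @param discard onset artifact excluded from the SC, seconds.
#' @param baseline_I0 drive to un-cued cells, Hz.
#' @param record_every recording cadence in steps.
#' @param ... passed to [simulate_ring()].
#' @return data frame of class `cued_replay`: `track`, `sc`; attribute `sim`
#'   holds the simulation.
#' @export
cued_replay <- function(W, ensemble, cue, params, motion = motion_model(),
                        dep = depression_params(), duration = 1.5,
                        discard = 0.05, baseline_I0 = 0, record_every = 20L,
                        ...) {
  stopifnot(inherits(ensemble, "track_ensemble"), inherits(cue, "replay_cue"))
  if (cue$kind == "selective" &&
      (cue$target_track < 1 || cue$target_track > ensemble$n_tracks)) {
    stop("unknown target_track")
  }
  driven <- if (cue$kind == "global") rep(TRUE, params$N) else
    ensemble$tuned[cue$target_track, ]
  ## constant cue drive: reuse the tuned/untuned input split with the place
  ## field off for untuned cells and IPF = 0 for driven cells
  cue_input <- input_config(I0 = cue$amplitude, IPF = 0, Itheta = 0,
                            place_field_on = TRUE)
  sim <- simulate_ring(params = params, input = cue_input, motion = motion,
                       dep = dep, rule = NULL, duration = duration,
                       tuned = driven, untuned_I0 = baseline_I0, W = W,
                       record_every = record_every, ...)
  keep <- sim$time - min(sim$time) >= discard
  out <- data.frame(track = seq_len(ensemble$n_tracks), sc = NA_real_)
  for (mu in seq_len(ensemble$n_tracks)) {
    ord_global <- track_ordering(ensemble, mu)
    R <- t(sim$rates[keep, ord_global, drop = FALSE])
    out$sc[mu] <- tryCatch(
      suppressWarnings(sequential_correlation(R)$sc),
      error = function(e) NA_real_)
  }
  attr(out, "sim") <- sim
  class(out) <- c("cued_replay", "data.frame")
  out
}
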