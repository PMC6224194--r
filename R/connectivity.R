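## Reduction of weight matrices to offset profiles and spatial Fourier modes.
## Offsets use the convention dtheta = theta_post - theta_pre, so a positive
## odd mode means stronger connections in the direction of (clockwise) motion.

#' Connectivity profile versus place-field offset
#'
#' Averages the weights `w_ij` over all ordered pairs whose wrapped
#' place-field offset `theta_i - theta_j` (post minus pre) falls in each of
#' `n_bins` uniform bins over `(-pi, pi]`. The diagonal (autapses) is
#' excluded; empty bins are filled by linear interpolation between the
#' neighboring occupied bins (periodically). The normalized profile subtracts
#' the overall mean and divides by `w_ref`.
#'
#' @param W weight matrix (post-by-pre), `N >= 3`.
#' @param centers per-neuron place-field centers, radians.
#' @param n_bins number of offset bins (>= 3); default one per neuron.
#' @param w_ref normalization constant (default 40, the initial weight).
#' @return data frame of class `connectivity_profile` with columns
#'   `offset_rad`, `mean_w`, `normalized_w`.
#' @export
profile_from_matrix <- function(W, centers, n_bins = nrow(W), w_ref = 40) {
  N <- nrow(W)
  check_that(
    "W must be a square matrix with N >= 3" = is.matrix(W) && N >= 3 && ncol(W) == N,
    "centers must match W and be finite" = length(centers) == N && all(is.finite(centers)),
    "n_bins must be >= 3" = is_num(n_bins) && n_bins >= 3
  )
  offs <- wrap_diff(outer(centers, centers, "-"))
  keep <- row(W) != col(W)
  d <- offs[keep]
  w <- W[keep]
  ## bins centered on a uniform grid over (-pi, pi]
  grid <- seq(-pi, pi, length.out = n_bins + 1)[-1] - pi / n_bins
  idx <- floor((d + pi) / (2 * pi) * n_bins) + 1
  idx[idx > n_bins] <- n_bins
  mean_w <- rep(NA_real_, n_bins)
  agg <- tapply(w, idx, mean)
  mean_w[as.integer(names(agg))] <- agg
  ## interpolate empty bins on the periodic grid
  if (anyNA(mean_w)) {
    filled <- which(!is.na(mean_w))
    if (length(filled) < 2) stop("too few occupied offset bins to interpolate")
    x <- c(grid[filled] - 2 * pi, grid[filled], grid[filled] + 2 * pi)
    y <- rep(mean_w[filled], 3)
    mean_w[is.na(mean_w)] <- approx(x, y, xout = grid[is.na(mean_w)])$y
  }
  out <- data.frame(offset_rad = grid, mean_w = mean_w,
                    normalized_w = (mean_w - mean(w)) / w_ref)
  class(out) <- c("connectivity_profile", "data.frame")
  out
}

#' First spatial Fourier modes of the connectivity
#'
#' Least-squares first-harmonic fit `w0 + weven cos(offset) + wodd sin(offset)`
#' of the weight-versus-offset relation. On a complete uniform offset grid
#' this equals the discrete projections `w0 = <w>`, `weven = 2 <w cos>`,
#' `wodd = 2 <w sin>`; the least-squares form additionally stays unbiased when
#' the diagonal (offset 0) is excluded or the offsets are irregular, where the
#' naive projections pick up an O(1/N) leakage of the mean into the even mode.
#' Either a [profile_from_matrix()] result or a raw `W` plus `centers` (fit
#' over all off-diagonal pairs directly, no binning) can be supplied.
#'
#' @param x a `connectivity_profile` or a weight matrix.
#' @param centers place-field centers (required when `x` is a matrix).
#' @param ordering_track optional label of the track ordering used.
#' @return list of class `fourier_modes` with `w0`, `weven`, `wodd`.
#' @export
fourier_modes <- function(x, centers = NULL, ordering_track = NA) {
  if (inherits(x, "connectivity_profile")) {
    off <- x$offset_rad
    w <- x$mean_w
  } else if (is.matrix(x)) {
    if (is.null(centers)) stop("centers required when x is a weight matrix")
    off <- wrap_diff(outer(centers, centers, "-"))
    keep <- row(x) != col(x)
    off <- off[keep]
    w <- x[keep]
  } else {
    stop("x must be a connectivity_profile or a weight matrix")
  }
  B <- cbind(1, cos(off), sin(off))
  cf <- solve(crossprod(B), crossprod(B, w))
  structure(list(w0 = cf[1], weven = cf[2], wodd = cf[3],
                 ordering_track = ordering_track),
            class = "fourier_modes")
}

#' @export
print.fourier_modes <- function(x, ...) {
  cat(sprintf("Fourier modes: w0 = %.4g, weven = %.4g, wodd = %.4g\n",
              x$w0, x$weven, x$wodd))
  invisible(x)
}

#' Detect the critical transition of the even connectivity mode
#'
#' Flags the first time at which `weven * gain * x0` exceeds the
#' traveling-wave stability threshold (2), i.e. `weven` crosses
#' [critical_even_mode()]. This is the mean-field predictor of the onset of
#' structured replay in quiescence probes.
#'
#' @param times numeric vector of snapshot times, seconds (ordered).
#' @param weven even-mode amplitudes at those times.
#' @param gain transfer gain at the quiescent operating point.
#' @param x0 depression fixed point (1 if disabled).
#' @return list with `transition` (logical), `time`, `weven_at_crossing` and
#'   `threshold`.
#' @export
critical_transition_check <- function(times, weven, gain, x0 = 1) {
  stopifnot(length(times) == length(weven), !is.unsorted(times))
  thr <- critical_even_mode(gain, x0)
  ix <- which(weven * gain * x0 > 2)
  if (!length(ix)) {
    return(list(transition = FALSE, time = NA_real_,
                weven_at_crossing = NA_real_, threshold = thr))
  }
  list(transition = TRUE, time = times[ix[1]],
       weven_at_crossing = weven[ix[1]], threshold = thr)
}
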