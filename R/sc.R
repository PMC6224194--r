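## Sequential correlation (SC): the mean zero-lag Pearson correlation of the
## binned rates of adjacently ordered cells. Under the place-field ordering of
## a track it is high for properly sequenced activity (exploration or replay)
## and near zero for orderings unrelated to the activity.

## internal: pairwise zero-lag correlation matrix of the rows of `rates`,
## with zero-variance rows flagged as NA
pair_correlation_matrix <- function(rates) {
  v <- apply(rates, 1, var)
  C <- suppressWarnings(cor(t(rates)))
  C[v == 0, ] <- NA_real_
  C[, v == 0] <- NA_real_
  C
}

#' Sequential correlation of a rate matrix under an ordering
#'
#' `SC = mean over i of cor(r_{o(i)}, r_{o(i+1)})`: the average zero-lag
#' Pearson correlation of the `N - 1` adjacent pairs of the ordering `o`
#' (an open chain, no wraparound). Cells with zero variance over the interval
#' are dropped from their pairs (with a warning); if no usable pair remains,
#' an error is raised.
#'
#' @param rates neurons-by-bins matrix of firing rates (Hz) or spike counts.
#' @param ordering permutation of the row indices (place-field order).
#' @return list with `sc`, `n_pairs_used`, and the per-pair correlations `cc`.
#' @export
sequential_correlation <- function(rates, ordering = seq_len(nrow(rates))) {
  stopifnot(is.matrix(rates), nrow(rates) >= 2)
  if (!setequal(ordering, seq_len(nrow(rates))) ||
      length(ordering) != nrow(rates)) {
    stop("ordering must be a permutation of the row indices")
  }
  R <- rates[ordering, , drop = FALSE]
  v <- apply(R, 1, var)
  n <- nrow(R)
  cc <- rep(NA_real_, n - 1)
  for (i in seq_len(n - 1)) {
    if (v[i] > 0 && v[i + 1] > 0) cc[i] <- cor(R[i, ], R[i + 1, ])
  }
  if (anyNA(cc)) {
    if (all(is.na(cc))) stop("all neighbor pairs unusable (zero variance)")
    warning(sum(is.na(cc)), " neighbor pair(s) dropped (zero-variance cell)")
  }
  list(sc = mean(cc, na.rm = TRUE), n_pairs_used = sum(!is.na(cc)), cc = cc)
}

#' Time-resolved sequential correlation
#'
#' Splits the recording into consecutive windows and computes the SC
#' independently in each (rebinned to `bin` seconds within the window).
#' Windows with fewer than 2 usable pairs yield `NA` rather than 0.
#'
#' @param rates neurons-by-bins matrix.
#' @param ordering permutation of row indices.
#' @param bin_width width of the columns of `rates`, seconds.
#' @param window window length, seconds (>= 2 bins).
#' @param bin analysis bin within each window, seconds (>= `bin_width`;
#'   must be a multiple).
#' @return data frame with `t_start`, `t_mid`, `sc`, `n_pairs`.
#' @export
time_resolved_sc <- function(rates, ordering, bin_width, window, bin = bin_width) {
  stopifnot(is.matrix(rates), window >= 2 * bin, bin >= bin_width)
  agg <- round(bin / bin_width)
  if (abs(agg * bin_width - bin) > 1e-9) {
    stop("bin must be a multiple of bin_width")
  }
  if (agg > 1) {
    nb <- floor(ncol(rates) / agg)
    rates <- sapply(seq_len(nb), function(k) {
      rowMeans(rates[, ((k - 1) * agg + 1):(k * agg), drop = FALSE])
    })
    bin_width <- bin
  }
  per_win <- round(window / bin_width)
  n_win <- floor(ncol(rates) / per_win)
  if (n_win < 1) stop("recording shorter than one window")
  out <- data.frame(t_start = (seq_len(n_win) - 1) * per_win * bin_width)
  out$t_mid <- out$t_start + per_win * bin_width / 2
  out$sc <- NA_real_
  out$n_pairs <- 0L
  for (k in seq_len(n_win)) {
    cols <- ((k - 1) * per_win + 1):(k * per_win)
    res <- tryCatch(
      suppressWarnings(sequential_correlation(rates[, cols, drop = FALSE],
                                              ordering)),
      error = function(e) NULL)
    if (!is.null(res) && res$n_pairs_used >= 2) {
      out$sc[k] <- res$sc
      out$n_pairs[k] <- res$n_pairs_used
    }
  }
  out
}

#' Shuffle null distribution of the SC
#'
#' Recomputes the SC under `n_shuffles` independent uniformly random orderings
#' of the cells. For spatially untuned or uniformly phased populations the
#' null mean is ~0. Also returns the empirical p-value of the observed SC
#' (when an observed ordering is supplied) and a one-sample t-test of the
#' observed SC against the null distribution.
#'
#' The pairwise correlation matrix is computed once, so shuffles cost
#' O(N) each.
#'
#' @param rates neurons-by-bins matrix.
#' @param n_shuffles number of random orderings (>= 100).
#' @param ordering optional observed ordering for the p-value.
#' @return object of class `sc_null`: list with `null` (vector of shuffled
#'   SCs), `null_mean`, `null_sd`, `se_mean`, and when `ordering` is given
#'   `observed`, `p_empirical`, `p_t`.
#' @export
shuffle_null <- function(rates, n_shuffles = 5000, ordering = NULL) {
  stopifnot(is.matrix(rates), n_shuffles >= 100)
  N <- nrow(rates)
  C <- pair_correlation_matrix(rates)
  sc_of <- function(p) {
    cc <- C[cbind(p[-N], p[-1])]
    if (all(is.na(cc))) return(NA_real_)
    mean(cc, na.rm = TRUE)
  }
  null <- vapply(seq_len(n_shuffles), function(i) sc_of(sample.int(N)),
                 numeric(1))
  out <- list(null = null,
              null_mean = mean(null, na.rm = TRUE),
              null_sd = sd(null, na.rm = TRUE),
              se_mean = sd(null, na.rm = TRUE) / sqrt(sum(!is.na(null))),
              n_shuffles = n_shuffles)
  if (!is.null(ordering)) {
    obs <- sc_of(ordering)
    out$observed <- obs
    out$p_empirical <- (1 + sum(null >= obs, na.rm = TRUE)) / (n_shuffles + 1)
    out$p_t <- tryCatch(t.test(null, mu = obs)$p.value,
                        error = function(e) NA_real_)
  }
  class(out) <- "sc_null"
  out
}

#' @export
print.sc_null <- function(x, ...) {
  cat(sprintf("SC shuffle null: mean = %.4f, sd = %.4f (%d shuffles)\n",
              x$null_mean, x$null_sd, x$n_shuffles))
  if (!is.null(x$observed)) {
    cat(sprintf("observed SC = %.4f (empirical p = %.4g)\n",
                x$observed, x$p_empirical))
  }
  invisible(x)
}

#' Transition time of an SC series
#'
#' Operational definition of the replay transition: the first probe whose SC
#' exceeds `frac` times the asymptotic SC (the mean over the final
#' `tail_frac` of the series) *and* stays above it for all later probes.
#' Series whose asymptote does not exceed `min_asymptote` are reported as
#' having no transition.
#'
#' @param times probe times, seconds.
#' @param sc SC values per probe.
#' @param frac threshold as a fraction of the asymptotic SC.
#' @param tail_frac fraction of the series used for the asymptote.
#' @param min_asymptote minimum asymptotic SC for a transition to count.
#' @return list with `transition`, `time`, `threshold`, `asymptote`.
#' @export
sc_transition_time <- function(times, sc, frac = 0.5, tail_frac = 0.2,
                               min_asymptote = 0.2) {
  stopifnot(length(times) == length(sc), !is.unsorted(times))
  ok <- !is.na(sc)
  times <- times[ok]; sc <- sc[ok]
  if (length(sc) < 3) return(list(transition = FALSE, time = NA_real_,
                                  threshold = NA_real_, asymptote = NA_real_))
  n_tail <- max(2, ceiling(tail_frac * length(sc)))
  asym <- mean(tail(sc, n_tail))
  thr <- frac * asym
  if (asym < min_asymptote) {
    return(list(transition = FALSE, time = NA_real_, threshold = thr,
                asymptote = asym))
  }
  above <- sc >= thr
  ## first index from which all later values stay above threshold
  ix <- which(rev(cumprod(rev(above))) == 1)
  if (!length(ix)) {
    return(list(transition = FALSE, time = NA_real_, threshold = thr,
                asymptote = asym))
  }
  list(transition = TRUE, time = times[ix[1]], threshold = thr,
       asymptote = asym)
}
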