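#' Wrap angles to the half-open interval [-pi, pi)
#'
#' Positions on the ring track live in `[-pi, pi)`; all motion updates wrap
#' through this helper.
#'
#' @param x numeric vector of angles, radians.
#' @return angles wrapped to `[-pi, pi)`.
#' @export
wrap_angle <- function(x) {
  ((x + pi) %% (2 * pi)) - pi
}

#' Wrapped angular difference in (-pi, pi]
#'
#' Difference `a - b` mapped to the interval `(-pi, pi]`, the convention used
#' for place-field offsets (post minus pre).
#'
#' @param a,b numeric vectors of angles, radians.
#' @return wrapped differences in `(-pi, pi]`.
#' @export
wrap_diff <- function(a, b = 0) {
  d <- ((a - b + pi) %% (2 * pi)) - pi
  d[d == -pi] <- pi
  d
}

## internal: stop unless all conditions hold, with the offending name
check_that <- function(...) {
  conds <- list(...)
  nms <- names(conds)
  for (i in seq_along(conds)) {
    if (!isTRUE(all(conds[[i]]))) {
      stop(nms[i], call. = FALSE)
    }
  }
  invisible(TRUE)
}

## internal: scalar finite numeric check
is_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
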