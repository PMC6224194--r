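## Mean-field theory for the slow growth of the Fourier modes of the recurrent
## connectivity. In the slow-plasticity limit the drift of the weight profile
## w(theta - theta') decomposes into a uniform mode w0, a first cosine (even)
## mode and a first sine (odd) mode; their growth rates follow from integrating
## the STDP kernel against the auto/cross-correlation of place-cell activity.

growth_rates <- function(dw0, dweven, dwodd) {
  structure(list(dw0 = dw0, dweven = dweven, dwodd = dwodd),
            class = "growth_rates")
}

#' @export
print.growth_rates <- function(x, ...) {
  cat("Connectivity mode growth rates (weight units / s):\n")
  cat(sprintf("  dw0    = %.6g\n  dweven = %.6g\n  dwodd  = %.6g\n",
              x$dw0, x$dweven, x$dwodd))
  invisible(x)
}

## internal: single-velocity pairwise contributions for one squared amplitude
pair_terms <- function(rule, amp2, v) {
  Ap <- rule$A_plus; Am <- rule$A_minus
  tp <- rule$tau_plus; tm <- rule$tau_minus
  dp <- 1 + tp^2 * v^2
  dm <- 1 + tm^2 * v^2
  list(
    even = amp2 / 2 * (Ap * tp / dp - Am * tm / dm),
    odd  = amp2 / 2 * (Ap * tp^2 * v / dp + Am * tm^2 * v / dm)
  )
}

#' Mode growth rates for a pairwise rule at constant velocity
#'
#' Closed forms for cosine-tuned activity `r(theta, t) = r0 + rPF cos(theta - v t)`
#' sweeping the ring at constant angular velocity `v`:
#' \deqn{\dot w_0 = (A_+\tau_+ - A_-\tau_-) r_0^2}
#' \deqn{\dot w_{even} = \frac{r_{PF}^2}{2}\left[\frac{A_+\tau_+}{1+\tau_+^2v^2}
#'   - \frac{A_-\tau_-}{1+\tau_-^2v^2}\right]}
#' \deqn{\dot w_{odd} = \frac{r_{PF}^2}{2}\left[\frac{A_+\tau_+^2 v}{1+\tau_+^2v^2}
#'   + \frac{A_-\tau_-^2 v}{1+\tau_-^2v^2}\right]}
#' For a balanced rule \eqn{\dot w_0 = 0} exactly, and for realistic running
#' speeds (\eqn{\tau^2 v^2 \ll 1}) the even-mode growth is nearly zero without
#' oscillatory modulation.
#'
#' @param rule a [pair_rule()].
#' @param r0 uniform rate, Hz.
#' @param rPF place-field rate amplitude, Hz.
#' @param v angular velocity, rad/s.
#' @return a `growth_rates` object (weight units per second).
#' @export
pair_growth_const_v <- function(rule, r0, rPF, v) {
  stopifnot(inherits(rule, "pair_rule"))
  pt <- pair_terms(rule, rPF^2, v)
  growth_rates(
    dw0 = (rule$A_plus * rule$tau_plus - rule$A_minus * rule$tau_minus) * r0^2,
    dweven = pt$even,
    dwodd = pt$odd
  )
}

#' Mode growth rates with multiplicative theta modulation
#'
#' With place-cell activity
#' `r = r0 + rPF cos(theta - v t) (1 + rtheta cos(2 pi f t))` the spatial term
#' splits into three traveling cosines at velocities `v`, `v + 2 pi f` and
#' `v - 2 pi f` with amplitudes `rPF`, `rPF*rtheta/2`, `rPF*rtheta/2`; each
#' contributes independently (squared amplitude) to the even/odd growth. For
#' `f` of a few Hz the sideband terms dominate the even-mode growth by orders
#' of magnitude, which is the theory's account of why theta-band modulation
#' accelerates learning.
#'
#' @inheritParams pair_growth_const_v
#' @param rtheta modulation depth of the rate (dimensionless).
#' @param f modulation frequency, Hz.
#' @return a `growth_rates` object.
#' @export
growth_with_theta <- function(rule, r0, rPF, rtheta, v, f) {
  stopifnot(inherits(rule, "pair_rule"), f >= 0)
  vs <- c(v, v + 2 * pi * f, v - 2 * pi * f)
  amps2 <- c(rPF^2, (rPF * rtheta / 2)^2, (rPF * rtheta / 2)^2)
  even <- 0
  odd <- 0
  for (k in 1:3) {
    pt <- pair_terms(rule, amps2[k], vs[k])
    even <- even + pt$even
    odd <- odd + pt$odd
  }
  growth_rates(
    dw0 = (rule$A_plus * rule$tau_plus - rule$A_minus * rule$tau_minus) *
      r0^2,
    dweven = even,
    dwodd = odd
  )
}

#' Leading-order even-mode growth under theta modulation
#'
#' The small-parameter (`eps = v/(2 pi f) << 1`) approximation in which the
#' even-mode growth is set entirely by the modulation frequency:
#' \deqn{\dot w_{even} \approx \frac{r_{PF}^2 r_{theta}^2}{4}
#'  \left[\frac{A_+\tau_+}{1+4\pi^2\tau_+^2 f^2} -
#'        \frac{A_-\tau_-}{1+4\pi^2\tau_-^2 f^2}\right]}
#' (derived from the exact three-velocity sum at `v = 0`; accurate to
#' `O(eps^2)`). Exposed for asymptotic checks; [growth_with_theta()] is the
#' exact expression.
#'
#' @inheritParams growth_with_theta
#' @return even-mode growth rate, weight units per second.
#' @export
growth_with_theta_leading_order <- function(rule, rPF, rtheta, f) {
  w <- 2 * pi * f
  amp2 <- (rPF * rtheta / 2)^2
  Ap <- rule$A_plus; Am <- rule$A_minus
  tp <- rule$tau_plus; tm <- rule$tau_minus
  2 * amp2 / 2 * (Ap * tp / (1 + tp^2 * w^2) - Am * tm / (1 + tm^2 * w^2))
}

#' Even-mode growth from kernel-times-autocorrelation quadrature
#'
#' Numerically integrates \eqn{\int K(T)\,AC(T)\,dT}, the general expression
#' for the growth of the even connectivity mode given the autocorrelation of
#' place-cell activity. Serves as the independent oracle for all closed forms.
#' Integration is truncated at `T_max = trunc_factor * max(tau+, tau-)`, where
#' the exponential tail of the kernel bounds the truncation error by
#' `(A+ tau+ + A- tau-) * max|AC| * exp(-trunc_factor)`.
#'
#' @param rule a [pair_rule()] supplying the kernel.
#' @param AC autocorrelation function of time lag `T` (seconds), vectorized or
#'   not; must be bounded.
#' @param trunc_factor truncation point in units of the slower kernel time
#'   constant (default 40, tail bound ~ 4e-18 of the kernel mass).
#' @param rel.tol quadrature relative tolerance.
#' @return growth rate (weight units per second).
#' @export
growth_from_AC <- function(rule, AC, trunc_factor = 40, rel.tol = 1e-12) {
  stopifnot(inherits(rule, "plasticity_rule"), is.function(AC))
  Tmax <- trunc_factor * max(rule$tau_plus, rule$tau_minus)
  ACv <- function(T) vapply(T, AC, numeric(1))
  f <- function(T) stdp_kernel(rule, T) * ACv(T)
  ## probe the AC for boundedness / non-convergence
  probe <- ACv(c(0, Tmax / 2, Tmax))
  if (any(!is.finite(probe))) {
    stop("autocorrelation is not finite on the integration window; integral does not converge")
  }
  ip <- integrate(f, 0, Tmax, rel.tol = rel.tol, abs.tol = 0,
                  subdivisions = 2000L)
  im <- integrate(f, -Tmax, 0, rel.tol = rel.tol, abs.tol = 0,
                  subdivisions = 2000L)
  ip$value + im$value
}

#' Mode growth rates for the triplet rule at constant velocity
#'
#' Closed forms extending [pair_growth_const_v()] with the triplet (A3) terms,
#' for activity `r = r0 + rPF cos(theta - v t)`:
#' the slow postsynaptic trace (tau_y) multiplies extra potentiation, the slow
#' presynaptic trace (tau_x3) extra depression. The fully balanced triplet rule
#' has `dw0 = 0` identically.
#'
#' @param rule a [triplet_rule()].
#' @inheritParams pair_growth_const_v
#' @return a `growth_rates` object.
#' @export
triplet_growth <- function(rule, r0, rPF, v) {
  stopifnot(inherits(rule, "triplet_rule"))
  Ap <- rule$A_plus; Am <- rule$A_minus
  tp <- rule$tau_plus; tm <- rule$tau_minus
  A3p <- rule$A3_plus; A3m <- rule$A3_minus
  ty <- rule$tau_y; tx <- rule$tau_x3
  dp <- 1 + tp^2 * v^2
  dm <- 1 + tm^2 * v^2
  dy <- 1 + ty^2 * v^2
  dx <- 1 + tx^2 * v^2
  a2 <- rPF^2 / 2

  dw0 <- (Ap * tp - Am * tm) * r0^2 +
    A3p * (tp * ty * r0^3 + tp * ty * r0 * a2 / dy) -
    A3m * (tm * tx * r0^3 + tm * tx * r0 * a2 / dx)

  dweven <- a2 * (Ap * tp / dp - Am * tm / dm) +
    A3p * tp * ty * r0 * a2 / dp * (1 + (1 + tp * ty * v^2) / dy) -
    A3m * tm * tx * r0 * a2 / dm * (1 + (1 + tm * tx * v^2) / dx)

  dwodd <- a2 * (Ap * tp^2 * v / dp + Am * tm^2 * v / dm) +
    A3p * tp * ty * v * r0 * a2 / dp * (tp + (tp - ty) / dy) +
    A3m * tm * tx * v * r0 * a2 / dm * (tm + (tm - tx) / dx)

  growth_rates(dw0, dweven, dwodd)
}

#' Velocity distribution for the averaged learning rule
#'
#' Either a point mass at `v_star` (`"delta"`, recovering the constant-velocity
#' results) or a symmetric uniform distribution on `|v| <= v_star`
#' (`"uniform_symmetric"`), the idealization of unbiased back-and-forth
#' exploration.
#'
#' @param kind `"delta"` or `"uniform_symmetric"`.
#' @param v_star velocity scale, rad/s.
#' @return an object of class `velocity_distribution`.
#' @export
velocity_distribution <- function(kind = c("delta", "uniform_symmetric"),
                                  v_star = 1) {
  kind <- match.arg(kind)
  stopifnot(is_num(v_star))
  structure(list(kind = kind, v_star = v_star),
            class = "velocity_distribution")
}

#' Mode growth rates averaged over a velocity distribution
#'
#' Averages the constant-velocity growth over a distribution of velocities.
#' For the symmetric uniform distribution the even mode becomes the
#' `sin(v* T)/(v* T)`-weighted kernel integral and the odd mode vanishes
#' exactly (clockwise and counter-clockwise contributions cancel), so unbiased
#' exploration builds symmetric connectivity.
#'
#' @param rule a [pair_rule()].
#' @param dist a [velocity_distribution()].
#' @param r0 uniform rate, Hz.
#' @param rPF place-field rate amplitude, Hz.
#' @return a `growth_rates` object.
#' @export
growth_with_velocity_dist <- function(rule, dist, r0, rPF) {
  stopifnot(inherits(rule, "pair_rule"),
            inherits(dist, "velocity_distribution"))
  if (dist$kind == "delta") {
    return(pair_growth_const_v(rule, r0, rPF, dist$v_star))
  }
  vst <- dist$v_star
  sinc <- function(x) ifelse(abs(x) < 1e-8, 1 - x^2 / 6, sin(x) / x)
  even <- growth_from_AC(rule, function(T) rPF^2 / 2 * sinc(vst * T))
  growth_rates(
    dw0 = (rule$A_plus * rule$tau_plus - rule$A_minus * rule$tau_minus) * r0^2,
    dweven = even,
    dwodd = 0
  )
}

#' Self-consistent rate coefficients of the driven linear ring
#'
#' Periodic steady state of the *linear* ring-rate equation under the
#' theta-modulated place-field input, with recurrent modes
#' `(w0, weven, wodd)`: the rate decomposes as
#' `r = r0~ + r_even cos(theta - v t) + r_odd sin(theta - v t) + (the same at
#' the sideband velocities v+- = v +- 2 pi f)`. Closed-form linear response:
#' \deqn{\tilde r_0 = I_0 / (1 - w_0)}
#' \deqn{r_{even} = I_{PF} (1 - w_{even}/2) / [(1-w_{even}/2)^2 +
#'   (w_{odd}/2 - \tau v)^2]}
#' and analogously (with amplitude `IPF*Itheta/2` and velocity `v+-`) for the
#' sidebands. Feeding these coefficients into the three-velocity growth
#' formulas closes the slow weight dynamics self-consistently.
#'
#' @param w0,weven,wodd connectivity Fourier modes (sub-critical:
#'   `w0 < 1`, `weven < 2`).
#' @param input an [input_config()].
#' @param tau rate time constant, seconds.
#' @param v angular velocity, rad/s.
#' @param f theta frequency, Hz (taken from `input` when `NULL`).
#' @param tol singularity tolerance on the denominators.
#' @return list of class `rate_coefficients` with `r0_tilde`, `r_even`,
#'   `r_odd`, `r_even_plus`, `r_odd_plus`, `r_even_minus`, `r_odd_minus`
#'   (all Hz) and the velocities used.
#' @export
selfconsistent_coefficients <- function(w0, weven, wodd, input, tau, v,
                                        f = NULL, tol = 1e-10) {
  stopifnot(inherits(input, "input_config"))
  if (is.null(f)) f <- input$f
  if (abs(1 - w0) < tol) stop("uniform mode at/above criticality (w0 -> 1)")
  a <- 1 - weven / 2
  one_mode <- function(amp, vel) {
    b <- wodd / 2 - tau * vel
    den <- a^2 + b^2
    if (den < tol) stop("spatial mode at/above criticality (denominator -> 0)")
    c(even = amp * a / den, odd = amp * b / den)
  }
  vp <- v + 2 * pi * f
  vm <- v - 2 * pi * f
  m0 <- one_mode(input$IPF, v)
  mp <- one_mode(input$IPF * input$Itheta / 2, vp)
  mm <- one_mode(input$IPF * input$Itheta / 2, vm)
  structure(list(
    r0_tilde = input$I0 / (1 - w0),
    r_even = m0[["even"]], r_odd = m0[["odd"]],
    r_even_plus = mp[["even"]], r_odd_plus = mp[["odd"]],
    r_even_minus = mm[["even"]], r_odd_minus = mm[["odd"]],
    v = v, v_plus = vp, v_minus = vm, tau = tau, f = f
  ), class = "rate_coefficients")
}

#' Self-consistent mode growth rates from rate coefficients
#'
#' Combines [selfconsistent_coefficients()] with the pairwise growth formulas:
#' each of the three traveling components contributes with squared amplitude
#' `(r_even^2 + r_odd^2)` at its own velocity.
#'
#' @param rule a [pair_rule()].
#' @param coef a `rate_coefficients` object.
#' @return a `growth_rates` object.
#' @export
selfconsistent_growth <- function(rule, coef) {
  stopifnot(inherits(rule, "pair_rule"), inherits(coef, "rate_coefficients"))
  contrib <- function(re, ro, vel) pair_terms(rule, re^2 + ro^2, vel)
  t0 <- contrib(coef$r_even, coef$r_odd, coef$v)
  tp <- contrib(coef$r_even_plus, coef$r_odd_plus, coef$v_plus)
  tm <- contrib(coef$r_even_minus, coef$r_odd_minus, coef$v_minus)
  growth_rates(
    dw0 = (rule$A_plus * rule$tau_plus - rule$A_minus * rule$tau_minus) *
      coef$r0_tilde^2,
    dweven = t0$even + tp$even + tm$even,
    dwodd = t0$odd + tp$odd + tm$odd
  )
}

#' Depression-corrected effective rate coefficients
#'
#' With short-term synaptic depression the recurrent drive is `w * (x r)`, so
#' the growth formulas use the *effective* coefficients of the product
#' `x(theta,t) r(theta,t)`. For weak place-field input the uniform equation
#' `r0 = w0 r0 / (1 + tau_x U0 r0) + I0` is solved by a bracketing root find;
#' the spatial coefficients follow from the linear response of `(r, x)` about
#' that fixed point (a 2x2 linear system per velocity). With `U0 = 0` this
#' reduces exactly to [selfconsistent_coefficients()].
#'
#' @inheritParams selfconsistent_coefficients
#' @param dep a [depression_params()].
#' @return list of class `rate_coefficients` holding the *effective*
#'   coefficients (`r0_tilde = x0 r0`, etc.), plus `r0`, `x0` and the raw
#'   spatial coefficients.
#' @export
depression_corrected_rates <- function(w0, weven, wodd, input, tau, dep, v,
                                       f = NULL, tol = 1e-10) {
  stopifnot(inherits(input, "input_config"), inherits(dep, "depression_params"))
  if (is.null(f)) f <- input$f
  g <- dep$tau_x * dep$U0
  ## uniform fixed point: r0 = w0 * r0 / (1 + g r0) + I0, r0 >= 0
  fun <- function(r) w0 * r / (1 + g * r) + input$I0 - r
  upper <- max(abs(input$I0), 1)
  while (fun(upper) > 0 && upper < 1e12) upper <- upper * 2
  if (fun(0) < 0 || fun(upper) > 0) stop("no nonnegative uniform fixed point")
  r0 <- uniroot(fun, c(0, upper), tol = 1e-14)$root
  beta <- 1 + g * r0
  x0 <- 1 / beta

  one_mode <- function(amp, vel) {
    ## unknowns (r_even, r_odd); x linear response:
    ##  x_even = -U0 (v tau_x r_odd + beta r_even) / (beta D)
    ##  x_odd  = -U0 (-v tau_x r_even + beta r_odd) / (beta D)
    ## with D = v^2 tau_x^2 + beta^2; effective r~ = x0 r + r0 x.
    D <- vel^2 * dep$tau_x^2 + beta^2
    ce <- -dep$U0 / (beta * D)
    ## r~even = x0 re + r0 * ce * (vel tau_x ro + beta re)
    ##        = (x0 + r0 ce beta) re + (r0 ce vel tau_x) ro
    Ae <- x0 + r0 * ce * beta
    Be <- r0 * ce * vel * dep$tau_x
    ## r~odd = x0 ro + r0 * ce * (-vel tau_x re + beta ro)
    Ao <- x0 + r0 * ce * beta
    Bo <- -r0 * ce * vel * dep$tau_x
    ## steady-state balance of the cos/sin components:
    ##  -tau vel r_odd = -r_even + (weven r~even - wodd r~odd)/2 + amp
    ##   tau vel r_even = -r_odd + (weven r~odd + wodd r~even)/2
    ## as M %*% c(re, ro) = c(-amp, 0)
    M <- matrix(0, 2, 2)
    M[1, 1] <- -1 + (weven * Ae - wodd * Bo) / 2
    M[1, 2] <- tau * vel + (weven * Be - wodd * Ao) / 2
    M[2, 1] <- -tau * vel + (weven * Bo + wodd * Ae) / 2
    M[2, 2] <- -1 + (weven * Ao + wodd * Be) / 2
    if (abs(det(M)) < tol) stop("spatial mode at/above criticality")
    sol <- solve(M, c(-amp, 0))
    re <- sol[1]; ro <- sol[2]
    c(even = Ae * re + Be * ro, odd = Bo * re + Ao * ro,
      r_even = re, r_odd = ro)
  }
  vp <- v + 2 * pi * f
  vm <- v - 2 * pi * f
  m0 <- one_mode(input$IPF, v)
  mp <- one_mode(input$IPF * input$Itheta / 2, vp)
  mm <- one_mode(input$IPF * input$Itheta / 2, vm)
  structure(list(
    r0_tilde = x0 * r0,
    r_even = m0[["even"]], r_odd = m0[["odd"]],
    r_even_plus = mp[["even"]], r_odd_plus = mp[["odd"]],
    r_even_minus = mm[["even"]], r_odd_minus = mm[["odd"]],
    v = v, v_plus = vp, v_minus = vm, tau = tau, f = f,
    r0 = r0, x0 = x0,
    raw = list(v = m0, v_plus = mp, v_minus = mm)
  ), class = "rate_coefficients")
}

#' Modulation frequency maximizing even-mode growth
#'
#' In the leading-order theory the even-mode growth under theta modulation is
#' maximal at \eqn{f^* = 1 / (2\pi\sqrt{\tau_+\tau_-})}; for the default
#' windows (20 ms, 60 ms) this is about 4.59 Hz, inside the theta band.
#'
#' @param rule a [pair_rule()].
#' @return optimal frequency, Hz.
#' @export
optimal_theta_frequency <- function(rule) {
  stopifnot(inherits(rule, "plasticity_rule"))
  1 / (2 * pi * sqrt(rule$tau_plus * rule$tau_minus))
}

#' Small parameters of the slow-plasticity expansion
#'
#' Diagnostics for the regime of validity of the leading-order formulas:
#' `eps = v / (2 pi f)` (motion slow compared to modulation) and
#' `tau^2 v^2` (synaptic window short compared to track traversal).
#'
#' @param v angular velocity, rad/s.
#' @param f modulation frequency, Hz.
#' @param tau a time constant, seconds (e.g. an STDP window).
#' @return named list with `eps` and `tau2v2`.
#' @export
stdp_small_parameters <- function(v, f, tau) {
  stopifnot(is_num(v), is_num(f) && f > 0, is_num(tau))
  list(eps = v / (2 * pi * f), tau2v2 = tau^2 * v^2)
}

#' Frequency sweep of the theta-modulated growth rates
#'
#' Evaluates [growth_with_theta()] over a grid of modulation frequencies and
#' reports the even/odd growth rates and the argmax frequency of the even
#' mode.
#'
#' @param rule a [pair_rule()].
#' @param f frequencies, Hz; default 200 log-spaced points in `[0.1, 100]`.
#' @param r0 uniform rate, Hz.
#' @param rPF place-field rate amplitude, Hz.
#' @param rtheta modulation depth of the rate.
#' @param v angular velocity, rad/s.
#' @return data frame of class `growth_sweep` with columns `f_Hz`, `dw_even`,
#'   `dw_odd`, `dw0`; attribute `f_opt` holds the argmax of `dw_even`.
#' @export
growth_frequency_sweep <- function(rule, f = 10^seq(-1, 2, length.out = 200),
                                   r0 = 1, rPF = 1, rtheta = 1, v = 1) {
  stopifnot(inherits(rule, "pair_rule"))
  rows <- lapply(f, function(fi) {
    g <- growth_with_theta(rule, r0, rPF, rtheta, v, fi)
    c(fi, g$dweven, g$dwodd, g$dw0)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("f_Hz", "dw_even", "dw_odd", "dw0")
  class(out) <- c("growth_sweep", "data.frame")
  attr(out, "f_opt") <- out$f_Hz[which.max(out$dw_even)]
  out
}

#' @export
plot.growth_sweep <- function(x, ...) {
  graphics::plot(x$f_Hz, x$dw_even, log = "x", type = "l",
                 xlab = "modulation frequency (Hz)",
                 ylab = "even-mode growth rate", ...)
  graphics::lines(x$f_Hz, x$dw_odd, lty = 2)
  graphics::abline(v = attr(x, "f_opt"), col = "grey60", lty = 3)
  graphics::legend("topright", legend = c("even", "odd"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}
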