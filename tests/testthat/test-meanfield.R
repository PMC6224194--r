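test_that("balanced rules give exactly zero uniform growth; v=0 kills both modes", {
  g <- pair_growth_const_v(pair_rule(), r0 = 3, rPF = 10, v = 1)
  expect_identical(g$dw0, 0)
  g0 <- pair_growth_const_v(pair_rule(), r0 = 3, rPF = 10, v = 0)
  expect_equal(g0$dweven, 0, tolerance = 1e-18)
  expect_equal(g0$dwodd, 0)
  ## unbalanced rule drifts
  gu <- pair_growth_const_v(pair_rule(A_minus = 0.1, tau_minus = 0.060),
                            r0 = 2, rPF = 1, v = 1)
  expect_equal(gu$dw0, (0.1 * 0.020 - 0.1 * 0.060) * 4)
  ## triplet: fully balanced rule has zero uniform growth at any v
  for (v in c(0, 0.5, 2)) {
    gt <- triplet_growth(triplet_rule(), r0 = 4, rPF = 6, v = v)
    expect_equal(gt$dw0, 0, tolerance = 1e-15)
  }
})

test_that("closed-form growth equals kernel-times-AC quadrature across the parameter grid", {
  rules <- list(pair = plasticity_preset("pair"),
                antisym = plasticity_preset("antisymmetric"),
                depdom = plasticity_preset("depression_dominant"),
                unbalanced = pair_rule(A_plus = 0.08, tau_plus = 0.015,
                                       A_minus = 0.05, tau_minus = 0.045))
  rPF <- 1.7
  for (rule in rules) {
    for (v in c(0.1, 1, 5)) {
      g <- pair_growth_const_v(rule, r0 = 1, rPF = rPF, v = v)
      q <- quad_growth(rule, rPF, v)
      scale <- kernel_mass(rule, rPF)
      expect_lt(abs(g$dweven - q$even) / scale, 1e-8)
      expect_lt(abs(g$dwodd - q$odd) / scale, 1e-8)
      for (f in c(0, 1, 4.59, 8, 20, 100)) {
        gth <- growth_with_theta(rule, r0 = 1, rPF = rPF, rtheta = 0.9,
                                 v = v, f = f)
        amps <- c(rPF, rPF * 0.9 / 2, rPF * 0.9 / 2)
        vels <- c(v, v + 2 * pi * f, v - 2 * pi * f)
        qth <- quad_growth(rule, amps, vels)
        scale <- kernel_mass(rule, amps)
        expect_lt(abs(gth$dweven - qth$even) / scale, 1e-8)
        expect_lt(abs(gth$dwodd - qth$odd) / scale, 1e-8)
      }
    }
  }
})

test_that("theta growth reduces to constant-velocity growth when rtheta = 0", {
  g1 <- growth_with_theta(pair_rule(), 1, 2, rtheta = 0, v = 0.7, f = 8)
  g2 <- pair_growth_const_v(pair_rule(), 1, 2, v = 0.7)
  expect_equal(g1$dweven, g2$dweven)
  expect_equal(g1$dwodd, g2$dwodd)
})

test_that("leading-order theta formula agrees with the exact sum to O(eps^2)", {
  rule <- pair_rule()
  v <- 1; f <- 8
  eps <- stdp_small_parameters(v, f, rule$tau_plus)$eps
  exact <- growth_with_theta(rule, 0, 1, 1, v, f)$dweven
  lead <- growth_with_theta_leading_order(rule, 1, 1, f)
  ## the balanced v-term is second order in tau*v; the sideband asymmetry is O(eps)
  expect_equal(lead / exact, 1, tolerance = 10 * eps)
  ## and the small parameters themselves
  expect_equal(eps, 1 / (16 * pi))
  expect_equal(stdp_small_parameters(1, 8, 0.050)$tau2v2, 0.0025)
})

test_that("even-mode growth peaks at 1/(2 pi sqrt(tau+ tau-)) inside the theta band", {
  rule <- pair_rule()
  fopt <- optimal_theta_frequency(rule)
  expect_equal(fopt, 1 / (2 * pi * sqrt(0.020 * 0.060)))
  sweep <- growth_frequency_sweep(rule, v = 1)
  f_arg <- attr(sweep, "f_opt")
  expect_gt(f_arg, 1)
  expect_lt(f_arg, 10)
  expect_equal(f_arg, fopt, tolerance = 0.05)
  ## frequency limits: growth -> 0 at high f and -> (balanced ~ 0) value at low f
  hi <- growth_with_theta(rule, 0, 1, 1, v = 0, f = 1000)$dweven
  lo <- growth_with_theta(rule, 0, 1, 1, v = 0, f = 1e-4)$dweven
  peak <- growth_with_theta(rule, 0, 1, 1, v = 0, f = fopt)$dweven
  expect_lt(abs(hi), 1e-3 * peak)
  expect_lt(abs(lo), 1e-3 * peak)
})

test_that("growth sign symmetries: odd in v; depression-dominant mirrors potentiation-dominant", {
  rule <- pair_rule()
  gp <- pair_growth_const_v(rule, 1, 1, v = 2)
  gm <- pair_growth_const_v(rule, 1, 1, v = -2)
  expect_equal(gp$dwodd, -gm$dwodd)
  expect_equal(gp$dweven, gm$dweven)
  ## anti-symmetric rule: zero even growth at any frequency
  ga <- growth_with_theta(plasticity_preset("antisymmetric"), 1, 1, 1, 1, 8)
  expect_equal(ga$dweven, 0, tolerance = 1e-15)
  ## time-mirrored kernel K_m(T) = -K(-T): even-mode growth flips sign exactly
  mirror <- pair_rule(A_plus = rule$A_minus, tau_plus = rule$tau_minus,
                      A_minus = rule$A_plus, tau_minus = rule$tau_plus)
  gm8 <- growth_with_theta(mirror, 1, 1, 1, 1, 8)
  gp8 <- growth_with_theta(rule, 1, 1, 1, 1, 8)
  expect_equal(gm8$dweven, -gp8$dweven, tolerance = 1e-15)
  ## the depression-dominant preset drives the even mode negative
  gd <- growth_with_theta(plasticity_preset("depression_dominant"), 1, 1, 1, 1, 8)
  expect_lt(gd$dweven, 0)
})

test_that("constant AC under a balanced kernel integrates to zero; antisymmetric kernel kills even AC", {
  expect_lt(abs(growth_from_AC(pair_rule(), function(T) 5)), 1e-12)
  expect_lt(abs(growth_from_AC(plasticity_preset("antisymmetric"),
                               function(T) cos(3 * T))), 1e-12)
  expect_error(growth_from_AC(pair_rule(), function(T) T / 0 * NA), "converge")
})

test_that("triplet closed forms match the factorized quadrature oracle", {
  rule <- triplet_rule(A3_plus = 0.05, tau_y = 0.1, tau_x3 = 0.15,
                       A3_minus = 0.02)
  for (v in c(0.3, 1, 5)) {
    cf <- triplet_growth(rule, r0 = 2, rPF = 1.5, v = v)
    or <- triplet_quad_oracle(rule, r0 = 2, a = 1.5, v = v)
    expect_equal(cf$dw0, or$dw0, tolerance = 1e-8)
    expect_equal(cf$dweven, or$dweven, tolerance = 1e-8)
    expect_equal(cf$dwodd, or$dwodd, tolerance = 1e-8)
  }
  ## A3 = 0 reduces to the pairwise closed form
  z <- triplet_rule(A3_plus = 0, A3_minus = 0)
  expect_equal(triplet_growth(z, 2, 1.5, 1)$dweven,
               pair_growth_const_v(pair_rule(), 2, 1.5, 1)$dweven)
})

test_that("closed-form growth matches brute-force Poisson trace simulations", {
  ## slow-plasticity Monte Carlo oracle: cosine-tuned rates
  ## r(theta, t) = r0 + a cos(theta - v t) realized by the network engine
  ## (linear transfer, tau = 1 ms so rates track the input; recurrent
  ## feedback nulled by wI = w_init), Poisson spikes, online trace updates.
  ## Balanced rules leave only near-cancelling residuals that Monte Carlo
  ## noise cannot resolve, so the pairwise part and the pure-triplet term
  ## are probed separately at amplitudes where each dominates.
  r0 <- 20; a <- 10; v <- 2
  N <- 24
  th <- uniform_centers(N)
  params <- network_params(N = N, tau = 1e-3, wI = 40, w_init = 40,
                           wmax = 1000, dt = 1e-4)
  inp <- input_config(I0 = r0, IPF = a, Itheta = 0, f = 0)
  mot <- motion_model(kind = "constant", v_const = v)
  run <- function(rule, dur, seed) {
    sim <- simulate_ring(params, inp, mot, depression_params(U0 = 0), rule,
                         duration = dur, centers = th, record_every = 0L,
                         linear_phi = TRUE, seed = seed)
    m <- fourier_modes(sim$W - 40, th)
    list(dw0 = m$w0 / dur, dweven = m$weven / dur, dwodd = m$wodd / dur)
  }
  ## balanced pairwise rule: the odd mode is the resolvable signal
  pw <- pair_rule(A_plus = 0.002, A_minus = 0.002 / 3)
  meas <- run(pw, dur = 300, seed = 5)
  pred <- pair_growth_const_v(pw, r0, a, v)
  expect_equal(meas$dwodd / pred$dwodd, 1, tolerance = 0.15)
  expect_lt(abs(meas$dweven - pred$dweven), 2e-5)
  expect_lt(abs(meas$dw0), 5e-5)
  ## pure triplet potentiation term (A2 = 0, A3- = 0): all three modes
  ## resolvable; the ~10% allowance covers the slow drift of the uniform
  ## mode feeding back into the rates over the window
  tri <- triplet_rule(A2_plus = 0, A2_minus = 0, A3_plus = 1e-4,
                      A3_minus = 0, tau_y = 0.1, tau_x3 = 0.1)
  meas <- run(tri, dur = 40, seed = 5)
  pred <- triplet_growth(tri, r0, a, v)
  expect_equal(meas$dw0 / pred$dw0, 1, tolerance = 0.15)
  expect_equal(meas$dweven / pred$dweven, 1, tolerance = 0.15)
  expect_equal(meas$dwodd / pred$dwodd, 1, tolerance = 0.15)
})

test_that("velocity-averaged growth: delta recovers constant v; uniform kills the odd mode", {
  rule <- pair_rule()
  gd <- growth_with_velocity_dist(rule, velocity_distribution("delta", 1.3),
                                  r0 = 1, rPF = 2)
  gc <- pair_growth_const_v(rule, 1, 2, 1.3)
  expect_equal(gd$dweven, gc$dweven)
  expect_equal(gd$dwodd, gc$dwodd)
  gu <- growth_with_velocity_dist(rule,
                                  velocity_distribution("uniform_symmetric", 1),
                                  r0 = 1, rPF = 2)
  expect_identical(gu$dwodd, 0)
  ## nested quadrature oracle over (v, T)
  vstar <- 1
  inner <- function(T) {
    integrate(function(v) cos(v * T) / (2 * vstar), -vstar, vstar,
              rel.tol = 1e-10)$value
  }
  f <- function(T) {
    vapply(T, function(Ti) stdp_kernel(rule, Ti) * 2 * inner(Ti), numeric(1))
  }
  Tmax <- 40 * 0.060
  oracle <- integrate(f, 0, Tmax, rel.tol = 1e-9, subdivisions = 2000L)$value +
    integrate(f, -Tmax, 0, rel.tol = 1e-9, subdivisions = 2000L)$value
  expect_equal(gu$dweven, oracle, tolerance = 1e-7)
})

test_that("self-consistent coefficients obey the stated limits and singularities", {
  inp <- input_config(I0 = 3, IPF = 25, Itheta = 1, f = 8)
  ## no recurrence, no lag: r_even = IPF, r_odd = 0, r0 = I0
  co <- selfconsistent_coefficients(0, 0, 0, inp, tau = 1e-9, v = 1)
  expect_equal(co$r0_tilde, 3)
  expect_equal(co$r_even, 25, tolerance = 1e-6)
  expect_equal(co$r_odd, 0, tolerance = 1e-6)
  ## criticality raises an error
  expect_error(selfconsistent_coefficients(0, 2, 2e-2, inp, tau = 0.01, v = 2e-2 / 2 / 0.01),
               "criticality")
  expect_error(selfconsistent_coefficients(1, 0, 0, inp, tau = 0.01, v = 1),
               "criticality")
  ## coefficients diverge approaching weven -> 2
  near <- selfconsistent_coefficients(0, 1.999, 0, inp, tau = 0.01, v = 0.01)
  far <- selfconsistent_coefficients(0, 1, 0, inp, tau = 0.01, v = 1)
  expect_gt(abs(near$r_even) + abs(near$r_odd), 100 * abs(far$r_even))
})

test_that("depression-corrected rates reduce correctly and match a bisection oracle", {
  inp <- input_config(I0 = 3, IPF = 1, Itheta = 1, f = 8)
  dep0 <- depression_params(U0 = 0)
  a <- depression_corrected_rates(0.5, 0.4, 0.1, inp, 0.01, dep0, v = 1)
  b <- selfconsistent_coefficients(0.5, 0.4, 0.1, inp, 0.01, v = 1)
  expect_equal(a$x0, 1)
  expect_equal(a$r_even, b$r_even, tolerance = 1e-10)
  expect_equal(a$r_odd, b$r_odd, tolerance = 1e-10)
  expect_equal(a$r0_tilde, b$r0_tilde, tolerance = 1e-10)
  ## w0 = 0 decouples the uniform equation: r0 = I0 exactly
  dep <- depression_params() # tau_x U0 = 0.00064
  d <- depression_corrected_rates(0, 0.2, 0, inp, 0.01, dep, v = 1)
  expect_equal(d$r0, 3, tolerance = 1e-12)
  expect_equal(d$x0, 1 / (1 + 0.8 * 8e-4 * 3), tolerance = 1e-12)
  ## uniform fixed point against an independent bisection oracle
  w0 <- 0.7; I0 <- 2
  inp2 <- input_config(I0 = I0, IPF = 1)
  d2 <- depression_corrected_rates(w0, 0, 0, inp2, 0.01, dep, v = 1)
  f <- function(r) w0 * r / (1 + 0.00064 * r) + I0 - r
  lo <- 0; hi <- 100
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(d2$r0, (lo + hi) / 2, tolerance = 1e-10)
  ## depression weakens the effective even coefficient
  expect_lt(abs(d2$r_even) - 0, abs(selfconsistent_coefficients(
    w0, 0, 0, inp2, 0.01, v = 1)$r_even))
})
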