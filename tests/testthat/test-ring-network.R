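test_that("softplus transfer matches closed form and asymptotes, gain is its derivative", {
  expect_equal(transfer_phi(0, 1), log(2), tolerance = 1e-12)
  expect_equal(transfer_phi(50, 1), 50, tolerance = 1e-10)
  expect_gt(transfer_phi(-50, 1), 0)
  expect_lt(transfer_phi(-50, 1), 1e-20)
  ## monotone, strictly positive, stable at extremes
  x <- seq(-1000, 1000, length.out = 401)
  y <- transfer_phi(x, 2)
  expect_true(all(is.finite(y)) && all(y > 0) && all(diff(y) > 0))
  ## derivative by central differences
  h <- 1e-6
  expect_equal(transfer_phi_prime(0.7, 1.3),
               (transfer_phi(0.7 + h, 1.3) - transfer_phi(0.7 - h, 1.3)) / (2 * h),
               tolerance = 1e-8)
  expect_error(transfer_phi(NaN), "non-finite")
  expect_error(transfer_phi(1, alpha = -1), "alpha")
})

test_that("constant motion advances linearly and wraps to [-pi, pi)", {
  m <- motion_model(kind = "constant", v_const = 1)
  st <- step_motion(0, 0, m, 1e-3)
  expect_equal(st$position, 1e-3)
  st <- step_motion(pi - 1e-4, 0, m, 1e-3)
  expect_lt(st$position, 0) # wrapped
  expect_gte(st$position, -pi)
})

test_that("noiseless OU velocity decays exponentially with time constant tau_v", {
  m <- motion_model(kind = "ou", v0 = 0, sigma_v = 0, tau_v = 2)
  v1 <- 1
  dt <- 1e-3
  for (i in 1:1000) v1 <- step_motion(0, v1, m, dt)$v1
  expect_equal(v1, (1 - dt / 2)^1000, tolerance = 1e-12)
  expect_equal(v1, exp(-0.5), tolerance = 1e-3)
})

test_that("OU velocity reaches the stationary spread of its discretization", {
  ## long-run empirical SD as oracle for the noise-scaling convention:
  ## v1 is AR(1) with a = 1 - dt/tau_v, b = sigma_v*sqrt(dt)/tau_v
  m <- motion_model(kind = "ou", v0 = 0, sigma_v = 2, tau_v = 10)
  dt <- 0.01
  set.seed(123)
  n <- 1e6 # 10^4 s
  a <- 1 - dt / m$tau_v
  b <- m$sigma_v * sqrt(dt) / m$tau_v
  v1 <- as.vector(stats::filter(b * rnorm(n), a, "recursive"))
  sd_expected <- b / sqrt(1 - a^2)
  expect_equal(sd(v1[-(1:1e4)]), sd_expected, tolerance = 0.02)
  ## and the step_motion update is that AR(1): one step reproducibly
  set.seed(1)
  st <- step_motion(0, 0.5, m, dt)
  set.seed(1)
  expect_equal(st$v1, 0.5 * a + b * rnorm(1))
})

test_that("one Euler step of a 2-neuron network matches hand-computed update", {
  params <- network_params(N = 2, tau = 0.01, alpha = 1, wI = 1, wmax = 80,
                           dt = 0.001)
  dep <- depression_params(tau_x = 0.8, U0 = 0.5)
  r <- c(2, 3)
  x <- c(0.9, 0.8)
  W <- matrix(c(4, 5, 6, 7), 2, 2)
  I <- c(1, -1)
  out <- step_network(r, x, W, I, params, dep)
  xr <- x * r
  ## W is column-major: row 1 = (4, 6), row 2 = (5, 7); wI = 1 subtracted
  drive1 <- ((4 - 1) * xr[1] + (6 - 1) * xr[2]) / 2 + 1
  drive2 <- ((5 - 1) * xr[1] + (7 - 1) * xr[2]) / 2 - 1
  expect_equal(out$drive, c(drive1, drive2))
  expect_equal(out$r[1], 2 + 0.1 * (-2 + log1p(exp(drive1))))
  expect_equal(out$r[2], 3 + 0.1 * (-3 + log1p(exp(drive2))))
  expect_equal(out$x[1], 0.9 + 0.001 * ((1 - 0.9) / 0.8 - 0.5 * 0.9 * 2))
  expect_error(step_network(c(NaN, 1), x, W, I, params, dep), "non-finite")
})

test_that("decoupled network relaxes to phi(I0) with time constant tau; U0=0 freezes x", {
  params <- network_params(N = 4, wI = 0, dt = 1e-4)
  inp <- input_config(I0 = 2, place_field_on = FALSE)
  dep <- depression_params(U0 = 0)
  sim <- simulate_ring(params, inp, motion_model(kind = "constant", v_const = 0),
                       dep, rule = NULL, duration = 0.2,
                       W = matrix(0, 4, 4), record_every = 100L, seed = 1)
  expect_equal(unname(sim$rates[nrow(sim$rates), ]),
               rep(transfer_phi(2), 4), tolerance = 1e-4)
  expect_true(all(sim$depression == 1))
  ## relaxation: after one tau the gap closes by ~1/e
  r0 <- transfer_phi(3) # initial condition is phi(I0) of the config... use r
  sim2 <- simulate_ring(params, inp, motion_model(kind = "constant", v_const = 0),
                        dep, rule = NULL, duration = 0.01,
                        W = matrix(0, 4, 4), record_every = 100L, seed = 1,
                        state = list(r = rep(5, 4), x = rep(1, 4),
                                     traces = new_trace_state(4, TRUE),
                                     position = 0, v1 = 0, t = 0))
  gap0 <- 5 - transfer_phi(2)
  gap1 <- sim2$rates[nrow(sim2$rates), 1] - transfer_phi(2)
  expect_equal(gap1 / gap0, exp(-1), tolerance = 0.01)
})

test_that("rates stay positive and depression stays in (0, 1] along a stochastic run", {
  sim <- simulate_ring(duration = 2, seed = 4, record_every = 5L)
  expect_true(all(sim$rates > 0))
  expect_true(all(sim$depression > 0 & sim$depression <= 1))
  expect_true(all(sim$position >= -pi & sim$position < pi))
  expect_true(all(sim$W >= 0 & sim$W <= sim$params$wmax))
})

test_that("spike generation is Bernoulli with probability r*dt", {
  set.seed(11)
  expect_equal(generate_spikes(rep(0, 5), 1e-3), rep(0L, 5))
  n <- 1e5
  s <- replicate(n, sum(generate_spikes(rep(20, 10), 1e-3)))
  p <- 20 * 1e-3
  expect_equal(mean(s) / 10, p, tolerance = 0.03)
  expect_equal(var(s), 10 * p * (1 - p), tolerance = 0.05)
  expect_warning(generate_spikes(2000, 1e-3), "clipped")
})

test_that("recorded lfp equals direct recomputation from saved state", {
  params <- network_params(N = 10, dt = 1e-3)
  inp <- input_config(I0 = 2, place_field_on = FALSE)
  dep <- depression_params()
  set.seed(3)
  W <- matrix(runif(100, 20, 60), 10, 10)
  sim <- simulate_ring(params, inp, motion_model(kind = "constant", v_const = 0),
                       dep, rule = NULL, duration = 0.1, W = W,
                       record_every = 1L, seed = 7)
  ## recompute the drive from the state one step earlier
  lfp2 <- network_lfp(rbind(rep(transfer_phi(2), 10), sim$rates[-nrow(sim$rates), ]),
                      rbind(rep(1, 10), sim$depression[-nrow(sim$depression), ]),
                      W, rep(2, 10), params)
  expect_equal(sim$lfp, lfp2, tolerance = 1e-10)
})

test_that("compiled and reference engines agree step for step", {
  for (eng_rule in list(plasticity_preset("pair"), plasticity_preset("triplet"), NULL)) {
    a <- simulate_ring(params = network_params(N = 30), duration = 0.3,
                       rule = eng_rule, record_spikes = TRUE, seed = 99,
                       engine = "cpp")
    b <- simulate_ring(params = network_params(N = 30), duration = 0.3,
                       rule = eng_rule, record_spikes = TRUE, seed = 99,
                       engine = "r")
    expect_equal(a$rates, b$rates, tolerance = 1e-10)
    expect_equal(a$W, b$W, tolerance = 1e-10)
    expect_identical(a$spikes, b$spikes)
    expect_equal(a$position, b$position, tolerance = 1e-12)
    expect_equal(a$state$traces$r1, b$state$traces$r1, tolerance = 1e-10)
  }
})

test_that("identical seeds give identical runs (determinism)", {
  a <- simulate_ring(duration = 0.5, seed = 31, record_spikes = TRUE)
  b <- simulate_ring(duration = 0.5, seed = 31, record_spikes = TRUE)
  expect_identical(a$rates, b$rates)
  expect_identical(a$W, b$W)
  expect_identical(a$spikes, b$spikes)
})

test_that("Euler integration converges at first order in dt", {
  run_dt <- function(dt) {
    params <- network_params(N = 20, dt = dt)
    sim <- simulate_ring(params, input_config(f = 8),
                         motion_model(kind = "constant", v_const = 1),
                         depression_params(), rule = NULL, duration = 0.1,
                         record_every = round(0.1 / dt), seed = 1)
    sim$rates[nrow(sim$rates), ]
  }
  ref <- run_dt(1.25e-5)
  e1 <- max(abs(run_dt(1e-4) - ref))
  e2 <- max(abs(run_dt(5e-5) - ref))
  expect_equal(e1 / e2, 2, tolerance = 0.25)
})

test_that("driven linear ring settles onto the closed-form periodic steady state", {
  ## fixed connectivity with known modes, linear transfer, no depression
  N <- 100
  th <- uniform_centers(N)
  w0 <- 0.5; weven <- 0.8; wodd <- 0.3
  c0 <- 40
  W <- c0 + weven * cos(outer(th, th, "-")) + wodd * sin(outer(th, th, "-"))
  v <- 1
  params <- network_params(N = N, wI = c0 - w0, dt = 2e-5)
  inp <- input_config(I0 = 3, IPF = 2, Itheta = 1, f = 8)
  sim <- simulate_ring(params, inp, motion_model(kind = "constant", v_const = v),
                       depression_params(U0 = 0), rule = NULL, duration = 3,
                       centers = th, W = W, record_every = 25L,
                       linear_phi = TRUE, seed = 1)
  keep <- sim$time > 2
  tt <- sim$time[keep]
  y <- as.vector(sim$rates[keep, ])
  X <- NULL
  for (vv in c(v, v + 2 * pi * 8, v - 2 * pi * 8)) {
    ph <- outer(tt, th, function(t, o) o - vv * t)
    X <- cbind(X, as.vector(cos(ph)), as.vector(sin(ph)))
  }
  cf <- unname(coef(lm(y ~ X)))
  theory <- selfconsistent_coefficients(w0, weven, wodd, inp, params$tau, v)
  expected <- c(theory$r0_tilde, theory$r_even, theory$r_odd,
                theory$r_even_plus, theory$r_odd_plus,
                theory$r_even_minus, theory$r_odd_minus)
  expect_equal(cf[1], expected[1], tolerance = 1e-3)
  expect_equal(cf[2:3], expected[2:3], tolerance = 1e-3)
  ## theta sidebands carry a slightly larger Euler bias at |v +/- 2 pi f|
  expect_equal(cf[4:7], expected[4:7], tolerance = 3e-3)
})
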