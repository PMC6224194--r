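test_that("STDP kernel is the stated piecewise exponential", {
  rule <- pair_rule()
  expect_equal(stdp_kernel(rule, 0), 0.1) # T = 0 counted as potentiation
  expect_equal(stdp_kernel(rule, -0.060), -(0.1 / 3) * exp(-1),
               tolerance = 1e-12)
  expect_equal(stdp_kernel(rule, 0.020), 0.1 * exp(-1), tolerance = 1e-12)
  expect_lt(abs(stdp_kernel(rule, 5)), 1e-20)
  expect_lt(abs(stdp_kernel(rule, -5)), 1e-20)
})

test_that("balance residuals are reported for pair and triplet rules", {
  b <- is_balanced(pair_rule())
  expect_true(b$balanced)
  expect_equal(unname(b$residuals["pair"]), 0)
  b2 <- is_balanced(pair_rule(A_plus = 0.1, tau_plus = 0.020,
                              A_minus = 0.1, tau_minus = 0.060))
  expect_false(b2$balanced)
  expect_equal(unname(b2$residuals["pair"]), -0.004)
  expect_true(is_balanced(plasticity_preset("antisymmetric"))$balanced)
  ## the depression-dominant variant swaps amplitudes but keeps the window
  ## widths, so it is net depressing at constant rates (bursts die out)
  expect_false(is_balanced(plasticity_preset("depression_dominant"))$balanced)
  bt <- is_balanced(triplet_rule())
  expect_true(bt$balanced)
  expect_length(bt$residuals, 3)
  bt2 <- is_balanced(triplet_rule(A3_minus = 0.09, tau_x3 = 0.2))
  expect_false(bt2$balanced)
})

test_that("no spikes leaves weights untouched and traces decaying", {
  W <- matrix(30, 4, 4)
  tr <- new_trace_state(4)
  tr$r1 <- c(1, 0, 0.5, 0)
  out <- apply_pair_updates(W, tr, rep(0L, 4), pair_rule(), 80, 1e-3)
  expect_identical(out$W, W)
  expect_equal(out$traces$r1, c(1, 0, 0.5, 0) * exp(-1e-3 / 0.020))
})

test_that("a pre-post pair at 10 ms latency potentiates by A+ exp(-10/20)", {
  dt <- 1e-3
  rule <- pair_rule()
  W <- matrix(40, 2, 2)
  tr <- new_trace_state(2)
  ## pre spike of neuron 2 at t = 0
  st <- apply_pair_updates(W, tr, c(0L, 1L), rule, 80, dt)
  ## 9 silent steps, post spike of neuron 1 at t = 10 ms
  for (i in 1:9) st <- apply_pair_updates(st$W, st$traces, c(0L, 0L), rule, 80, dt)
  st <- apply_pair_updates(st$W, st$traces, c(1L, 0L), rule, 80, dt)
  dw <- st$W[1, 2] - 40
  ## net change = potentiation A+ e^{-10/20}; (no depression: neuron 1 had no
  ## post trace at neuron 2's spike)
  expect_equal(dw, 0.1 * exp(-0.010 / 0.020), tolerance = 1e-12)
  ## reversed order depresses
  tr <- new_trace_state(2)
  st <- apply_pair_updates(W, tr, c(1L, 0L), rule, 80, dt) # post first
  for (i in 1:9) st <- apply_pair_updates(st$W, st$traces, c(0L, 0L), rule, 80, dt)
  st <- apply_pair_updates(st$W, st$traces, c(0L, 1L), rule, 80, dt) # then pre
  expect_equal(st$W[1, 2] - 40, -(0.1 / 3) * exp(-0.010 / 0.060),
               tolerance = 1e-12)
})

test_that("trace superposition: two pre spikes sum their exponential contributions", {
  dt <- 1e-3
  rule <- pair_rule()
  W <- matrix(40, 2, 2)
  tr <- new_trace_state(2)
  st <- apply_pair_updates(W, tr, c(0L, 1L), rule, 80, dt)     # pre at 0
  for (i in 1:4) st <- apply_pair_updates(st$W, st$traces, c(0L, 0L), rule, 80, dt)
  st <- apply_pair_updates(st$W, st$traces, c(0L, 1L), rule, 80, dt)     # pre at 5 ms
  for (i in 1:4) st <- apply_pair_updates(st$W, st$traces, c(0L, 0L), rule, 80, dt)
  st <- apply_pair_updates(st$W, st$traces, c(1L, 0L), rule, 80, dt)     # post at 10 ms
  expect_equal(st$W[1, 2] - 40,
               0.1 * (exp(-0.010 / 0.020) + exp(-0.005 / 0.020)),
               tolerance = 1e-12)
})

test_that("weights stay clipped to [0, wmax] under repeated updates", {
  dt <- 1e-3
  rule <- pair_rule(A_plus = 50, A_minus = 50)
  W <- matrix(79, 2, 2)
  tr <- new_trace_state(2)
  tr$r1 <- c(1, 1)
  st <- apply_pair_updates(W, tr, c(1L, 0L), rule, 80, dt)
  expect_equal(st$W[1, 2], 80)
  tr <- new_trace_state(2)
  tr$o1 <- c(1, 1)
  W <- matrix(0.5, 2, 2)
  st <- apply_pair_updates(W, tr, c(0L, 1L), rule, 80, dt)
  expect_equal(st$W[1, 2], 0)
  expect_equal(st$W[1, 1], 0.5) # autapse untouched
})

test_that("triplet rule with A3 = 0 reproduces the pairwise trajectory", {
  set.seed(8)
  dt <- 1e-3
  tri <- triplet_rule(A3_plus = 0, A3_minus = 0)
  pw <- pair_rule()
  W1 <- W2 <- matrix(40, 5, 5)
  t1 <- new_trace_state(5, triplet = TRUE)
  t2 <- new_trace_state(5)
  for (k in 1:200) {
    sp <- as.integer(runif(5) < 0.05)
    s1 <- apply_triplet_updates(W1, t1, sp, tri, 80, dt)
    s2 <- apply_pair_updates(W2, t2, sp, pw, 80, dt)
    W1 <- s1$W; t1 <- s1$traces
    W2 <- s2$W; t2 <- s2$traces
  }
  expect_equal(W1, W2, tolerance = 1e-12)
})

test_that("post-post-pre triplet sequence matches event-by-event hand computation", {
  dt <- 1e-3
  rule <- triplet_rule(A2_plus = 0.1, A2_minus = 0.05, A3_plus = 0.2,
                       A3_minus = 0.15, tau_y = 0.1, tau_x3 = 0.1)
  W <- matrix(40, 2, 2)
  tr <- new_trace_state(2, triplet = TRUE)
  ## post (cell 1) at t=0; post at t=5ms; pre (cell 2) at t=9ms; post at t=12ms
  st <- apply_triplet_updates(W, tr, c(1L, 0L), rule, 80, dt)
  for (i in 1:4) st <- apply_triplet_updates(st$W, st$traces, c(0L, 0L), rule, 80, dt)
  ## second post: o2 trace (pre-increment) = e^{-5ms/tau_y}; but r1 = 0, so no change
  st <- apply_triplet_updates(st$W, st$traces, c(1L, 0L), rule, 80, dt)
  expect_equal(st$W[1, 2], 40)
  for (i in 1:3) st <- apply_triplet_updates(st$W, st$traces, c(0L, 0L), rule, 80, dt)
  ## pre spike at 9 ms: depression o1_1*(A2- + A3- * r2_2(before incr = 0))
  o1_at_9 <- exp(-0.009 / rule$tau_minus) + exp(-0.004 / rule$tau_minus)
  st <- apply_triplet_updates(st$W, st$traces, c(0L, 1L), rule, 80, dt)
  w_after_pre <- 40 - o1_at_9 * rule$A_minus
  expect_equal(st$W[1, 2], w_after_pre, tolerance = 1e-12)
  for (i in 1:2) st <- apply_triplet_updates(st$W, st$traces, c(0L, 0L), rule, 80, dt)
  ## post at 12 ms: potentiation r1_2 * (A2+ + A3+ * o2_1(before incr))
  r1_at_12 <- exp(-0.003 / rule$tau_plus)
  o2_before <- exp(-0.012 / rule$tau_y) + exp(-0.007 / rule$tau_y)
  st <- apply_triplet_updates(st$W, st$traces, c(1L, 0L), rule, 80, dt)
  expect_equal(st$W[1, 2],
               w_after_pre + r1_at_12 * (rule$A_plus + rule$A3_plus * o2_before),
               tolerance = 1e-12)
})

test_that("amplitude scaling multiplies all amplitudes and preserves balance", {
  r <- scale_rule(plasticity_preset("triplet"), 3)
  expect_equal(r$A_plus, 0.3)
  expect_equal(r$A3_plus, 0.3)
  expect_true(is_balanced(r)$balanced)
})
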