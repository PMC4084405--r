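test_that("synapse_kinetics validates its arguments", {
  expect_error(synapse_kinetics(components = list(c(0.7, 700), c(0.5, 1300))),
               "sum to 1")
  expect_error(synapse_kinetics(components = list(c(1, -5))), "tau")
  expect_error(synapse_kinetics(v_slope = 0), "v_slope")
  k <- synapse_kinetics()
  expect_s3_class(k, "synapse_kinetics")
  expect_equal(k$tau, c(700, 1300))
  expect_equal(k$weights, c(0.5, 0.5))
})

test_that("steady-state activation is threshold-gated and bounded", {
  k <- synapse_kinetics()
  expect_identical(steady_state_activation(-50, k), 0)
  expect_identical(steady_state_activation(k$v_thresh, k), 0)
  s <- steady_state_activation(c(0, 10, 30, 1000), k)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s < 1))
  expect_equal(steady_state_activation(10, k), tanh(20 / 20))
  expect_error(steady_state_activation(NaN, k), "non-finite")
})

test_that("step_activation enforces the stability contract and decays below threshold", {
  k <- synapse_kinetics()
  st <- activation_state(k)
  expect_error(step_activation(st, -50, 0, k), "dt")
  expect_error(step_activation(st, -50, 200, k), "dt too large")
  # a single step from S = 0 below threshold stays at zero
  st2 <- step_activation(st, -50, 1, k)
  expect_identical(st2$S, c(0, 0))
  expect_identical(st2$t, 1)
})

test_that("clamp_trace agrees with the explicit per-step update loop", {
  k <- synapse_kinetics()
  set.seed(3)
  v <- -50 + cumsum(rnorm(500, 0, 3))
  dt <- 0.5
  fast <- clamp_trace(v, k, dt)
  st <- activation_state(k)
  slow <- numeric(length(v))
  for (i in seq_along(v)) {
    st <- step_activation(st, v[i], dt, k)
    slow[i] <- synaptic_current(st, k)
  }
  expect_equal(fast, slow, tolerance = 1e-9)
})

test_that("clamp current is inhibitory for depolarised C2 and zero at rest", {
  k <- synapse_kinetics()
  dt <- 1
  v_rest <- rep(-50, 200)
  expect_true(all(clamp_trace(v_rest, k, dt) == 0))
  v_spike <- c(rep(-50, 10), rep(30, 20), rep(-50, 400))
  i_syn <- clamp_trace(v_spike, k, dt)
  expect_lt(min(i_syn), 0)          # V_syn (-80) below rest (-50): inhibitory
  expect_true(all(i_syn <= 0))
  # and the tail decays monotonically after the presynaptic spike
  tail_part <- i_syn[40:400]
  expect_true(all(diff(tail_part) >= 0))
})

test_that("clamp_trace rejects degenerate input", {
  k <- synapse_kinetics()
  expect_error(clamp_trace(numeric(0), k, 1), "empty")
  expect_error(clamp_trace(c(-50, NA), k, 1), "non-finite")
  expect_error(clamp_trace(rep(-50, 5), k, 1000), "dt")
})
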