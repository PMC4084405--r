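test_that("measure_psp recovers known biphasic amplitudes on a clean trace", {
  dt <- 0.5
  t <- seq(0, 10, by = dt / 1000)
  base <- -50
  depol <- 0.8 * exp(-(t - 2.2)^2 / 0.01)
  hyper <- -2.9 * exp(-(t - 4.0)^2 / 0.5)
  v <- base + depol + hyper
  m <- measure_psp(v, dt, baseline_window = c(0, 1.5), search_window = c(1.8, 8))
  expect_equal(m$baseline, -50, tolerance = 1e-6)
  expect_equal(m$depolarization, 0.8, tolerance = 0.01)
  expect_equal(m$hyperpolarization, 2.9, tolerance = 0.01)
  expect_lt(m$peak_time, m$trough_time)
})

test_that("measure_psp floors monophasic potentials at zero", {
  dt <- 0.5
  t <- seq(0, 10, by = dt / 1000)
  v <- -50 - 2 * exp(-(t - 4)^2 / 0.5)    # purely hyperpolarizing
  m <- measure_psp(v, dt, c(0, 1.5), c(2, 5))
  expect_lt(m$depolarization, 1e-3)
  expect_gt(m$hyperpolarization, 1.9)
  expect_error(measure_psp(v, dt, c(0, 20), c(2, 8)), "window")
})

test_that("Hi-Di PSP generator round-trips through measure_psp without noise", {
  for (h in c(0.5, 2.9, 5.5)) {
    a <- virtual_animal(h = h, d = 0.8)
    tr <- generate_hi_di_psp_trace(a, noise_sd = 0, seed = 1)
    m <- measure_psp(tr$trace$VSI, tr$dt, tr$baseline_window, tr$search_window)
    expect_equal(m$hyperpolarization, h, tolerance = 0.005 * h)
    expect_equal(m$depolarization, 0.8, tolerance = 0.05)
  }
})

test_that("measure_epsp_barrage recovers synthetic EPSP events", {
  dt <- 0.5
  n <- 30000                                  # 15 s
  t <- (seq_len(n) - 1L) * dt / 1000
  v <- rep(-50, n)
  ev <- c(2.5, 3.0, 3.5, 4.2, 5.0)            # s
  for (te in ev) {
    idx <- which(t >= te & t < te + 0.15)
    v[idx] <- v[idx] + 1.2 * exp(-(t[idx] - te) / 0.03) *
      (1 - exp(-(t[idx] - te) / 0.004))
  }
  out <- measure_epsp_barrage(v, dt, stim_onset = 2)
  expect_length(out$times, length(ev))
  expect_true(all(abs(out$times - ev) < 0.05))
  expect_true(all(out$amplitudes > 0.5))
  expect_equal(nrow(out$frequency), length(ev) - 1L)
  expect_equal(out$frequency$hz[1], 1 / 0.5, tolerance = 0.1)
})

test_that("measure_epsp_barrage validates the window", {
  expect_error(measure_epsp_barrage(rep(-50, 100), 0.5, stim_onset = 2),
               "span")
})
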