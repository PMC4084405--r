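test_that("detect_spikes finds peak-aligned threshold crossings", {
  dt <- 0.5
  n <- 4000
  v <- rep(-60, n)
  spike_at <- c(500, 1500, 3000)          # sample indices
  for (i0 in spike_at) v[i0 + 0:4] <- c(-20, 10, 30, 10, -20)
  tt <- detect_spikes(v, dt, threshold = -10)
  expect_length(tt, 3)
  expect_equal(tt, (spike_at + 2 - 1) * dt / 1000, tolerance = 1e-9)
})

test_that("detect_spikes honours the refractory window", {
  dt <- 1
  v <- rep(-60, 100)
  v[c(10, 12, 14)] <- 20                   # 2 ms apart: one event
  v[40] <- 20
  tt <- detect_spikes(v, dt, threshold = 0, refractory = 5)
  expect_length(tt, 2)
  expect_error(detect_spikes(numeric(0), 1), "empty")
  expect_error(detect_spikes(c(1, NA), 1), "non-finite")
})

test_that("detect_bursts edge cases", {
  expect_identical(detect_bursts(numeric(0))$n, 0L)
  # singleton groups are discarded
  expect_identical(detect_bursts(c(1, 5, 9))$n, 0L)
  # a gap of exactly max_isi splits
  b <- detect_bursts(c(1, 1.5, 2.5, 3.0))
  expect_identical(b$n, 2L)
  # stimulus-window spikes are excluded and counted
  b2 <- detect_bursts(c(0.2, 0.5, 2, 2.1, 2.2), stim_window = c(0, 1))
  expect_identical(b2$n, 1L)
  expect_identical(b2$excluded_stim_spikes, 2L)
  expect_error(detect_bursts(c(2, 1)), "sorted")
})

test_that("match_and_classify pairs one-to-one and labels by lag sign", {
  soma <- c(1.0, 2.0, 3.0)
  nerve <- c(1.0 - 0.02, 2.0 + 0.02, 3.5)   # lead, lag, far away
  out <- match_and_classify(soma, nerve, window = 50)
  expect_identical(out$spikes$label, c("antidromic", "orthodromic", "unmatched"))
  expect_equal(out$spikes$lag_ms, c(-20, 20, NA))
  # ambiguous lags inside the band are unmatched
  amb <- match_and_classify(1, 1.0002, window = 50, ambiguity = 0.5)
  expect_identical(amb$spikes$label, "unmatched")
})

test_that("match_and_classify aggregates burst and animal labels", {
  soma <- c(seq(1, 1.4, 0.1), seq(8, 8.4, 0.1))
  nerve <- c(soma[1:5] - 0.025, soma[6:10] + 0.025)
  out <- match_and_classify(soma, nerve)
  expect_identical(out$animal, "mixed")
  expect_identical(out$bursts$label, c("antidromic", "orthodromic"))
  # empty input: NA animal
  expect_true(is.na(match_and_classify(numeric(0), numeric(0))$animal))
})

test_that("classify_impulse_waveform distinguishes triphasic from biphasic", {
  dt <- 0.1
  t <- seq(0, 8, by = dt)
  tri <- -exp(-(t - 2)^2 / 0.05) + 1.5 * exp(-(t - 3)^2 / 0.05) -
    exp(-(t - 4)^2 / 0.05)
  bi <- -exp(-(t - 3)^2 / 0.05) + 0.8 * exp(-(t - 4)^2 / 0.05)
  expect_identical(classify_impulse_waveform(tri, dt), "triphasic")
  expect_identical(classify_impulse_waveform(bi, dt), "biphasic")
  expect_identical(classify_impulse_waveform(rep(0, 100), dt), "unknown")
  expect_error(classify_impulse_waveform(rep(0, 10), 0.1), "5 ms")
})

test_that("rendered nerve impulse templates classify as their own kind", {
  dt <- 0.05
  for (kind in c("triphasic", "biphasic")) {
    tpl <- nerve_impulse_template(kind, dt = dt)
    pad <- rep(0, round(3 / dt))
    expect_identical(classify_impulse_waveform(c(pad, tpl, pad), dt), kind)
  }
})
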