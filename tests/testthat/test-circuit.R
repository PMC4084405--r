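test_that("circuit construction and switches", {
  a <- virtual_animal(h = 2.9, d = 0.8)
  circ <- build_circuit(a)
  expect_s3_class(circ, "cpg_circuit")
  expect_true(circ$pdn6_intact)
  expect_identical(circ$clamp_mode, "off")
  les <- apply_lesion(circ)
  expect_false(les$pdn6_intact)
  hd <- set_hi_di(circ)
  expect_true(hd$hi_di)
  cl <- attach_dynamic_clamp(circ, synapse_kinetics(), mode = "subtract")
  expect_identical(cl$clamp_mode, "subtract")
  expect_error(attach_dynamic_clamp(circ, synapse_kinetics(
    components = list(c(1, 700))), mode = "add"), "two decay components")
})

test_that("episodes are deterministic given a seed and silent without stimulation", {
  circ <- build_circuit(virtual_animal())
  r1 <- simulate_episode(circ, stim_swim(), duration = 80, seed = 5)
  r2 <- simulate_episode(circ, stim_swim(), duration = 80, seed = 5)
  expect_identical(r1$soma_events, r2$soma_events)
  expect_identical(r1$nerve_impulse_times, r2$nerve_impulse_times)
  r3 <- simulate_episode(circ, stim_swim(), duration = 80, seed = 6)
  expect_false(identical(r1$soma_events, r3$soma_events))

  quiet <- simulate_episode(circ, stim_none(), duration = 80, seed = 5)
  expect_identical(nrow(quiet$soma_events), 0L)
  expect_identical(count_vsi_bursts(quiet), 0L)
})

test_that("the default animal swims with the canonical burst count and bounded voltages", {
  circ <- build_circuit(virtual_animal(h = 2.9, d = 0.8))
  rec <- simulate_episode(circ, stim_swim(), duration = 80, seed = 1,
                          keep_traces = TRUE)
  nb <- count_vsi_bursts(rec)
  expect_gte(nb, 5)
  expect_lte(nb, 7)
  v <- as.matrix(rec$channels[, c("C2", "VSI_soma")])
  expect_true(all(v >= -120 & v <= 60))
  expect_true(all(diff(rec$channels$time) > 0))
})

test_that("the lesion silences the nerve and the distal pathway", {
  circ <- apply_lesion(build_circuit(virtual_animal()))
  rec <- simulate_episode(circ, stim_swim(), duration = 80, seed = 1)
  expect_length(rec$nerve_impulse_times, 0)
  expect_true(all(rec$soma_events$origin == "proximal"))
})

test_that("late-episode VSI spikes of the intact default animal are antidromic", {
  circ <- build_circuit(virtual_animal())
  rec <- simulate_episode(circ, stim_swim(), duration = 80, seed = 2)
  pr <- classify_episode_propagation(rec)
  bb <- detect_bursts(rec$soma_events$time, rec$stim_window)$bursts
  last <- bb[nrow(bb), ]
  lab <- pr$spikes$label[pr$spikes$time >= last$start &
                           pr$spikes$time <= last$end]
  expect_gt(mean(lab == "antidromic"), 0.5)
})

test_that("Hi-Di PSP of the calibrated circuit matches the animal's phenotype", {
  # noise-free configuration: the end-to-end Hi-Di measurement is then exact
  cfg <- cpg_defaults(dsi_noise = 0, c2_noise = 0, vsip_noise = 0,
                      vsid_noise = 0)
  for (h in c(0.5, 2.9, 5.5)) {
    circ <- set_hi_di(build_circuit(virtual_animal(h = h, d = 0.8), cfg))
    rec <- simulate_episode(circ, stim_c2(), duration = 14, seed = 1,
                            keep_traces = TRUE)
    m <- measure_psp(rec$channels$VSI_soma, rec$dt,
                     baseline_window = c(0.5, 1.8), search_window = c(2, 12))
    expect_lt(abs(m$hyperpolarization - h) / h, 0.05)
    expect_lt(abs(m$depolarization - 0.8) / 0.8, 0.05)
  }
})

test_that("episode recordings round-trip through the text writers", {
  circ <- build_circuit(virtual_animal())
  rec <- simulate_episode(circ, stim_c2(), duration = 14, seed = 1,
                          keep_traces = TRUE)
  stem <- file.path(tempdir(), "episode-roundtrip")
  write_episode(rec, stem)
  back <- read_trace(paste0(stem, ".tsv"))
  expect_identical(names(back), names(rec$channels))
  expect_equal(back$VSI_soma, rec$channels$VSI_soma, tolerance = 1e-6)
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  expect_equal(meta$stim_window, rec$stim_window)
})
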