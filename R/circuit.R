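#' Default parameters of the swim-circuit model
#'
#' A named list of every numeric constant of the hybrid integrate-and-fire
#' model of the DSI-C2-VSI circuit: membrane parameters per unit (pF, nS, mV,
#' ms), current-based synaptic kernel weights (pA) and time constants (ms),
#' the PdN6 conduction delay, the threshold-gated release kinetics of the
#' direct C2-to-VSI synapse, the recruited polysynaptic EPSP pool, and the
#' swim-drive reservoir that paces and terminates the episode.
#'
#' The three DSIs are collapsed into one unit carrying their summed synaptic
#' weight. VSI is split into a proximal (soma-side) and a distal
#' spike-initiation zone; only axonal spikes that cross PdN6 connect the two.
#'
#' @param ... Named overrides of individual defaults.
#' @return Named list of parameters.
#' @export
cpg_defaults <- function(...) {
  p <- list(
    # DSI (lumped group of three)
    dsi_C = 120, dsi_gL = 8, dsi_EL = -55, dsi_VT = -40, dsi_Vreset = -62,
    dsi_tref = 12, dsi_b = 24, dsi_tauw = 600, dsi_noise = 25,
    # C2
    c2_C = 160, c2_gL = 8, c2_EL = -55, c2_VT = -40, c2_Vreset = -60,
    c2_tref = 70, c2_b = 70, c2_tauw = 2600, c2_noise = 25,
    c2_w_hi = 110, c2_w_lo = 10,  # hysteretic burst gate (0 = disabled)
    # VSI proximal zone (recorded at the soma)
    vsip_C = 120, vsip_gL = 8, vsip_EL = -50, vsip_VT = -40, vsip_Vreset = -58,
    vsip_tref = 18, vsip_b = 8, vsip_tauw = 1500, vsip_noise = 25,
    # VSI distal zone (in the distal pedal ganglion)
    vsid_C = 100, vsid_gL = 10, vsid_EL = -55, vsid_VT = -40, vsid_Vreset = -60,
    vsid_tref = 25, vsid_b = 2, vsid_tauw = 900, vsid_noise = 25,
    spike_render_ms = 2,
    # network kernels
    tau_dsi_c2 = 180, w_dsi_c2 = 220,
    tau_c2_dsi = 150, w_c2_dsi = 8,
    tau_vsi_c2 = 1200, w_vsi_c2 = -60,
    tau_vsi_dsi = 800, w_vsi_dsi = -40,
    vsip_inh_scale = 0, tau_vsip_inh = 1200,
    tau_c2_vsid = 550, w_c2_vsid = 120,
    pdn6_delay = 25, pdn6_electrode_frac = 0.3,
    # direct C2->VSIp synapse: release kinetics
    syn_vthresh = -10, syn_vslope = 20,
    syn_tau_fast = 150, syn_tau_slow1 = 700, syn_tau_slow2 = 1300,
    A_d = 0, A_h = 0,          # set per animal by the PSP calibration
    # normal-saline gains of the two components relative to Hi-Di, and the
    # deactivation time constant of the slow inhibitory conductance
    depol_gain_normal = 1, hyperpol_gain_normal = 600, h_filter_tau = 2500,
    # dynamic clamp (literal dual-component model, V_post fixed)
    clamp_gsyn = 0, clamp_vsyn = -80, clamp_vpost = -50, clamp_w1 = 0.5,
    clamp_net_gain = 0.25,     # pA per nS*mV in the reduced current scale
    # recruited polysynaptic pool
    tau_pool = 180, pool_rise = 80, pool_per_spike = 1,
    pool_rate_hz = 550, pool_rate0 = 0.5, pool_cap = 3, pool_floor = 0.6,
    epsp_meanlog = log(0.3), epsp_sdlog = 0.45, epsp_gain = 120, tau_epsp = 30,
    # swim drive
    D0 = 1, tau_D = 42000, c_rel = 0.004, kD = 500,
    stim_dsi = 150, stim_vsip = 60, stim_vsip_dur = 600,
    # direct C2 stimulation
    c2_pulse = 620, c2_pulse_width = 20, c2_rate = 10,
    hidi_vt_shift = 60, hidi_pulse_boost = 2.5,
    # per-animal hidden parameters (overridden by build_circuit)
    distal_gain = 1,
    # switches / protocol placeholders filled by simulate_episode
    pdn6_intact = TRUE, hi_di = FALSE, clamp_mode = 0L,
    stim_type = 0L, stim_start = 2, stim_dur = 3
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("cpg_defaults(): unknown parameter(s): ",
                          paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p
}

#' Build a swim circuit for one (virtual) animal
#'
#' Instantiates the circuit with the animal's hidden synaptic phenotype: the
#' direct C2-to-VSI synaptic scales are calibrated so that, in high-divalent
#' (Hi-Di) saline with the standard 10 Hz / 4 s C2 stimulation, the isolated
#' biphasic PSP measured at the VSI soma has depolarization amplitude `d` and
#' hyperpolarization amplitude `h` (mV). The distal excitability multiplier
#' scales the C2 drive onto the distal spike-initiation zone.
#'
#' @param animal A [virtual_animal()] (or any list with numeric `h`, `d`,
#'   and optionally `drive`, `distal_gain`).
#' @param config Circuit parameter list from [cpg_defaults()].
#' @return Object of class `cpg_circuit`.
#' @export
build_circuit <- function(animal, config = cpg_defaults()) {
  h <- animal$h; d <- animal$d
  if (!is.numeric(h) || h < 0 || !is.numeric(d) || d < 0)
    stop("build_circuit(): need h >= 0 and d >= 0")
  par <- config
  if (!is.null(animal$distal_gain)) par$distal_gain <- animal$distal_gain
  if (!is.null(animal$drive)) par$D0 <- animal$drive
  amp <- calibrate_direct_synapse(h, d, config)
  par$A_h <- amp["A_h"]; par$A_d <- amp["A_d"]
  structure(list(par = par, animal = animal,
                 pdn6_intact = TRUE, hi_di = FALSE,
                 clamp = NULL, clamp_mode = "off"),
            class = "cpg_circuit")
}

#' @export
print.cpg_circuit <- function(x, ...) {
  cat(sprintf("Swim CPG circuit: h = %.2f mV, d = %.2f mV; PdN6 %s; %s saline; clamp %s\n",
              x$animal$h, x$animal$d,
              if (x$pdn6_intact) "intact" else "disconnected",
              if (x$hi_di) "Hi-Di" else "normal",
              x$clamp_mode))
  invisible(x)
}

#' Disconnect PdN6
#'
#' Models both physical transection and TTX propagation block: no axonal
#' spike crosses between the distal and proximal pedal ganglia in either
#' direction, and C2's commissural drive onto the distal VSI zone is cut.
#' Idempotent; all other parameters untouched.
#'
#' @param circuit A `cpg_circuit`.
#' @return The lesioned circuit.
#' @export
apply_lesion <- function(circuit) {
  stopifnot(inherits(circuit, "cpg_circuit"))
  circuit$pdn6_intact <- FALSE
  circuit
}

#' Switch the bathing medium to (or from) Hi-Di saline
#'
#' High-divalent-cation saline raises every unit's firing threshold and
#' silences the recruited polysynaptic pool, isolating the monosynaptic
#' C2-to-VSI potential.
#'
#' @param circuit A `cpg_circuit`.
#' @param on Logical.
#' @return The modified circuit.
#' @export
set_hi_di <- function(circuit, on = TRUE) {
  stopifnot(inherits(circuit, "cpg_circuit"))
  circuit$hi_di <- isTRUE(on)
  circuit
}

#' Attach (or detach) the dynamic clamp
#'
#' During simulation the clamp computes the artificial synaptic current from
#' the C2 membrane potential with the given release kinetics and injects it
#' into the proximal VSI zone only (the site of electrode impalement, the
#' soma). `"subtract"` negates the maximal conductance.
#'
#' @param circuit A `cpg_circuit`.
#' @param kinetics A [synapse_kinetics()] object (two decay components).
#' @param mode One of `"add"`, `"subtract"`, `"off"`.
#' @return The modified circuit.
#' @export
attach_dynamic_clamp <- function(circuit, kinetics = synapse_kinetics(),
                                 mode = c("add", "subtract", "off")) {
  stopifnot(inherits(circuit, "cpg_circuit"),
            inherits(kinetics, "synapse_kinetics"))
  mode <- match.arg(mode)
  if (circuit$hi_di && mode != "off")
    warning("attach_dynamic_clamp(): clamping in Hi-Di saline is untested territory")
  if (length(kinetics$tau) != 2L)
    stop("attach_dynamic_clamp(): clamp kinetics must have two decay components")
  circuit$clamp <- kinetics
  circuit$clamp_mode <- mode
  circuit
}

# ---- calibration of the direct synapse --------------------------------------

# cache of Hi-Di unit responses, keyed by the config values they depend on
.swimcpg_cache <- new.env(parent = emptyenv())

.unit_response_key <- function(config) {
  dep <- config[c("vsip_C", "vsip_gL", "vsip_EL", "syn_vthresh", "syn_vslope",
                  "syn_tau_fast", "syn_tau_slow1", "syn_tau_slow2",
                  "c2_pulse", "c2_pulse_width", "c2_rate", "hidi_vt_shift",
                  "hidi_pulse_boost", "c2_C", "c2_gL", "c2_EL", "c2_VT",
                  "c2_Vreset", "c2_tref", "c2_b", "c2_tauw", "spike_render_ms")]
  paste(format(unlist(dep), digits = 12), collapse = "|")
}

# Simulate the deterministic (noise-free) Hi-Di voltage deviation of the
# proximal VSI zone for a unit-amplitude depolarising and a unit-amplitude
# hyperpolarising synaptic component under the standard 10 Hz / 4 s C2 train.
.hidi_unit_responses <- function(config) {
  key <- .unit_response_key(config)
  hit <- .swimcpg_cache[[key]]
  if (!is.null(hit)) return(hit)
  base <- config
  base[c("dsi_noise", "c2_noise", "vsip_noise", "vsid_noise")] <- 0
  base$hi_di <- TRUE
  # the unit response is a passive-membrane property of the proximal zone;
  # excluding the nerve path keeps antidromic resets out of the measurement
  base$pdn6_intact <- FALSE
  base$clamp_mode <- 0L
  base$stim_type <- 2L
  base$stim_start <- 2
  base$stim_dur <- 4
  run_unit <- function(A_d, A_h) {
    par <- base; par$A_d <- A_d; par$A_h <- A_h
    out <- simulate_core(par, duration_s = 14, dt = 0.25, keep_traces = TRUE)
    out$traces[, 3] - base$vsip_EL
  }
  u0 <- run_unit(0, 0)     # residual deviation with no direct synapse
  ud <- run_unit(1, 0) - u0
  uh <- run_unit(0, 1) - u0
  res <- list(u0 = u0, ud = ud, uh = uh, dt = 0.25, rest = base$vsip_EL,
              stim_onset = 2)
  .swimcpg_cache[[key]] <- res
  res
}

#' Calibrate the direct C2-to-VSI synaptic scales for target PSP amplitudes
#'
#' Finds the current scales of the fast depolarising and slow (700/1300 ms)
#' hyperpolarising components such that the simulated Hi-Di PSP, measured
#' exactly as in the analysis pipeline ([measure_psp()]), has depolarization
#' amplitude `d` and hyperpolarization amplitude `h`. Because the Hi-Di
#' membrane is passive, the response is linear in the scales and a short
#' fixed-point iteration on the two measured amplitudes converges rapidly.
#'
#' @param h,d Target hyperpolarization / depolarization amplitudes, mV.
#' @param config Circuit parameter list.
#' @param tol Relative tolerance on the recovered amplitudes.
#' @return Named vector `c(A_d, A_h)` in pA.
#' @export
calibrate_direct_synapse <- function(h, d, config = cpg_defaults(),
                                     tol = 0.005) {
  stopifnot(h >= 0, d >= 0)
  if (h == 0 && d == 0) return(c(A_d = 0, A_h = 0))
  ur <- .hidi_unit_responses(config)
  measure <- function(a_d, a_h) {
    v <- ur$rest + ur$u0 + a_d * ur$ud + a_h * ur$uh
    m <- measure_psp(v, ur$dt, baseline_window = c(0.5, ur$stim_onset - 0.2),
                     search_window = c(ur$stim_onset, 12))
    c(dep = m$depolarization, hyp = m$hyperpolarization)
  }
  # initial guesses from the individual unit-response amplitudes
  md <- measure(1, 0); mh <- measure(0, 1)
  a_d <- if (d > 0) d / max(md["dep"], 1e-9) else 0
  a_h <- if (h > 0) h / max(mh["hyp"], 1e-9) else 0
  converged <- function(m) {
    (d == 0 || abs(m["dep"] - d) <= tol * max(d, 0.05)) &&
      (h == 0 || abs(m["hyp"] - h) <= tol * max(h, 0.05))
  }
  # a few damped proportional updates usually land close ...
  for (i in 1:15) {
    m <- measure(a_d, a_h)
    if (converged(m)) break
    if (d > 0 && m["dep"] > 0.05 * d)
      a_d <- a_d * min(max(d / m["dep"], 0.5), 2)
    if (h > 0 && m["hyp"] > 0.05 * h)
      a_h <- a_h * min(max(h / m["hyp"], 0.5), 2)
  }
  # ... and the strongly coupled cases use nested root-finding, which the
  # monotone structure makes reliable: dep increases in a_d and decreases in
  # a_h, hyp increases in a_h and decreases in a_d.
  if (!converged(measure(a_d, a_h)) && d > 0 && h > 0) {
    expand_root <- function(f, hi0) {
      hi <- hi0
      for (i in 1:30) {
        if (f(hi) >= 0) return(stats::uniroot(f, c(0, hi), tol = 1e-9)$root)
        hi <- hi * 2
      }
      stop("calibrate_direct_synapse(): could not bracket PSP targets (d = ",
           d, ", h = ", h, ")")
    }
    ah_for <- function(ad) expand_root(function(x) measure(ad, x)["hyp"] - h,
                                       max(a_h, 1))
    a_d <- expand_root(function(x) measure(x, ah_for(x))["dep"] - d,
                       max(a_d, 1))
    a_h <- ah_for(a_d)
  }
  if (!converged(measure(a_d, a_h)))
    stop("calibrate_direct_synapse(): could not match PSP targets (d = ",
         d, ", h = ", h, ")")
  c(A_d = unname(a_d), A_h = unname(a_h))
}
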