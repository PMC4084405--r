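#' Stimulation protocols
#'
#' `stim_swim()` models the body-wall nerve (PdN3) shock that initiates a
#' swim episode: a 3 s excitatory drive to the DSI group (the stimulus train
#' itself) which also charges the slow drive reservoir that sustains and
#' eventually terminates the rhythm. `stim_c2()` models direct intracellular
#' C2 stimulation: repeated 20 ms current pulses producing a constant-rate
#' spike train (default 10 Hz).
#'
#' @param start Stimulus onset, s.
#' @param duration Stimulus duration, s.
#' @param rate Pulse rate for C2 stimulation, Hz.
#' @return A protocol list consumed by [simulate_episode()].
#' @export
stim_swim <- function(start = 2, duration = 3) {
  structure(list(type = 1L, start = start, duration = duration),
            class = "stim_protocol")
}

#' @rdname stim_swim
#' @export
stim_c2 <- function(start = 2, duration = 4, rate = 10) {
  structure(list(type = 2L, start = start, duration = duration, rate = rate),
            class = "stim_protocol")
}

#' @rdname stim_swim
#' @export
stim_none <- function() {
  structure(list(type = 0L, start = 0, duration = 0), class = "stim_protocol")
}

#' Simulate one recording episode
#'
#' Integrates the circuit and returns an episode recording: somatic spike
#' events with their zone of origin, nerve impulse times on PdN6, the
#' recruited-EPSP event train, and (optionally) the sampled voltage traces.
#' With PdN6 intact, a distal-zone spike reaches the soma channel after the
#' commissural conduction delay (an antidromic event, its nerve impulse
#' preceding the soma spike), while a proximal-zone spike reaches the nerve
#' channel after the same delay (orthodromic). With PdN6 disconnected no
#' event crosses in either direction and the nerve channel stays silent.
#' Identical circuit, protocol and seed give an identical recording.
#'
#' @param circuit A `cpg_circuit` from [build_circuit()].
#' @param stim A protocol from [stim_swim()], [stim_c2()] or [stim_none()].
#' @param duration Episode length, s (swim episodes need >= 60 s to play out).
#' @param dt Integration step, ms (must be <= 0.5 ms).
#' @param seed Integer seed; every random element of the episode derives
#'   from it.
#' @param keep_traces Keep the sampled channels (C2, VSI soma, PdN6)?
#' @return Object of class `episode_recording`.
#' @export
simulate_episode <- function(circuit, stim = stim_swim(), duration = 80,
                             dt = 0.25, seed = 1, keep_traces = FALSE) {
  stopifnot(inherits(circuit, "cpg_circuit"), inherits(stim, "stim_protocol"))
  if (dt <= 0 || dt > 0.5) stop("simulate_episode(): need 0 < dt <= 0.5 ms")
  if (stim$type == 1L && duration < 60)
    stop("simulate_episode(): swim episodes need duration >= 60 s")
  par <- circuit$par
  par$pdn6_intact <- circuit$pdn6_intact
  par$hi_di <- circuit$hi_di
  par$stim_type <- stim$type
  par$stim_start <- stim$start
  par$stim_dur <- stim$duration
  if (!is.null(stim$rate)) par$c2_rate <- stim$rate
  par$clamp_mode <- switch(circuit$clamp_mode, off = 0L, add = 1L,
                           subtract = -1L)
  if (!is.null(circuit$clamp) && circuit$clamp_mode != "off") {
    k <- circuit$clamp
    par$clamp_gsyn <- abs(k$g_syn)
    par$clamp_vsyn <- k$v_syn
    par$clamp_vpost <- k$v_post_rest
    par$clamp_w1 <- k$weights[1L]
    # clamp taus follow the kinetics object
    par$syn_tau_slow1 <- par$syn_tau_slow1  # network synapse untouched
    if (k$g_syn < 0 && circuit$clamp_mode == "add")
      par$clamp_mode <- -1L  # negative conductance supplied explicitly
  }
  set.seed(as.integer(seed))
  out <- simulate_core(par, duration_s = duration, dt = dt,
                       keep_traces = keep_traces)
  for (nm in c("spikes_dsi", "spikes_c2", "spikes_vsip", "spikes_vsid",
               "vsid_arrivals", "epsp_times", "epsp_amps"))
    if (any(!is.finite(out[[nm]])))
      stop("simulate_episode(): integration failure (non-finite event) in ", nm)

  delay_s <- par$pdn6_delay / 1000
  if (circuit$pdn6_intact) {
    ev <- rbind(
      data.frame(time = out$spikes_vsip,
                 origin = rep("proximal", length(out$spikes_vsip)),
                 stringsAsFactors = FALSE),
      data.frame(time = out$vsid_arrivals,
                 origin = rep("distal", length(out$vsid_arrivals)),
                 stringsAsFactors = FALSE))
    ev <- ev[order(ev$time), , drop = FALSE]
    # axonal collision clean-up: events closer than 5 ms collapse to the first
    if (nrow(ev) > 1L) {
      keep <- c(TRUE, diff(ev$time) >= 0.005)
      ev <- ev[keep, , drop = FALSE]
    }
    # the en-passant nerve electrode sits a fraction of the conduction path
    # from the soma, so recorded impulses lead/lag soma events by that share
    # of the full delay
    el <- delay_s * par$pdn6_electrode_frac
    nerve <- sort(c(out$vsid_arrivals - el, out$spikes_vsip + el))
    nerve_kind <- "triphasic"
  } else {
    ev <- data.frame(time = out$spikes_vsip,
                     origin = rep("proximal", length(out$spikes_vsip)),
                     stringsAsFactors = FALSE)
    nerve <- numeric(0)
    nerve_kind <- "none"
  }
  rownames(ev) <- NULL

  channels <- NULL
  if (keep_traces) {
    n <- out$n_steps
    tvec <- (seq_len(n) - 1L) * dt / 1000
    soma <- out$traces[, 3]
    # render antidromic invasions on the soma channel
    if (length(out$vsid_arrivals)) {
      shape_n <- max(2L, as.integer(round(2 / dt)))
      shape <- seq(30, par$vsip_Vreset, length.out = shape_n)
      for (ts in out$vsid_arrivals) {
        i0 <- as.integer(round(ts * 1000 / dt)) + 1L
        idx <- i0:min(n, i0 + shape_n - 1L)
        soma[idx] <- pmax(soma[idx], shape[seq_along(idx)])
      }
    }
    nerve_trace <- render_nerve_trace(n, dt, nerve, kind = "triphasic",
                                      noise_sd = 0.05)
    channels <- data.frame(time = tvec, C2 = out$traces[, 2],
                           VSI_soma = soma, PdN6 = nerve_trace,
                           I_clamp = out$traces[, 4])
  }

  structure(list(
    dt = dt, duration = duration,
    channels = channels,
    spike_times = list(DSI = out$spikes_dsi, C2 = out$spikes_c2,
                       VSI_proximal = out$spikes_vsip,
                       VSI_distal = out$spikes_vsid),
    soma_events = ev,
    nerve_impulse_times = nerve,
    nerve_kind = nerve_kind,
    epsp_events = data.frame(time = out$epsp_times, amplitude = out$epsp_amps),
    stim_window = c(stim$start, stim$start + stim$duration),
    condition = list(pdn6_intact = circuit$pdn6_intact, hi_di = circuit$hi_di,
                     clamp_mode = circuit$clamp_mode,
                     stim = class(stim)[1L], stim_type = stim$type),
    animal = circuit$animal, seed = seed),
    class = "episode_recording")
}

#' @export
print.episode_recording <- function(x, ...) {
  nb <- count_vsi_bursts(x)
  cat(sprintf("Episode (%.0f s, dt %.2f ms): PdN6 %s, clamp %s; %d soma spike(s), %d VSI burst(s)\n",
              x$duration, x$dt,
              if (x$condition$pdn6_intact) "intact" else "disconnected",
              x$condition$clamp_mode, nrow(x$soma_events), nb))
  invisible(x)
}

#' Count VSI bursts in an episode recording
#'
#' Applies the burst rule (clusters of >= 2 spikes with < 1 s intervals,
#' stimulus-window spikes excluded) to the somatic spike events.
#'
#' @param rec An `episode_recording`.
#' @return Integer burst count.
#' @export
count_vsi_bursts <- function(rec) {
  stopifnot(inherits(rec, "episode_recording"))
  detect_bursts(rec$soma_events$time, stim_window = rec$stim_window)$n
}

#' Classify VSI spike propagation in an episode
#'
#' Pairs the episode's somatic spikes with its nerve impulses and returns the
#' per-spike, per-burst and per-animal propagation labels.
#'
#' @param rec An `episode_recording`.
#' @param window Pairing window, ms.
#' @return A `propagation_label` (see [match_and_classify()]).
#' @export
classify_episode_propagation <- function(rec, window = 50) {
  stopifnot(inherits(rec, "episode_recording"))
  soma <- rec$soma_events$time
  keep <- soma < rec$stim_window[1L] | soma > rec$stim_window[2L]
  soma <- soma[keep]
  match_and_classify(soma, rec$nerve_impulse_times, window = window,
                     bursts = detect_bursts(soma))
}
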