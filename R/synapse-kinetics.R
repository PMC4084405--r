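#' Artificial synapse kinetics for dynamic clamp
#'
#' Parameters of the first-order-kinetics model of the inhibitory C2-to-VSI
#' synapse used for dynamic-clamp conductance addition and subtraction.
#' The injected current is
#' \deqn{I_{syn}(t) = g_{syn} S(t) [V_{syn} - V_{post}]}
#' with the instantaneous activation of each kinetic component obeying
#' \deqn{(1 - S_\infty(V_{pre}))\,\tau_{syn}\, dS/dt = S_\infty(V_{pre}) - S(t)}
#' and a threshold-gated steady state
#' \deqn{S_\infty = \tanh[(V_{pre} - V_{thresh})/V_{slope}]} for
#' \eqn{V_{pre} > V_{thresh}}, zero otherwise. \eqn{V_{post}} is fixed at the
#' postsynaptic resting potential, so the model is effectively current-based.
#'
#' Two decay components (700 ms and 1300 ms, equal weights) reproduce the
#' time course of the natural slow inhibition. A negative `g_syn` of the
#' same magnitude implements conductance subtraction.
#'
#' @param g_syn Total maximal conductance, nS. Negative values = subtraction.
#' @param v_syn Reversal potential, mV.
#' @param components List of `c(weight, tau_ms)` pairs; weights must sum to 1,
#'   each in (0, 1], every tau > 0.
#' @param v_thresh Presynaptic release threshold, mV (the 50 percent height
#'   of the smallest presynaptic action potentials; default -10 mV for model
#'   C2 spikes peaking near +30 mV from a -50 mV rest).
#' @param v_slope Activation slope, mV (> 0).
#' @param v_post_rest Fixed postsynaptic potential, mV.
#' @return Object of class `synapse_kinetics`.
#' @export
synapse_kinetics <- function(g_syn = 1000, v_syn = -80,
                             components = list(c(0.5, 700), c(0.5, 1300)),
                             v_thresh = -10, v_slope = 20,
                             v_post_rest = -50) {
  stopifnot(is.numeric(g_syn), length(g_syn) == 1L, is.finite(g_syn),
            is.numeric(v_syn), length(v_syn) == 1L, is.finite(v_syn),
            is.list(components), length(components) >= 1L,
            is.numeric(v_thresh), is.numeric(v_slope), is.numeric(v_post_rest))
  w <- vapply(components, `[`, 0, 1L)
  tau <- vapply(components, `[`, 0, 2L)
  if (any(w <= 0) || any(w > 1) || abs(sum(w) - 1) > 1e-9)
    stop("synapse_kinetics(): component weights must be in (0,1] and sum to 1")
  if (any(tau <= 0)) stop("synapse_kinetics(): every tau_syn must be > 0")
  if (v_slope <= 0) stop("synapse_kinetics(): v_slope must be > 0")
  structure(list(g_syn = g_syn, v_syn = v_syn,
                 weights = w, tau = tau,
                 v_thresh = v_thresh, v_slope = v_slope,
                 v_post_rest = v_post_rest),
            class = "synapse_kinetics")
}

#' @export
print.synapse_kinetics <- function(x, ...) {
  cat(sprintf("Artificial synapse: g_syn %.0f nS, V_syn %.0f mV, V_thresh %.0f mV, V_slope %.0f mV\n",
              x$g_syn, x$v_syn, x$v_thresh, x$v_slope))
  cat("  components (weight, tau ms):",
      paste(sprintf("(%.2f, %.0f)", x$weights, x$tau), collapse = " "), "\n")
  invisible(x)
}

# upper clamp keeping the (1 - S_inf) factor of the activation ODE regular
.S_INF_MAX <- 1 - 1e-6

#' Steady-state synaptic activation
#'
#' `tanh((V_pre - V_thresh)/V_slope)` above the release threshold, zero at or
#' below it. The result is capped just below 1 so the effective time constant
#' of the activation equation stays positive.
#'
#' @param v_pre Presynaptic membrane potential, mV (vectorised).
#' @param k A [synapse_kinetics()] object.
#' @return Activation fraction(s) in `[0, 1)`.
#' @export
steady_state_activation <- function(v_pre, k) {
  stopifnot(inherits(k, "synapse_kinetics"))
  if (any(!is.finite(v_pre)))
    stop("steady_state_activation(): non-finite presynaptic voltage (corrupt trace sample)")
  s <- ifelse(v_pre > k$v_thresh,
              tanh((v_pre - k$v_thresh) / k$v_slope), 0)
  pmin(s, .S_INF_MAX)
}

#' Fresh activation state
#'
#' @param k A [synapse_kinetics()] object.
#' @param t Start time, ms.
#' @return Object of class `activation_state` with one zero activation per
#'   kinetic component.
#' @export
activation_state <- function(k, t = 0) {
  stopifnot(inherits(k, "synapse_kinetics"))
  structure(list(S = rep(0, length(k$tau)), t = t), class = "activation_state")
}

#' Advance the synaptic activation by one time step
#'
#' One explicit-Euler step of the activation equation for every kinetic
#' component; this mirrors the per-cycle update of a real-time dynamic clamp.
#' Below threshold (`S_inf = 0`) the update is exponential decay with time
#' constant `tau_syn` exactly. `S` is clamped to `[0, 1 - 1e-9]`.
#'
#' @param state An `activation_state`.
#' @param v_pre Presynaptic membrane potential at this step, mV.
#' @param dt Step, ms; must satisfy `dt <= min(tau)/10` (stability contract).
#' @param k A [synapse_kinetics()] object.
#' @return The advanced `activation_state`.
#' @export
step_activation <- function(state, v_pre, dt, k) {
  stopifnot(inherits(state, "activation_state"), inherits(k, "synapse_kinetics"))
  if (dt <= 0) stop("step_activation(): dt must be > 0")
  if (dt > min(k$tau) / 10)
    stop("step_activation(): dt too large relative to the synaptic time constant")
  s_inf <- steady_state_activation(v_pre, k)
  S <- state$S + dt * (s_inf - state$S) / ((1 - s_inf) * k$tau)
  state$S <- pmin(pmax(S, 0), 1 - 1e-9)
  state$t <- state$t + dt
  state
}

#' Synaptic current for the current activation state
#'
#' @param state An `activation_state`.
#' @param k A [synapse_kinetics()] object.
#' @return Current in pA (nS x mV): the weighted sum over components of
#'   `g_syn * weight * S * (V_syn - V_post_rest)`. Negating `g_syn` flips the
#'   sign (conductance subtraction).
#' @export
synaptic_current <- function(state, k) {
  stopifnot(inherits(state, "activation_state"), inherits(k, "synapse_kinetics"))
  if (any(!is.finite(state$S))) stop("synaptic_current(): non-finite activation")
  sum(k$g_syn * k$weights * state$S * (k$v_syn - k$v_post_rest))
}

#' Compute the dynamic-clamp current for a presynaptic voltage trace
#'
#' Runs the activation update and the current equation sample by sample from
#' a fully deactivated synapse, exactly as a dynamic clamp does on every
#' cycle. The output has the same length as the input.
#'
#' @param v_pre_trace Uniformly sampled presynaptic voltage, mV.
#' @param k A [synapse_kinetics()] object.
#' @param dt Sample interval, ms.
#' @return Numeric vector of injected currents, pA.
#' @export
clamp_trace <- function(v_pre_trace, k, dt) {
  stopifnot(inherits(k, "synapse_kinetics"))
  if (length(v_pre_trace) == 0L) stop("clamp_trace(): empty trace")
  if (any(!is.finite(v_pre_trace)))
    stop("clamp_trace(): non-finite trace sample")
  if (dt <= 0 || dt > min(k$tau) / 10)
    stop("clamp_trace(): dt must be positive and <= min(tau)/10")
  s_inf <- steady_state_activation(v_pre_trace, k)
  S <- clamp_activation_core(s_inf, k$tau, dt)      # components x samples
  drive <- k$g_syn * k$weights * (k$v_syn - k$v_post_rest)
  as.numeric(drive %*% S)
}
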