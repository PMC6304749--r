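# Neuron and synapse dynamics: the membrane equation with the GABA-A switch
# and instantaneous-rise / exponential-decay conductance synapses.

#' Leaky integrate-and-fire neuron parameters
#'
#' Defaults follow the Brette-Gerstner leak parameter set used by the model:
#' the leak drives the membrane toward `E_leak` with time constant `tau_m`,
#' a spike is emitted at `V_threshold`, after which the membrane is clamped
#' at `V_reset` for an absolute refractory period `tau_ref`.  `c_m` divides
#' the synaptic current (the leak term already carries `1/tau_m`).
#'
#' @param tau_m membrane time constant, ms.
#' @param c_m membrane capacitance, pF.
#' @param E_leak leak reversal potential, mV.
#' @param V_threshold spike threshold, mV.
#' @param V_reset post-spike reset (and refractory clamp) potential, mV.
#' @param tau_ref absolute refractory period, ms.
#' @return an object of class `neuron_params`.
#' @export
neuron_params <- function(tau_m = 20, c_m = 281, E_leak = -70.6,
                          V_threshold = -50.4, V_reset = -74, tau_ref = 5) {
  stopifnot(tau_m > 0, c_m > 0, tau_ref >= 0, V_reset < V_threshold)
  structure(list(tau_m = tau_m, c_m = c_m, E_leak = E_leak,
                 V_threshold = V_threshold, V_reset = V_reset,
                 tau_ref = tau_ref),
            class = "neuron_params")
}

#' Synaptic conductance parameters
#'
#' Conductances rise instantaneously by a fixed per-spike increment and
#' decay exponentially (AMPA with `tau_exc`, GABA-A with `tau_inh`).
#'
#' @param tau_exc AMPA conductance decay time constant, ms.
#' @param tau_inh GABA-A conductance decay time constant, ms.
#' @param g_exc per-spike excitatory conductance increment, nS.
#' @param g_inh per-spike inhibitory conductance increment, nS.
#' @param g_ext per-spike external (Poisson input) conductance increment, nS.
#' @param E_exc AMPA reversal potential, mV.
#' @return an object of class `synapse_params`.
#' @export
synapse_params <- function(tau_exc = 5, tau_inh = 10, g_exc = 4, g_inh = 64,
                           g_ext = 200, E_exc = 0) {
  stopifnot(tau_exc > 0, tau_inh > 0,
            g_exc >= 0, g_inh >= 0, g_ext >= 0)
  structure(list(tau_exc = tau_exc, tau_inh = tau_inh, g_exc = g_exc,
                 g_inh = g_inh, g_ext = g_ext, E_exc = E_exc),
            class = "synapse_params")
}

#' Maturation state of GABA-A signalling
#'
#' The developmental switch is modelled purely as the GABA-A reversal
#' potential: depolarizing -40 mV in the immature network, hyperpolarizing
#' -70 mV in the mature network.
#'
#' @param label `"immature"` or `"mature"`.
#' @return an object of class `maturation_state` with fields `label` and
#'   `E_gaba` (mV).
#' @export
maturation_state <- function(label = c("immature", "mature")) {
  label <- match.arg(label)
  structure(list(label = label,
                 E_gaba = if (label == "immature") -40 else -70),
            class = "maturation_state")
}

#' Instantaneous state of one neuron
#'
#' @param V membrane potential, mV.
#' @param g_e summed excitatory conductance, nS.
#' @param g_i summed inhibitory conductance, nS.
#' @param refractory_remaining time left in the refractory clamp, ms.
#' @param last_spike time of the most recent spike, s, or `NA`.
#' @return an object of class `neuron_state`.
#' @export
neuron_state <- function(V, g_e = 0, g_i = 0, refractory_remaining = 0,
                         last_spike = NA_real_) {
  stopifnot(g_e >= 0, g_i >= 0, refractory_remaining >= 0)
  structure(list(V = V, g_e = g_e, g_i = g_i,
                 refractory_remaining = refractory_remaining,
                 last_spike = last_spike),
            class = "neuron_state")
}

#' Exponential conductance decay
#'
#' @param g conductance, nS (`>= 0`).
#' @param tau decay time constant, ms (`> 0`).
#' @param dt elapsed time, ms (`>= 0`).
#' @return `g * exp(-dt / tau)`.
#' @export
conductance_decay <- function(g, tau, dt) {
  if (any(tau <= 0)) stop("conductance decay time constant must be > 0")
  if (any(g < 0)) stop("conductance must be >= 0")
  if (any(dt < 0)) stop("dt must be >= 0")
  g * exp(-dt / tau)
}

#' Deliver one presynaptic spike to a neuron
#'
#' Increments the excitatory or inhibitory conductance instantaneously by
#' `weight`; everything else is untouched.
#'
#' @param state a [neuron_state()].
#' @param weight conductance increment, nS (`>= 0`).
#' @param is_inhibitory logical; route the increment to `g_i` instead of `g_e`.
#' @return the updated `neuron_state`.
#' @export
on_presynaptic_spike <- function(state, weight, is_inhibitory = FALSE) {
  if (weight < 0) stop("synaptic weight must be >= 0")
  if (is_inhibitory) state$g_i <- state$g_i + weight
  else state$g_e <- state$g_e + weight
  state
}

#' Advance one neuron by one time step
#'
#' Forward-Euler update of the membrane potential
#' `dV/dt = (E_leak - V)/tau_m + [g_e (E_exc - V) + g_i (E_gaba - V)] / c_m`
#' followed by threshold/reset handling and exact exponential conductance
#' decay.  During the refractory period the membrane is held at `V_reset`
#' and only the timer decrements (conductances keep decaying).
#'
#' This scalar stepper is the reference implementation: the compiled network
#' engine reproduces it operation-for-operation.
#'
#' @param state a [neuron_state()].
#' @param np [neuron_params()].
#' @param sp [synapse_params()].
#' @param ms [maturation_state()].
#' @param dt time step, ms (`> 0`).
#' @param t current time at the start of the step, s (only used to stamp
#'   `last_spike`).
#' @return `list(state = <neuron_state>, spiked = <logical>)`.
#' @export
membrane_step <- function(state, np, sp, ms, dt, t = NA_real_) {
  if (dt <= 0) stop("dt must be > 0")
  vals <- c(state$V, state$g_e, state$g_i, state$refractory_remaining)
  if (!all(is.finite(vals))) {
    stop("non-finite neuron state: V=", state$V, " g_e=", state$g_e,
         " g_i=", state$g_i, " refractory=", state$refractory_remaining)
  }
  spiked <- FALSE
  if (state$refractory_remaining > 0) {
    state$V <- np$V_reset
    state$refractory_remaining <- state$refractory_remaining - dt
    if (state$refractory_remaining < 0) state$refractory_remaining <- 0
  } else {
    dv <- (np$E_leak - state$V) / np$tau_m +
      (state$g_e * (sp$E_exc - state$V) +
         state$g_i * (ms$E_gaba - state$V)) / np$c_m
    state$V <- state$V + dt * dv
    if (state$V >= np$V_threshold) {
      spiked <- TRUE
      state$V <- np$V_reset
      state$refractory_remaining <- np$tau_ref
      state$last_spike <- if (is.na(t)) NA_real_ else t + dt / 1000
    }
  }
  state$g_e <- state$g_e * exp(-dt / sp$tau_exc)
  state$g_i <- state$g_i * exp(-dt / sp$tau_inh)
  list(state = state, spiked = spiked)
}
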