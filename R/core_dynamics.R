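#' Neuron parameters
#'
#' Static coefficients of a leaky integrate-and-fire (LIF) point neuron,
#' optionally with spike-frequency adaptation. All quantities are strict SI
#' (volts, amperes, ohms, farads, siemens, seconds); millivolt/megaohm
#' conversions belong at the reporting boundary, never inside the dynamics.
#'
#' The membrane behaves like an RC circuit relaxing toward the resting
#' potential `Vr` with time constant `tau_m = Rm * Cm`. When the membrane
#' potential reaches `Vthres` the neuron emits a spike, the potential is reset
#' to `Vreset` and held there for the absolute refractory period `tau_r`.
#' Adaptive neurons additionally carry a conductance `g_adapt` that is
#' incremented by `delta_g_adapt` at every spike and decays with time constant
#' `tau_adapt`, producing a hyperpolarizing current that lengthens successive
#' inter-spike intervals.
#'
#' @param Cm Membrane capacitance (farad).
#' @param Rm Membrane resistance (ohm).
#' @param Vr Resting potential (volt).
#' @param Vreset Post-spike reset potential (volt); must be below `Vthres`.
#' @param Vthres Firing threshold (volt).
#' @param tau_r Absolute refractory period (second), `>= 0`.
#' @param polarity `"excitatory"` or `"inhibitory"`; determines the sign of
#'   the current this cell injects into its postsynaptic targets.
#' @param adaptive Logical; enable spike-frequency adaptation.
#' @param tau_adapt Adaptation time constant (second).
#' @param delta_g_adapt Conductance increment per spike (siemens).
#'
#' @return An object of class `lif_neuron_params`.
#' @export
#' @examples
#' p <- neuron_params()
#' p$Rm * p$Cm  # membrane time constant, seconds
neuron_params <- function(Cm = 1e-9,
                          Rm = 1e8,
                          Vr = -0.065,
                          Vreset = -0.065,
                          Vthres = -0.050,
                          tau_r = 0.002,
                          polarity = c("excitatory", "inhibitory"),
                          adaptive = FALSE,
                          tau_adapt = 0.250,
                          delta_g_adapt = 1e-9) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(Cm), Cm > 0,
            is.numeric(Rm), Rm > 0,
            is.numeric(Vreset), is.numeric(Vthres), Vreset < Vthres,
            is.numeric(tau_r), tau_r >= 0,
            is.logical(adaptive), length(adaptive) == 1L,
            is.numeric(delta_g_adapt), delta_g_adapt >= 0)
  if (adaptive && !(is.numeric(tau_adapt) && tau_adapt > 0)) {
    stop("'tau_adapt' must be > 0 for an adaptive neuron")
  }
  structure(list(Cm = Cm, Rm = Rm, Vr = Vr, Vreset = Vreset, Vthres = Vthres,
                 tau_r = tau_r, polarity = polarity, adaptive = adaptive,
                 tau_adapt = tau_adapt, delta_g_adapt = delta_g_adapt),
            class = "lif_neuron_params")
}

#' Neuron dynamic state
#'
#' @param V Membrane potential (volt); defaults to the resting potential.
#' @param g_adapt Adaptive conductance (siemens), `>= 0`.
#' @param refractory_remaining Time left in the refractory hold (second).
#' @param params A [neuron_params()] object supplying the default `V`.
#'
#' @return An object of class `lif_neuron_state`.
#' @export
neuron_state <- function(params = neuron_params(), V = params$Vr,
                         g_adapt = 0, refractory_remaining = 0) {
  stopifnot(g_adapt >= 0, refractory_remaining >= 0)
  structure(list(V = V, g_adapt = g_adapt,
                 refractory_remaining = refractory_remaining,
                 last_fired = FALSE),
            class = "lif_neuron_state")
}

#' Synapse parameters
#'
#' A current-based synapse: each presynaptic spike injects a current transient
#' that jumps by `peak_current` and then decays exponentially with time
#' constant `tau_syn`. The stored magnitude is nonnegative; the sign of the
#' postsynaptic current is inherited from the presynaptic node's polarity.
#' Successive spikes superpose linearly on a single decaying state variable.
#'
#' @param peak_current Current increment per spike (ampere, magnitude).
#' @param tau_syn Synaptic decay time constant (second).
#' @param delay Transmission delay (second); rounded to whole simulation
#'   steps with a floor of one step, so delivery is always at least one step
#'   after the presynaptic fire.
#'
#' @return An object of class `lif_synapse_params`.
#' @export
synapse_params <- function(peak_current = 1e-9, tau_syn = 0.010, delay = 0) {
  stopifnot(is.numeric(peak_current), peak_current >= 0,
            is.numeric(tau_syn), tau_syn > 0,
            is.numeric(delay), delay >= 0)
  structure(list(peak_current = peak_current, tau_syn = tau_syn, delay = delay),
            class = "lif_synapse_params")
}

#' Membrane-voltage clamp policy
#'
#' Current-based synapses place no intrinsic bound on the membrane potential,
#' so by default the simulator limits it to the range -90 to 60 mV — the
#' reversal potentials of K+ and Na+ respectively. The limits can be changed
#' or the clamp disabled.
#'
#' @param enabled Logical; apply the clamp after every integration step.
#' @param v_min,v_max Bounds (volt), `v_min < v_max`.
#'
#' @return An object of class `lif_clamp_policy`.
#' @export
clamp_policy <- function(enabled = TRUE, v_min = -0.090, v_max = 0.060) {
  stopifnot(is.logical(enabled), length(enabled) == 1L, v_min < v_max)
  structure(list(enabled = enabled, v_min = v_min, v_max = v_max),
            class = "lif_clamp_policy")
}

#' Leak current
#'
#' The RC leak driving the membrane back to rest: `-(V - Vr) / Rm`.
#'
#' @param V Membrane potential (volt); vectorized.
#' @param params A [neuron_params()] object.
#' @return Leak current (ampere).
#' @export
leak_current <- function(V, params) {
  -(V - params$Vr) / params$Rm
}

#' Adaptation current magnitude
#'
#' Returns `g_adapt * (V - Vr)`. The caller subtracts this term in the
#' membrane equation, so for a depolarized cell (`V > Vr`) it acts as a
#' hyperpolarizing current that makes firing harder.
#'
#' @param g_adapt Adaptive conductance (siemens), `>= 0`.
#' @param V Membrane potential (volt).
#' @param params A [neuron_params()] object.
#' @return Current (ampere) to be subtracted from the net membrane current.
#' @export
adaptation_current <- function(g_adapt, V, params) {
  g_adapt * (V - params$Vr)
}

#' One Euler step of adaptation-conductance decay
#'
#' `g <- g - g * dt / tau_adapt`; the continuous dynamics is a pure
#' exponential decay with time constant `tau_adapt`.
#'
#' @param g_adapt Conductance (siemens); vectorized.
#' @param dt Time step (second); must satisfy `dt < tau_adapt` for stability.
#' @param params A [neuron_params()] object.
#' @return Decayed conductance (siemens), nonnegative.
#' @export
decay_adaptation <- function(g_adapt, dt, params) {
  if (dt <= 0 || dt >= params$tau_adapt) {
    stop("invalid step: require 0 < dt < tau_adapt")
  }
  g_adapt - g_adapt * dt / params$tau_adapt
}

#' One Euler step of synaptic-current decay
#'
#' `s <- s - s * dt / tau_syn`. Spike arrivals are handled separately by
#' incrementing `s` by the synapse's peak current, so overlapping transients
#' superpose linearly.
#'
#' @param s Synaptic current state (ampere); vectorized.
#' @param dt Time step (second); must satisfy `dt < tau_syn`.
#' @param syn A [synapse_params()] object.
#' @return Decayed current (ampere).
#' @export
decay_synaptic_current <- function(s, dt, syn) {
  if (dt <= 0 || dt >= syn$tau_syn) {
    stop("invalid step: require 0 < dt < tau_syn")
  }
  s - s * dt / syn$tau_syn
}

#' Clamp a membrane voltage
#'
#' @param V Voltage (volt); vectorized.
#' @param clamp A [clamp_policy()] object.
#' @return `V` unchanged when the clamp is disabled, otherwise
#'   `min(max(V, v_min), v_max)` elementwise.
#' @export
clamp_voltage <- function(V, clamp = clamp_policy()) {
  if (!clamp$enabled) return(V)
  pmin(pmax(V, clamp$v_min), clamp$v_max)
}

#' Advance one neuron by one time step
#'
#' Forward-Euler update of the membrane equation
#' `Cm dV/dt = I_leak + I_syn + I_inj - I_adapt`, with threshold/reset/
#' refractory handling. During the refractory period the membrane is pinned
#' at `Vreset` and integration is suspended; the adaptation conductance
#' decays every step regardless. After the Euler update the voltage is
#' clamped per `clamp`, and a spike is emitted if the clamped voltage is at
#' or above threshold: the returned state then has `V = Vreset`,
#' `refractory_remaining = tau_r`, and (for adaptive cells) `g_adapt`
#' incremented by `delta_g_adapt`.
#'
#' The returned `v_recorded` is the post-clamp, pre-reset voltage — the value
#' a voltmeter trace shows for this step.
#'
#' @param state A [neuron_state()] object.
#' @param params A [neuron_params()] object.
#' @param I_syn_total Summed synaptic current (ampere).
#' @param I_inj_total Summed injected current (ampere).
#' @param dt Time step (second).
#' @param clamp A [clamp_policy()] object.
#' @return A list with elements `state` (the new `lif_neuron_state`), `fired`
#'   (logical) and `v_recorded` (volt).
#' @export
#' @examples
#' p <- neuron_params()
#' s <- neuron_state(p)
#' step_neuron(s, p, 0, 0, 1e-4)$fired
step_neuron <- function(state, params, I_syn_total, I_inj_total, dt,
                        clamp = clamp_policy()) {
  stopifnot(dt > 0, is.finite(I_syn_total), is.finite(I_inj_total))
  g <- if (params$adaptive) decay_adaptation(state$g_adapt, dt, params) else 0
  fired <- FALSE
  if (state$refractory_remaining > 0) {
    V <- params$Vreset
    refr <- max(0, state$refractory_remaining - dt)
    v_rec <- params$Vreset
  } else {
    I_leak <- leak_current(state$V, params)
    I_adapt <- adaptation_current(g, state$V, params)
    V <- state$V + dt / params$Cm * (I_leak + I_syn_total + I_inj_total - I_adapt)
    V <- clamp_voltage(V, clamp)
    if (!is.finite(V)) {
      stop("numerical blow-up: membrane potential is not finite; ",
           "check dt and the input currents")
    }
    v_rec <- V
    refr <- 0
    if (V >= params$Vthres) {
      fired <- TRUE
      V <- params$Vreset
      refr <- params$tau_r
      if (params$adaptive) g <- g + params$delta_g_adapt
    }
  }
  out <- state
  out$V <- V
  out$g_adapt <- g
  out$refractory_remaining <- refr
  out$last_fired <- fired
  list(state = out, fired = fired, v_recorded = v_rec)
}

#' Analytic firing rate of a non-adaptive LIF neuron under constant current
#'
#' Closed-form stationary rate `1 / (tau_r + tau_m * log((Vinf - Vreset) /
#' (Vinf - Vthres)))` where `Vinf = Vr + Rm * I` is the asymptotic membrane
#' potential. Returns 0 when `Vinf <= Vthres` (subthreshold drive).
#'
#' @param I_inj Constant injected current (ampere).
#' @param params A [neuron_params()] object (non-adaptive).
#' @return Firing rate (Hz).
#' @export
analytic_firing_rate <- function(I_inj, params = neuron_params()) {
  v_inf <- params$Vr + params$Rm * I_inj
  if (v_inf <= params$Vthres) return(0)
  tau_m <- params$Rm * params$Cm
  1 / (params$tau_r + tau_m * log((v_inf - params$Vreset) /
                                    (v_inf - params$Vthres)))
}
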