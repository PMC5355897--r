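# Reference circuit motifs. All synaptic weights and current levels below
# are implementer-chosen named constants, calibrated once so that each
# motif's documented behavioral contract holds with a comfortable margin at
# the default time step; each contract has a dedicated test.
#
# With the default membrane (Rm = 1e8 ohm, Cm = 1e-9 F, threshold 15 mV
# above rest) and synaptic time constant 10 ms, a synaptic transient of peak
# current I produces a peak depolarization of about I * 7.7e6 V/A:
#   1.0e-9 A -> ~7.7 mV (subthreshold), 3.0e-9 A -> ~23 mV (suprathreshold).

# Touch-like event inputs use a brief, strong transient: ~25 mV peak
# depolarization (suprathreshold) but with a 2 ms synaptic time constant, so
# by the time the refractory hold ends the residual current can no longer
# re-fire the cell — one activation, one spike.
TOUCH_PEAK <- 1.35e-8
TOUCH_TAU <- 0.002
# reliable one-to-one relay between neurons (~23 mV EPSP)
RELAY_PEAK <- 3e-9
# single-input subthreshold convergence weight for the summation motif
SUMMATION_PEAK <- 1e-9
# relay -> output weight in the direction-selective motif: one relay spike
# stays ~2 mV below threshold, two within 0.1 s summate past it
DS_OUTPUT_PEAK <- 1.7e-9
# one-sided lateral inhibition strong enough to veto a relay 0.1 s later
DS_INHIB_PEAK <- 6e-9
# feedback inhibition weight (B -> A)
FB_INHIB_PEAK <- 3e-9
# default DC drive: 25 mV asymptotic depolarization, ~10.7 Hz analytic rate
DC_DRIVE <- 2.5e-10

#' Spike-threshold demonstration circuit
#'
#' One DC source, one neuron and one voltmeter per current level. The
#' neurons use an artificial resting (and reset) potential of 0 mV with the
#' threshold at +15 mV, so the textbook picture — no firing below threshold
#' drive, then monotonically increasing rate with current — reads directly
#' in millivolts from zero. The default levels give asymptotic
#' depolarizations of 10, 20 and 40 mV: one subthreshold, one low-rate, one
#' high-rate.
#'
#' @param current_levels Injected currents (ampere), at least two.
#' @return A `lif_network`. Neuron ids are labeled `"cell_1"`, `"cell_2"`,
#'   ... in the order of `current_levels`.
#' @export
build_threshold_demo <- function(current_levels = c(1e-10, 2e-10, 4e-10)) {
  if (length(current_levels) < 2) {
    stop("need at least two current levels")
  }
  net <- network()
  for (j in seq_along(current_levels)) {
    net <- add_node(net, "dc_source", amplitude = current_levels[j])
    dc <- attr(net, "last_id")
    net <- add_node(net, "neuron", Vr = 0, Vreset = 0, Vthres = 0.015,
                    label = paste0("cell_", j))
    cell <- attr(net, "last_id")
    net <- add_node(net, "voltmeter")
    vm <- attr(net, "last_id")
    net <- connect(net, dc, cell)
    net <- connect(net, cell, vm)
  }
  net
}

#' Synaptic-summation circuit
#'
#' `n_inputs` presynaptic neurons, each driven by its own scheduled event
#' source, converge on a single output neuron. The convergent weights are
#' subthreshold one at a time (~7.7 mV EPSP against a 15 mV gap) so that a
#' single input cannot fire the output, while three near-simultaneous inputs
#' summate past threshold.
#'
#' @param n_inputs Number of converging inputs, `>= 1`.
#' @param activation_time When every event source activates (second).
#' @return A `lif_network`; the output neuron is labeled `"output"`.
#' @export
build_summation <- function(n_inputs, activation_time = 0.1) {
  if (!is.numeric(n_inputs) || n_inputs < 1) {
    stop("need at least one input")
  }
  net <- network()
  net <- add_node(net, "neuron", label = "output")
  out <- attr(net, "last_id")
  for (j in seq_len(n_inputs)) {
    net <- add_node(net, "event_source", activation_times = activation_time)
    ev <- attr(net, "last_id")
    net <- add_node(net, "neuron", label = paste0("input_", j))
    cell <- attr(net, "last_id")
    net <- connect(net, ev, cell,
                   synapse = synapse_params(peak_current = TOUCH_PEAK,
                                            tau_syn = TOUCH_TAU))
    net <- connect(net, cell, out,
                   synapse = synapse_params(peak_current = SUMMATION_PEAK))
  }
  net <- add_node(net, "spike_detector")
  net <- connect(net, out, attr(net, "last_id"))
  net
}

#' Touch-gated inhibition circuit
#'
#' Two scheduled touch inputs drive an excitatory neuron A and an inhibitory
#' neuron B, both of which synapse onto neuron C (with a voltmeter
#' attached). Activating A alone fires C; activating B shortly before A
#' cancels the excitation so C stays below threshold.
#'
#' @param touch_a,touch_b Activation times (second) of the touches driving A
#'   and B; empty vectors mean never.
#' @return A `lif_network` with neurons labeled `"A"`, `"B"`, `"C"`.
#' @export
build_touch_inhibition <- function(touch_a = numeric(), touch_b = numeric()) {
  net <- network()
  net <- add_node(net, "event_source", activation_times = touch_a,
                  label = "touch_A")
  ta <- attr(net, "last_id")
  net <- add_node(net, "event_source", activation_times = touch_b,
                  label = "touch_B")
  tb <- attr(net, "last_id")
  net <- add_node(net, "neuron", label = "A")
  a <- attr(net, "last_id")
  net <- add_node(net, "neuron", polarity = "inhibitory", label = "B")
  b <- attr(net, "last_id")
  net <- add_node(net, "neuron", label = "C")
  cc <- attr(net, "last_id")
  net <- add_node(net, "voltmeter")
  vm <- attr(net, "last_id")
  touch_syn <- synapse_params(peak_current = TOUCH_PEAK, tau_syn = TOUCH_TAU)
  net <- connect(net, ta, a, synapse = touch_syn)
  net <- connect(net, tb, b, synapse = touch_syn)
  net <- connect(net, a, cc, synapse = synapse_params(peak_current = RELAY_PEAK))
  net <- connect(net, b, cc, synapse = synapse_params(peak_current = RELAY_PEAK))
  net <- connect(net, cc, vm)
  net
}

#' Feedback-inhibition (gain control) circuit
#'
#' A DC source drives the neuron labeled `"Input"`, which excites `"A"`,
#' which excites `"Output"`. The output neuron drives the inhibitory neuron
#' `"B"`, which closes the loop by inhibiting A — feedback inhibition that
#' reduces the output rate below the input rate.
#'
#' @param dc_amplitude Constant drive on the input neuron (ampere).
#' @param inhibition Include the B -> A inhibitory edge; set `FALSE` to open
#'   the loop for comparison.
#' @return A `lif_network`.
#' @export
build_feedback_inhibition <- function(dc_amplitude = DC_DRIVE,
                                      inhibition = TRUE) {
  net <- network()
  net <- add_node(net, "dc_source", amplitude = dc_amplitude)
  dc <- attr(net, "last_id")
  net <- add_node(net, "neuron", label = "Input")
  inp <- attr(net, "last_id")
  net <- add_node(net, "neuron", label = "A")
  a <- attr(net, "last_id")
  net <- add_node(net, "neuron", label = "Output")
  out <- attr(net, "last_id")
  net <- add_node(net, "neuron", polarity = "inhibitory", label = "B")
  b <- attr(net, "last_id")
  net <- add_node(net, "spike_detector")
  sd <- attr(net, "last_id")
  net <- connect(net, dc, inp)
  net <- connect(net, inp, a, synapse = synapse_params(peak_current = RELAY_PEAK))
  net <- connect(net, a, out, synapse = synapse_params(peak_current = RELAY_PEAK))
  net <- connect(net, out, b, synapse = synapse_params(peak_current = RELAY_PEAK))
  if (inhibition) {
    net <- connect(net, b, a,
                   synapse = synapse_params(peak_current = FB_INHIB_PEAK))
  }
  net <- connect(net, inp, sd)
  net <- connect(net, out, sd)
  net
}

#' Direction-selective feedforward circuit
#'
#' A linear array of `n_columns` columns, each with a scheduled touch input,
#' an input neuron, a relay neuron and an inhibitory neuron. The input
#' neuron of column i excites both its relay and its inhibitory neuron; the
#' inhibitory neuron provides one-sided lateral inhibition onto the relay of
#' column i+1 (its right-hand neighbor). All relays converge on a single
#' output neuron with weights that need at least two relay spikes within the
#' sweep interval to fire.
#'
#' Sweeping the touches right-to-left means each inhibitory volley lands on
#' a relay that has already fired — the inhibition arrives too late — so the
#' relays and the output fire. Sweeping left-to-right, every relay beyond
#' the first is inhibited just before its excitation arrives, only one relay
#' spike reaches the output, and the output stays silent.
#'
#' @param n_columns Number of columns, `>= 2`.
#' @param sweep `"right_to_left"` (preferred direction) or
#'   `"left_to_right"` (null direction).
#' @param inter_touch_interval Time between successive touches (second).
#' @param t_start Time of the first touch (second).
#' @return A `lif_network`; the output neuron is labeled `"output"`.
#' @export
build_direction_selective <- function(n_columns = 4,
                                      sweep = c("right_to_left",
                                                "left_to_right"),
                                      inter_touch_interval = 0.1,
                                      t_start = 0.05) {
  sweep <- match.arg(sweep)
  if (!is.numeric(n_columns) || n_columns < 2) {
    stop("need at least two columns")
  }
  n_columns <- as.integer(n_columns)
  order <- if (sweep == "left_to_right") seq_len(n_columns)
           else rev(seq_len(n_columns))
  touch_time <- numeric(n_columns)
  touch_time[order] <- t_start + (seq_len(n_columns) - 1) * inter_touch_interval

  net <- network()
  net <- add_node(net, "neuron", label = "output")
  out <- attr(net, "last_id")
  input <- relay <- inhib <- character(n_columns)
  for (j in seq_len(n_columns)) {
    net <- add_node(net, "event_source", activation_times = touch_time[j],
                    label = paste0("touch_", j))
    ev <- attr(net, "last_id")
    net <- add_node(net, "neuron", label = paste0("input_", j))
    input[j] <- attr(net, "last_id")
    net <- add_node(net, "neuron", label = paste0("relay_", j))
    relay[j] <- attr(net, "last_id")
    net <- add_node(net, "neuron", polarity = "inhibitory",
                    label = paste0("inhib_", j))
    inhib[j] <- attr(net, "last_id")
    net <- connect(net, ev, input[j],
                   synapse = synapse_params(peak_current = TOUCH_PEAK,
                                            tau_syn = TOUCH_TAU))
    net <- connect(net, input[j], relay[j],
                   synapse = synapse_params(peak_current = RELAY_PEAK))
    net <- connect(net, input[j], inhib[j],
                   synapse = synapse_params(peak_current = RELAY_PEAK))
    net <- connect(net, relay[j], out,
                   synapse = synapse_params(peak_current = DS_OUTPUT_PEAK))
  }
  for (j in seq_len(n_columns - 1)) {
    net <- connect(net, inhib[j], relay[j + 1],
                   synapse = synapse_params(peak_current = DS_INHIB_PEAK))
  }
  net
}

#' Direction-selectivity index
#'
#' `(preferred - null) / (preferred + null)` of the output spike counts; 1
#' means complete suppression in the null direction.
#'
#' @param preferred,null Output spike counts in the two sweep directions.
#' @return The index in `[-1, 1]`, or `NA` if both counts are zero.
#' @export
direction_selectivity_index <- function(preferred, null) {
  if (preferred + null == 0) return(NA_real_)
  (preferred - null) / (preferred + null)
}
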