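#' Current-source parameters
#'
#' @param amplitude Peak current (ampere). For a DC source this is the
#'   constant injected current; for an AC source the sine amplitude.
#' @param frequency Oscillation frequency (Hz); 0 for DC.
#' @return An object of class `lif_current_source_params`.
#' @export
current_source_params <- function(amplitude = 2.5e-10, frequency = 0) {
  stopifnot(is.numeric(amplitude), is.numeric(frequency), frequency >= 0)
  structure(list(amplitude = amplitude, frequency = frequency),
            class = "lif_current_source_params")
}

#' Spike-generator parameters
#'
#' Shared by the regular (metronome-like) and irregular (Poisson) spike
#' generators. `time_since_fire` is the regular generator's state variable.
#'
#' @param rate Firing rate (Hz), `>= 0`. Zero is legal and silent.
#' @param polarity `"excitatory"` or `"inhibitory"`; output spikes inherit
#'   this sign at the postsynaptic current.
#' @param time_since_fire Elapsed time since the last fire (second).
#' @return An object of class `lif_generator_params`.
#' @export
generator_params <- function(rate = 10, polarity = c("excitatory", "inhibitory"),
                             time_since_fire = 0) {
  polarity <- match.arg(polarity)
  stopifnot(is.numeric(rate), rate >= 0, time_since_fire >= 0)
  structure(list(rate = rate, polarity = polarity,
                 time_since_fire = time_since_fire),
            class = "lif_generator_params")
}

#' Scheduled activation times (touch stand-in)
#'
#' A headless replacement for interactive touch input: a pre-declared sorted
#' list of activation times. Each activation makes the source node fire once;
#' the effect reaches connected neurons through ordinary current-based
#' synapses.
#'
#' @param activation_times Strictly increasing activation times (second).
#' @return An object of class `lif_event_schedule`.
#' @export
event_schedule <- function(activation_times = numeric()) {
  activation_times <- as.numeric(activation_times)
  if (length(activation_times) > 1 && any(diff(activation_times) <= 0)) {
    stop("'activation_times' must be strictly increasing")
  }
  if (any(activation_times < 0)) stop("'activation_times' must be >= 0")
  structure(list(activation_times = activation_times),
            class = "lif_event_schedule")
}

#' DC current at time t
#'
#' @param params A [current_source_params()] object.
#' @param t Time (second); the DC source is time-invariant.
#' @return Current (ampere).
#' @export
dc_current <- function(params, t) {
  rep_len(params$amplitude, length(t))
}

#' AC (sine-wave) current at time t
#'
#' `amplitude * sin(2 * pi * frequency * t)`; phase is fixed at zero and
#' there is no DC offset.
#'
#' @param params A [current_source_params()] object with `frequency > 0`.
#' @param t Time (second); vectorized.
#' @return Current (ampere).
#' @export
ac_current <- function(params, t) {
  stopifnot(params$frequency > 0)
  params$amplitude * sin(2 * pi * params$frequency * t)
}

#' One step of the regular spike generator
#'
#' Accumulates elapsed time and fires whenever it exceeds the period
#' `1 / rate`, then resets the accumulator to zero. A rate of zero never
#' fires. The fires are delivered to connected neurons through current-based
#' synapses exactly like neuron spikes.
#'
#' @param state A [generator_params()] object (carries `time_since_fire`).
#' @param dt Time step (second).
#' @return A list with `state` (updated) and `fired` (logical).
#' @export
regular_generator_step <- function(state, dt) {
  stopifnot(dt > 0)
  period <- if (state$rate > 0) 1 / state$rate else Inf
  tsf <- state$time_since_fire + dt
  fired <- tsf > period
  if (fired) tsf <- 0
  state$time_since_fire <- tsf
  list(state = state, fired = fired)
}

#' One step of the Poisson (irregular) spike generator
#'
#' A homogeneous Poisson process approximated per step: on every step there
#' is a constant probability `rate * dt` of emitting a spike, independent of
#' history. The approximation bias is O(rate * dt); a warning is issued above
#' `rate * dt = 0.1` and values above 1 are a configuration error.
#'
#' @param params A [generator_params()] object.
#' @param dt Time step (second).
#' @return Logical: did the generator fire this step? Consumes one uniform
#'   draw from the R random stream.
#' @export
poisson_generator_step <- function(params, dt) {
  p <- params$rate * dt
  if (p > 1) stop("rate * dt > 1: not a probability; reduce dt or rate")
  if (p > 0.1) warning("rate * dt > 0.1: per-step Bernoulli approximation is biased")
  stats::runif(1) < p
}

#' Simulate a full Poisson spike train
#'
#' Vectorized equivalent of calling [poisson_generator_step()] on every step
#' of a run: draws `ceiling(duration / dt)` independent Bernoulli variables
#' with probability `rate * dt` from the current R random stream and returns
#' the spike times (the end-of-step times of the successful draws).
#'
#' @param rate Rate (Hz).
#' @param duration Run length (second).
#' @param dt Time step (second).
#' @return Numeric vector of spike times (second).
#' @export
simulate_poisson_train <- function(rate, duration, dt) {
  p <- rate * dt
  if (p > 1) stop("rate * dt > 1: not a probability; reduce dt or rate")
  n <- ceiling(duration / dt)
  which(stats::runif(n) < p) * dt
}

#' One step of a scheduled event source
#'
#' Fires if and only if some activation time falls in the half-open bin
#' `(t - dt, t]`. Multiple activations inside one bin coalesce into a single
#' fire.
#'
#' @param schedule An [event_schedule()] object.
#' @param t End-of-step time (second).
#' @param dt Time step (second).
#' @return Logical.
#' @export
event_source_step <- function(schedule, t, dt) {
  any(schedule$activation_times > t - dt & schedule$activation_times <= t)
}
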