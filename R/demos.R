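# Behavioral experiments: each demo builds a reference motif, runs it, and
# checks the circuit-level contract it illustrates. They are the executable
# form of the package's behavioral guarantees; `cli_main("demo", ...)`
# exposes them from the shell.

spike_count <- function(rec, id) length(rec$spikes[[id]])

demo_registry <- function() {
  c("fig2", "fig6", "fig7", "fig8", "fig9")
}

#' Run a behavioral demo experiment
#'
#' Builds one of the reference circuits, simulates it and evaluates its
#' behavioral assertions:
#' \describe{
#'   \item{`"fig2"`}{touch-gated inhibition: touching A alone fires C;
#'     touching B shortly before A keeps C below threshold.}
#'   \item{`"fig6"`}{spike threshold: three current levels produce spike
#'     counts (0, n1 > 0, n2 > n1) over 2 s.}
#'   \item{`"fig7"`}{synaptic summation: one simultaneous input cannot fire
#'     the output, three can.}
#'   \item{`"fig8"`}{feedback inhibition: the output rate is strictly below
#'     the input rate, and opening the inhibitory loop raises it.}
#'   \item{`"fig9"`}{direction selectivity: a right-to-left touch sweep
#'     fires the output, a left-to-right sweep leaves it silent.}
#' }
#'
#' @param figure One of `"fig2"`, `"fig6"`, `"fig7"`, `"fig8"`, `"fig9"`.
#' @param seed Simulation seed.
#' @param dt Time step (second).
#' @return A list with `pass` (all assertions hold), `checks` (named logical
#'   vector) and `values` (the measured quantities).
#' @export
run_demo <- function(figure, seed = 1L, dt = 1e-4) {
  figure <- match.arg(figure, demo_registry())
  switch(figure,
    fig2 = demo_touch_inhibition(seed, dt),
    fig6 = demo_threshold(seed, dt),
    fig7 = demo_summation(seed, dt),
    fig8 = demo_feedback_inhibition(seed, dt),
    fig9 = demo_direction_selectivity(seed, dt)
  )
}

demo_result <- function(checks, values) {
  list(pass = all(unlist(checks)), checks = unlist(checks), values = values)
}

demo_touch_inhibition <- function(seed, dt) {
  cfg <- sim_config(duration = 0.6, dt = dt, seed = seed)
  alone <- run_network(build_touch_inhibition(touch_a = 0.1), cfg)
  gated <- run_network(build_touch_inhibition(touch_a = 0.12, touch_b = 0.1),
                       cfg)
  c_alone <- spike_count(alone, node_by_label_rec(alone, "C"))
  c_gated <- spike_count(gated, node_by_label_rec(gated, "C"))
  demo_result(
    list(fires_when_a_alone = c_alone >= 1,
         silent_when_b_precedes_a = c_gated == 0),
    list(spikes_a_alone = c_alone, spikes_b_then_a = c_gated)
  )
}

demo_threshold <- function(seed, dt) {
  net <- build_threshold_demo()
  rec <- run_network(net, sim_config(duration = 2, dt = dt, seed = seed))
  counts <- vapply(paste0("cell_", 1:3),
                   function(lb) spike_count(rec, node_by_label_rec(rec, lb)),
                   numeric(1))
  demo_result(
    list(subthreshold_silent = counts[1] == 0,
         low_drive_fires = counts[2] > 0,
         rate_increases_with_current = counts[3] > counts[2]),
    list(spike_counts = counts)
  )
}

demo_summation <- function(seed, dt) {
  cfg <- sim_config(duration = 0.6, dt = dt, seed = seed)
  one <- run_network(build_summation(1), cfg)
  three <- run_network(build_summation(3), cfg)
  n1 <- spike_count(one, node_by_label_rec(one, "output"))
  n3 <- spike_count(three, node_by_label_rec(three, "output"))
  demo_result(
    list(single_input_subthreshold = n1 == 0,
         three_inputs_fire = n3 >= 1),
    list(output_spikes_1_input = n1, output_spikes_3_inputs = n3)
  )
}

demo_feedback_inhibition <- function(seed, dt) {
  cfg <- sim_config(duration = 2, dt = dt, seed = seed)
  closed <- run_network(build_feedback_inhibition(), cfg)
  open <- run_network(build_feedback_inhibition(inhibition = FALSE), cfg)
  n_in <- spike_count(closed, node_by_label_rec(closed, "Input"))
  n_out <- spike_count(closed, node_by_label_rec(closed, "Output"))
  n_out_open <- spike_count(open, node_by_label_rec(open, "Output"))
  demo_result(
    list(output_below_input = n_out < n_in,
         opening_loop_raises_output = n_out_open > n_out),
    list(input_spikes = n_in, output_spikes = n_out,
         output_spikes_no_inhibition = n_out_open,
         input_rate_hz = n_in / 2, output_rate_hz = n_out / 2)
  )
}

demo_direction_selectivity <- function(seed, dt) {
  dur <- 0.05 + 3 * 0.1 + 0.5
  cfg <- sim_config(duration = dur, dt = dt, seed = seed)
  pref <- run_network(build_direction_selective(sweep = "right_to_left"), cfg)
  null <- run_network(build_direction_selective(sweep = "left_to_right"), cfg)
  n_pref <- spike_count(pref, node_by_label_rec(pref, "output"))
  n_null <- spike_count(null, node_by_label_rec(null, "output"))
  demo_result(
    list(preferred_direction_fires = n_pref >= 1,
         null_direction_silent = n_null == 0),
    list(preferred_spikes = n_pref, null_spikes = n_null,
         selectivity_index = direction_selectivity_index(n_pref, n_null))
  )
}

# Recording-side label lookup (recordings carry labels, not the network).
node_by_label_rec <- function(rec, label) {
  hit <- names(rec$labels)[!is.na(rec$labels) & rec$labels == label]
  if (!length(hit)) stop("no node labeled '", label, "' in recording")
  hit[1]
}
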