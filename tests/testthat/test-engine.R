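test_that("empty and resting networks are exact no-ops", {
  rec <- run_network(network(), sim_config(duration = 0.01))
  expect_equal(length(rec$times), 101)
  expect_equal(ncol(rec$voltages), 0)

  net <- add_node(network(), "neuron")
  rec <- run_network(net, sim_config(duration = 0.01))
  p <- neuron_params()
  expect_true(all(rec$voltages[, "n1"] == p$Vr))
  expect_length(rec$spikes[["n1"]], 0)
})

test_that("graph construction rejects duplicate labels, bad endpoints and sensor sources", {
  net <- add_node(network(), "neuron", label = "A")
  expect_error(add_node(net, "neuron", label = "A"), "duplicate label")
  expect_error(add_node(net, "not_a_kind"), "unknown node kind")
  expect_error(connect(net, "n1", "missing"), "unknown node id")
  net <- add_node(net, "voltmeter")
  expect_error(connect(net, "n2", "n1"), "sensors cannot be edge sources")
  net <- add_node(net, "dc_source")
  expect_error(connect(net, "n1", "n3"), "targets must be neurons or sensors")
  expect_error(connect(net, "n1", "n1"), "self-loop")
  expect_silent(connect(net, "n1", "n1", allow_self_loop = TRUE))
})

test_that("voltage traces have n_steps + 1 samples on the shared grid from t = 0", {
  net <- add_node(network(), "neuron")
  rec <- run_network(net, sim_config(duration = 10 * 1e-4))
  expect_equal(length(rec$times), 11)
  expect_equal(nrow(rec$voltages), 11)
  expect_identical(rec$times[1], 0)
})

test_that("a DC source injects current without ever entering the spike queue", {
  net <- dc_neuron_net(2.5e-10)
  rec <- run_network(net, sim_config(duration = 1))
  expect_gt(length(rec$spikes[["n2"]]), 0)
  expect_false("n1" %in% names(rec$spikes))  # current sources never spike
})

test_that("fires are delivered in the next step and delays shift onset by whole steps", {
  onset_step <- function(delay) {
    net <- event_neuron_net(0.01, synapse_params(1e-10, delay = delay))
    rec <- run_network(net, sim_config(duration = 0.05))
    which(rec$voltages[, "n2"] > neuron_params()$Vr + 1e-12)[1] - 1L
  }
  fire_step <- 100L  # activation at 0.01 s with dt = 1e-4
  expect_identical(onset_step(0), fire_step + 1L)       # minimum one-step latency
  for (k in c(3L, 7L)) {
    expect_identical(onset_step(k * 1e-4), fire_step + k)
  }
})

test_that("identical network and seed reproduce the recording bit-identically", {
  net <- add_node(network(), "poisson_generator", rate = 200)
  net <- add_node(net, "neuron")
  net <- connect(net, "n1", "n2", synapse_params(5e-10))
  cfg <- sim_config(duration = 0.5, seed = 42)
  r1 <- run_network(net, cfg)
  r2 <- run_network(net, cfg)
  expect_identical(r1, r2)
  r3 <- run_network(net, sim_config(duration = 0.5, seed = 43))
  expect_false(identical(r1$spikes, r3$spikes))
})

test_that("subthreshold deflections from two stimulators superpose linearly", {
  base <- function(times1 = numeric(), times2 = numeric()) {
    net <- network()
    net <- add_node(net, "event_source", activation_times = times1)
    net <- add_node(net, "event_source", activation_times = times2,
                    polarity = "inhibitory")
    net <- add_node(net, "neuron")
    net <- connect(net, "n1", "n3", synapse_params(3e-10))
    net <- connect(net, "n2", "n3", synapse_params(5e-10))
    rec <- run_network(net, sim_config(duration = 0.3,
                                       clamp = clamp_policy(enabled = FALSE)))
    rec$voltages[, "n3"] - neuron_params()$Vr
  }
  both <- base(0.02, 0.05)
  sum_of_parts <- base(times1 = 0.02) + base(times2 = 0.05)
  expect_equal(both, sum_of_parts, tolerance = 1e-12)
})

test_that("nodes with no path to a recorded node never affect its trace", {
  build <- function(extra) {
    net <- dc_neuron_net(2.0e-10)
    if (extra) {
      net <- add_node(net, "regular_generator", rate = 50)
      net <- add_node(net, "neuron")
      net <- connect(net, "n3", "n4", synapse_params(2e-9))
    }
    run_network(net, sim_config(duration = 0.5))
  }
  expect_identical(build(FALSE)$voltages[, "n2"],
                   build(TRUE)$voltages[, "n2"])
})

test_that("spike count under constant drive matches the closed-form prediction", {
  p <- neuron_params()
  I <- 2.5e-10
  tau_m <- p$Rm * p$Cm
  v_inf <- p$Vr + p$Rm * I
  t_first <- tau_m * log((v_inf - p$Vr) / (v_inf - p$Vthres))
  period <- 1 / analytic_firing_rate(I, p)
  predicted <- 1 + floor((2 - t_first) / period)
  rec <- run_network(dc_neuron_net(I), sim_config(duration = 2))
  expect_lte(abs(length(rec$spikes[["n2"]]) - predicted), 1)
})

test_that("every inter-spike interval respects the refractory floor", {
  net <- dc_neuron_net(1e-9, tau_r = 0.005)  # strong drive
  cfg <- sim_config(duration = 1)
  rec <- run_network(net, cfg)
  isi <- diff(rec$spikes[["n2"]])
  expect_gt(length(isi), 10)
  expect_true(all(isi >= 0.005 + cfg$dt - 1e-12))
})

test_that("clamped recordings never leave the clamp interval", {
  net <- add_node(network(), "ac_source", amplitude = 1e-5, frequency = 3)
  net <- add_node(net, "neuron")
  net <- connect(net, "n1", "n2")
  rec <- run_network(net, sim_config(duration = 1))
  expect_true(all(rec$voltages >= -0.090 & rec$voltages <= 0.060))
})

test_that("an unconnected sensor warns but does not abort the run", {
  net <- add_node(network(), "neuron")
  net <- add_node(net, "voltmeter")
  expect_warning(run_network(net, sim_config(duration = 0.01)),
                 "not connected")
})
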