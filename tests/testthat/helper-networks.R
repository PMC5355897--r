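# Small fixture networks built in code.

# One DC source driving one neuron; returns the network (neuron id "n2").
dc_neuron_net <- function(amplitude = 2.5e-10, ...) {
  net <- network()
  net <- add_node(net, "dc_source", amplitude = amplitude)
  net <- add_node(net, "neuron", ...)
  connect(net, "n1", "n2")
}

# One event source kicking one neuron through a synapse ("n2" is the neuron).
event_neuron_net <- function(times, synapse = synapse_params(),
                             polarity = "excitatory", ...) {
  net <- network()
  net <- add_node(net, "event_source", activation_times = times,
                  polarity = polarity)
  net <- add_node(net, "neuron", ...)
  connect(net, "n1", "n2", synapse = synapse)
}

# A network exercising every node kind, for serialization tests.
all_kinds_net <- function() {
  net <- network()
  net <- add_node(net, "neuron", label = "cell", Rm = 2e8, adaptive = TRUE)
  net <- add_node(net, "neuron")
  net <- add_node(net, "dc_source", amplitude = 1e-10)
  net <- add_node(net, "ac_source", amplitude = 2e-10, frequency = 5)
  net <- add_node(net, "regular_generator", rate = 7)
  net <- add_node(net, "poisson_generator", rate = 20,
                  polarity = "inhibitory")
  net <- add_node(net, "event_source", activation_times = c(0.1, 0.25))
  net <- add_node(net, "visual_input",
                  kernel = make_dog_kernel(8, 8, 1, 2),
                  stimulus = matrix(runif(64), 8, 8), gain = 50)
  net <- add_node(net, "voltmeter")
  net <- add_node(net, "spike_detector", window = 0.5)
  net <- add_node(net, "firing_rate_meter", sigma_w = 0.2)
  net <- connect(net, "n3", "n1")
  net <- connect(net, "n4", "n1")
  net <- connect(net, "n5", "n1", synapse_params(5e-10, 0.02, 0.003))
  net <- connect(net, "n6", "n1", synapse_params(4e-10))
  net <- connect(net, "n7", "n2", synapse_params(2e-9))
  net <- connect(net, "n8", "n2")
  net <- connect(net, "n1", "n2", synapse_params(1e-9, delay = 0.001))
  net <- connect(net, "n1", "n9")
  net <- connect(net, "n1", "n10")
  net <- connect(net, "n1", "n11")
  net <- connect(net, "n2", "n11")
  net
}

expect_spike_count <- function(rec, id, expected) {
  expect_equal(length(rec$spikes[[id]]), expected)
}
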