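# Node-kind registry. Each kind maps to its default parameter list; add_node
# validates user parameters against these names and fills the rest.

NODE_KINDS <- c("neuron", "dc_source", "ac_source", "regular_generator",
                "poisson_generator", "event_source", "visual_input",
                "voltmeter", "spike_detector", "firing_rate_meter")

STIMULATOR_KINDS <- c("dc_source", "ac_source", "regular_generator",
                      "poisson_generator", "event_source", "visual_input")
SENSOR_KINDS <- c("voltmeter", "spike_detector", "firing_rate_meter")
# Nodes whose fires travel through synapse edges (as opposed to the direct
# current injection of dc/ac sources).
SPIKING_KINDS <- c("neuron", "regular_generator", "poisson_generator",
                   "event_source", "visual_input")
CURRENT_SOURCE_KINDS <- c("dc_source", "ac_source")

node_defaults <- function(kind) {
  switch(kind,
    neuron = unclass(neuron_params()),
    dc_source = list(amplitude = 2.5e-10),
    ac_source = list(amplitude = 2.5e-10, frequency = 10),
    regular_generator = list(rate = 10, polarity = "excitatory"),
    poisson_generator = list(rate = 10, polarity = "excitatory"),
    event_source = list(activation_times = numeric(),
                        polarity = "excitatory"),
    visual_input = list(kernel = NULL, stimulus = NULL, gain = 100,
                        polarity = "excitatory", frame_interval = Inf),
    voltmeter = list(),
    spike_detector = list(window = Inf),
    firing_rate_meter = list(sigma_w = 0.1, rate_min = 0, rate_max = 100),
    stop("unknown node kind: '", kind, "'")
  )
}

node_polarity_sign <- function(spec) {
  pol <- spec$params$polarity
  if (is.null(pol) || identical(pol, "excitatory")) 1 else -1
}

#' Create an empty network
#'
#' A network is a directed multigraph of typed nodes — neurons, stimulators
#' and sensors — connected by edges. Edges between spiking nodes and neurons
#' are current-based synapses; edges from DC/AC sources attach injected
#' currents; edges from neurons into sensors attach recordings.
#'
#' @return An object of class `lif_network`.
#' @export
#' @examples
#' net <- network()
#' net <- add_node(net, "neuron", label = "A")
#' net <- add_node(net, "dc_source", amplitude = 2.5e-10)
#' net <- connect(net, "n2", "n1")
network <- function() {
  structure(list(nodes = list(), edges = list(), workspace = list(),
                 counter = 0L),
            class = "lif_network")
}

#' Add a node to a network
#'
#' @param net A [network()].
#' @param kind One of `"neuron"`, `"dc_source"`, `"ac_source"`,
#'   `"regular_generator"`, `"poisson_generator"`, `"event_source"`,
#'   `"visual_input"`, `"voltmeter"`, `"spike_detector"`,
#'   `"firing_rate_meter"`.
#' @param ... Kind-specific parameters overriding the defaults (for a neuron,
#'   the fields of [neuron_params()]; for generators `rate` and `polarity`;
#'   for an event source `activation_times`; for a visual input `kernel`,
#'   `stimulus`, `gain`; for a rate meter `sigma_w`, `rate_min`, `rate_max`).
#' @param label Optional human-readable label, unique across the network.
#' @param id Optional node id; autogenerated (`"n1"`, `"n2"`, ...) if omitted.
#' @return The network with the node added. The assigned id is also attached
#'   as `attr(net, "last_id")`.
#' @export
add_node <- function(net, kind, ..., label = NULL, id = NULL) {
  stopifnot(inherits(net, "lif_network"))
  if (!kind %in% NODE_KINDS) stop("unknown node kind: '", kind, "'")
  params <- node_defaults(kind)
  override <- list(...)
  if (length(override)) {
    nm <- names(override)
    if (is.null(nm) || any(nm == "")) stop("node parameters must be named")
    bad <- setdiff(nm, names(params))
    if (length(bad)) {
      stop("unknown parameter(s) for kind '", kind, "': ",
           paste(bad, collapse = ", "))
    }
    params[nm] <- override
  }
  if (kind == "neuron") {
    params <- unclass(do.call(neuron_params, params))
  }
  if (!is.null(label)) {
    labels <- vapply(net$nodes, function(n) n$label %||% NA_character_,
                     character(1))
    if (label %in% labels) stop("duplicate label: '", label, "'")
  }
  net$counter <- net$counter + 1L
  if (is.null(id)) id <- paste0("n", net$counter)
  if (id %in% names(net$nodes)) stop("duplicate node id: '", id, "'")
  net$nodes[[id]] <- list(id = id, kind = kind, label = label,
                          params = params)
  attr(net, "last_id") <- id
  net
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Connect two nodes
#'
#' Connecting a neuron or spike generator to a neuron creates a current-based
#' synapse. Connecting a DC/AC source to a neuron attaches its current to the
#' neuron's injected-current sum. Connecting a neuron to a sensor attaches a
#' recording. Sensors can never be sources, and only
#' stimulator-to-neuron, neuron-to-neuron and neuron-to-sensor edges are
#' allowed.
#'
#' @param net A [network()].
#' @param src,dst Node ids.
#' @param synapse A [synapse_params()] object; used only for synapse edges
#'   (ignored for current-source and sensor attachments). The synapse's
#'   stored current is a magnitude — the sign of the postsynaptic current is
#'   inherited from the source node's polarity.
#' @param allow_self_loop Permit a neuron to synapse onto itself.
#' @return The network with the edge appended.
#' @export
connect <- function(net, src, dst, synapse = synapse_params(),
                    allow_self_loop = FALSE) {
  stopifnot(inherits(net, "lif_network"))
  for (endpoint in c(src, dst)) {
    if (!endpoint %in% names(net$nodes)) {
      stop("unknown node id: '", endpoint, "'")
    }
  }
  src_kind <- net$nodes[[src]]$kind
  dst_kind <- net$nodes[[dst]]$kind
  if (src_kind %in% SENSOR_KINDS) {
    stop("sensors cannot be edge sources: '", src, "' is a ", src_kind)
  }
  if (dst_kind %in% SENSOR_KINDS) {
    if (src_kind != "neuron") {
      stop("only neurons can be connected to sensors; '", src,
           "' is a ", src_kind)
    }
    edge <- list(source = src, target = dst, synapse = NULL)
  } else if (dst_kind == "neuron") {
    if (src == dst && !allow_self_loop) {
      stop("self-loop synapse on '", src,
           "' (set allow_self_loop = TRUE to permit)")
    }
    syn <- if (src_kind %in% CURRENT_SOURCE_KINDS) NULL else {
      stopifnot(inherits(synapse, "lif_synapse_params"))
      unclass(synapse)
    }
    edge <- list(source = src, target = dst, synapse = syn)
  } else {
    stop("cannot connect ", src_kind, " to ", dst_kind,
         ": targets must be neurons or sensors")
  }
  net$edges[[length(net$edges) + 1L]] <- edge
  net
}

#' Node ids of a network
#' @param net A [network()].
#' @return Character vector of node ids in insertion order.
#' @export
node_ids <- function(net) names(net$nodes)

#' Look up a node id by label
#' @param net A [network()].
#' @param label A node label.
#' @return The matching node id.
#' @export
node_by_label <- function(net, label) {
  for (n in net$nodes) if (identical(n$label, label)) return(n$id)
  stop("no node labeled '", label, "'")
}

#' Validate a network's structural invariants
#'
#' Checks that every edge endpoint exists, sensor/stimulator pairing rules
#' hold, and labels are unique. Construction via [add_node()]/[connect()]
#' enforces these already; this is the entry point used when loading
#' documents from disk.
#'
#' @param net A [network()].
#' @return Invisibly `TRUE`; errors on violation.
#' @export
validate_network <- function(net) {
  stopifnot(inherits(net, "lif_network"))
  labels <- unlist(lapply(net$nodes, function(n) n$label))
  if (anyDuplicated(labels)) {
    stop("duplicate label: '", labels[duplicated(labels)][1], "'")
  }
  for (e in net$edges) {
    for (endpoint in c(e$source, e$target)) {
      if (!endpoint %in% names(net$nodes)) {
        stop("edge references missing node id: '", endpoint, "'")
      }
    }
    src_kind <- net$nodes[[e$source]]$kind
    dst_kind <- net$nodes[[e$target]]$kind
    if (src_kind %in% SENSOR_KINDS) {
      stop("sensors cannot be edge sources: '", e$source, "'")
    }
    if (!(dst_kind == "neuron" ||
            (dst_kind %in% SENSOR_KINDS && src_kind == "neuron"))) {
      stop("disallowed edge ", e$source, " -> ", e$target,
           " (", src_kind, " -> ", dst_kind, ")")
    }
  }
  invisible(TRUE)
}

#' @export
print.lif_network <- function(x, ...) {
  kinds <- vapply(x$nodes, `[[`, character(1), "kind")
  cat("<lif_network> ", length(x$nodes), " nodes, ", length(x$edges),
      " edges\n", sep = "")
  if (length(kinds)) {
    tab <- table(kinds)
    cat("  ", paste(names(tab), tab, sep = ": ", collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Simulation configuration
#'
#' @param duration Total simulated time (second).
#' @param dt Integration time step (second); default 1e-4 s.
#' @param seed Integer seed controlling every stochastic draw of the run.
#' @param clamp A [clamp_policy()] applied to every neuron after each
#'   integration step.
#' @param record `"all"` (record every neuron's voltage and every spiking
#'   node's spike train) or a character vector of node ids to restrict the
#'   returned traces to.
#' @return An object of class `lif_sim_config`.
#' @export
sim_config <- function(duration, dt = 1e-4, seed = 1L,
                       clamp = clamp_policy(), record = "all") {
  stopifnot(is.numeric(dt), dt > 0, is.numeric(duration), duration >= dt,
            inherits(clamp, "lif_clamp_policy"))
  structure(list(duration = duration, dt = dt, seed = as.integer(seed),
                 clamp = clamp, record = record),
            class = "lif_sim_config")
}
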