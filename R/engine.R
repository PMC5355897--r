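# Graph engine: compiles a network into flat vectors and advances it with a
# fixed time step. Within every step the order of operations is fixed:
#   (1) deliver due spike events as synaptic-current increments
#   (2) decay all edge currents
#   (3) evaluate stimulators at the step's start time
#   (4) integrate all neurons with the summed synaptic + injected currents
#   (5) enqueue new fires with a per-edge delivery offset of
#       max(1, round(delay / dt)) steps
#   (6) update sensors / recordings
# A fire can therefore never influence a target at or before its own step:
# every edge has at least one step of latency.

compile_network <- function(net, cfg) {
  validate_network(net)
  ids <- names(net$nodes)
  kinds <- vapply(net$nodes, `[[`, character(1), "kind")
  idx_of <- stats::setNames(seq_along(ids), ids)
  dt <- cfg$dt
  n_steps <- ceiling(cfg$duration / dt)

  neuron_idx <- which(kinds == "neuron")
  np <- lapply(net$nodes[neuron_idx], `[[`, "params")
  num <- function(field) vapply(np, function(p) as.numeric(p[[field]]),
                                numeric(1))
  neurons <- list(
    node_idx = neuron_idx,
    Cm = num("Cm"), Rm = num("Rm"), Vr = num("Vr"), Vreset = num("Vreset"),
    Vthres = num("Vthres"), tau_r = num("tau_r"),
    adaptive = vapply(np, function(p) isTRUE(p$adaptive), logical(1)),
    tau_adapt = num("tau_adapt"), dga = num("delta_g_adapt")
  )
  neurons$dga[!neurons$adaptive] <- 0
  # pure decay factor; non-adaptive cells keep g = 0 regardless
  neurons$g_decay <- ifelse(neurons$adaptive, 1 - dt / neurons$tau_adapt, 1)
  if (any(neurons$adaptive & dt >= neurons$tau_adapt)) {
    stop("invalid step: dt must be smaller than every tau_adapt")
  }
  neuron_pos <- integer(length(ids))          # node idx -> position in vectors
  neuron_pos[neuron_idx] <- seq_along(neuron_idx)

  syn_src <- integer(0); syn_tgt_pos <- integer(0)
  syn_peak <- numeric(0); syn_tau <- numeric(0); syn_delay_steps <- integer(0)
  cur_src <- integer(0); cur_tgt_pos <- integer(0)
  sensor_edges <- list()
  for (e in net$edges) {
    si <- idx_of[[e$source]]; ti <- idx_of[[e$target]]
    tk <- kinds[ti]; sk <- kinds[si]
    if (tk == "neuron" && sk %in% CURRENT_SOURCE_KINDS) {
      cur_src <- c(cur_src, si); cur_tgt_pos <- c(cur_tgt_pos, neuron_pos[ti])
    } else if (tk == "neuron") {
      syn <- e$synapse
      if (dt >= syn$tau_syn) {
        stop("invalid step: dt must be smaller than tau_syn on edge ",
             e$source, " -> ", e$target)
      }
      syn_src <- c(syn_src, si)
      syn_tgt_pos <- c(syn_tgt_pos, neuron_pos[ti])
      sign <- node_polarity_sign(net$nodes[[si]])
      syn_peak <- c(syn_peak, sign * syn$peak_current)
      syn_tau <- c(syn_tau, syn$tau_syn)
      syn_delay_steps <- c(syn_delay_steps, max(1L, as.integer(round(syn$delay / dt))))
    } else {
      sensor_edges[[length(sensor_edges) + 1L]] <- list(src = si, sensor = ti)
    }
  }
  outgoing <- vector("list", length(ids))
  for (j in seq_along(syn_src)) {
    outgoing[[syn_src[j]]] <- c(outgoing[[syn_src[j]]], j)
  }

  connected_sensors <- unique(vapply(sensor_edges, `[[`, integer(1), "sensor"))
  for (si in which(kinds %in% SENSOR_KINDS)) {
    if (!si %in% connected_sensors) {
      warning("sensor '", ids[si], "' (", kinds[si], ") is not connected ",
              "to any neuron", call. = FALSE)
    }
  }

  # stimulator tables
  reg_idx <- which(kinds == "regular_generator")
  reg_rate <- vapply(net$nodes[reg_idx], function(n) n$params$rate, numeric(1))
  reg_period <- ifelse(reg_rate > 0, 1 / reg_rate, Inf)
  reg_tsf <- vapply(net$nodes[reg_idx],
                    function(n) n$params$time_since_fire %||% 0, numeric(1))

  stoch_idx <- which(kinds %in% c("poisson_generator", "visual_input"))
  stoch_p <- numeric(length(stoch_idx))
  vis_frame_p <- vector("list", length(stoch_idx))  # per-frame probabilities
  for (j in seq_along(stoch_idx)) {
    nd <- net$nodes[[stoch_idx[j]]]
    if (nd$kind == "poisson_generator") {
      p <- nd$params$rate * dt
      if (p > 1) stop("rate * dt > 1 on node '", nd$id, "'")
      if (p > 0.1) warning("rate * dt > 0.1 on node '", nd$id,
                           "': Bernoulli-per-step approximation is biased",
                           call. = FALSE)
      stoch_p[j] <- p
    } else {
      stoch_p[j] <- visual_step_probability(nd, t = 0, dt = dt)
      vis_frame_p[[j]] <- nd
    }
  }
  vis_static <- vapply(seq_along(stoch_idx), function(j) {
    is.null(vis_frame_p[[j]]) || visual_is_static(vis_frame_p[[j]])
  }, logical(1))

  ev_idx <- which(kinds == "event_source")
  ev_steps <- lapply(net$nodes[ev_idx], function(n) {
    tms <- as.numeric(n$params$activation_times)
    ks <- unique(ceiling(tms / dt - 1e-9))
    ks[ks >= 1 & ks <= n_steps]
  })

  list(ids = ids, kinds = kinds, n_steps = n_steps, dt = dt,
       neurons = neurons, neuron_pos = neuron_pos,
       syn = list(src = syn_src, tgt = syn_tgt_pos, peak = syn_peak,
                  tau = syn_tau, delay = syn_delay_steps),
       cur = list(src = cur_src, tgt = cur_tgt_pos),
       outgoing = outgoing, sensor_edges = sensor_edges,
       reg = list(idx = reg_idx, period = reg_period, tsf = reg_tsf),
       stoch = list(idx = stoch_idx, p = stoch_p, nodes = vis_frame_p,
                    static = vis_static),
       ev = list(idx = ev_idx, steps = ev_steps))
}

visual_is_static <- function(node) {
  !is.list(node$params$stimulus) || length(node$params$stimulus) <= 1
}

visual_step_probability <- function(node, t, dt) {
  p <- node$params
  if (is.null(p$kernel) || is.null(p$stimulus)) return(0)
  kernel <- as_rf_kernel(p$kernel)
  stim <- p$stimulus
  if (is.list(stim) && !is.matrix(stim)) {
    fi <- min(length(stim), floor(t / p$frame_interval) + 1)
    stim <- stim[[fi]]
  }
  resp <- field_response(kernel, as.matrix(stim))
  min(1, max(0, resp) * p$gain * dt)
}

as_rf_kernel <- function(kernel) {
  if (inherits(kernel, "lif_rf_kernel")) return(kernel)
  # plain list from a loaded document: rebuild the grid from parameters
  k <- kernel
  switch(k$kind,
    edge = make_edge_kernel(k$H, k$W, k$orientation %||% 0),
    dog = make_dog_kernel(k$H, k$W, k$sigma_center, k$sigma_surround,
                          k$on_center %||% TRUE),
    gabor = make_gabor_kernel(k$H, k$W, k$orientation %||% 0, k$sigma_x,
                              k$sigma_y, k$wavelength, k$phase %||% 0),
    stop("unknown receptive-field kind: '", k$kind, "'")
  )
}

#' Run a network simulation
#'
#' Executes `ceiling(duration / dt)` fixed steps from `t = 0`, with all
#' stochastic draws governed by `cfg$seed` (the global R random state is
#' saved and restored around the run). The state at `t = 0` is recorded
#' before the first step, so every voltage trace has `n_steps + 1` samples.
#' Recorded voltages are the post-clamp, pre-reset values of each step, so a
#' spiking trace touches threshold and a saturating input shows the clamp
#' bound before the reset is applied.
#'
#' @param net A valid [network()].
#' @param cfg A [sim_config()].
#' @return An object of class `lif_recordings` with elements `times` (the
#'   shared time grid, second), `voltages` (matrix, one column per neuron id),
#'   `spikes` (named list of spike-time vectors for every spiking node),
#'   `rates` (named list of firing-rate traces, one per connected rate meter,
#'   Hz), plus `labels`, `kinds`, `dt`, `duration` and `seed`.
#' @export
#' @examples
#' net <- network()
#' net <- add_node(net, "dc_source", amplitude = 2.5e-10)
#' net <- add_node(net, "neuron", label = "cell")
#' net <- connect(net, "n1", "n2")
#' rec <- run_network(net, sim_config(duration = 0.5))
#' length(rec$spikes[["n2"]])
run_network <- function(net, cfg) {
  stopifnot(inherits(cfg, "lif_sim_config"))
  cn <- compile_network(net, cfg)
  dt <- cn$dt; n_steps <- cn$n_steps
  clamp <- cfg$clamp

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(cfg$seed)

  nn <- length(cn$neurons$node_idx)
  ne <- length(cn$syn$src)
  V <- cn$neurons$Vr
  g <- numeric(nn)
  refr <- numeric(nn)
  s <- numeric(ne)
  syn_decay <- if (ne) 1 - dt / cn$syn$tau else numeric(0)
  syn_grp <- cn$syn$tgt
  syn_grp_u <- sort(unique(syn_grp))

  # constant part of the injected current (DC sources)
  I_dc <- numeric(nn)
  ac_edges <- integer(0)
  ac_amp <- numeric(0); ac_freq <- numeric(0); ac_tgt <- integer(0)
  if (length(cn$cur$src)) {
    for (j in seq_along(cn$cur$src)) {
      nd <- net$nodes[[cn$cur$src[j]]]
      tgt <- cn$cur$tgt[j]
      if (nd$kind == "dc_source") {
        I_dc[tgt] <- I_dc[tgt] + nd$params$amplitude
      } else {
        ac_amp <- c(ac_amp, nd$params$amplitude)
        ac_freq <- c(ac_freq, nd$params$frequency)
        ac_tgt <- c(ac_tgt, tgt)
      }
    }
  }

  reg_tsf <- cn$reg$tsf
  stoch_p <- cn$stoch$p
  all_static <- all(cn$stoch$static)

  max_delay <- if (ne) max(cn$syn$delay) else 1L
  L <- max_delay + 1L
  ring <- vector("list", L)
  for (i in seq_len(L)) ring[[i]] <- integer(0)

  volt <- matrix(NA_real_, nrow = n_steps + 1L, ncol = nn,
                 dimnames = list(NULL, cn$ids[cn$neurons$node_idx]))
  if (nn) volt[1L, ] <- V

  fire_cap <- 1024L
  fire_steps <- integer(fire_cap); fire_nodes <- integer(fire_cap)
  n_fires <- 0L
  push_fires <- function(nodes, k) {
    m <- length(nodes)
    if (n_fires + m > fire_cap) {
      fire_cap <<- max(fire_cap * 2L, n_fires + m)
      length(fire_steps) <<- fire_cap
      length(fire_nodes) <<- fire_cap
    }
    fire_steps[(n_fires + 1L):(n_fires + m)] <<- k
    fire_nodes[(n_fires + 1L):(n_fires + m)] <<- nodes
    n_fires <<- n_fires + m
  }

  ev_fire_steps <- cn$ev$steps
  Cm <- cn$neurons$Cm; Rm <- cn$neurons$Rm; Vr <- cn$neurons$Vr
  Vreset <- cn$neurons$Vreset; Vthres <- cn$neurons$Vthres
  tau_r <- cn$neurons$tau_r; dga <- cn$neurons$dga
  g_decay <- cn$neurons$g_decay
  dt_over_Cm <- dt / Cm

  for (k in seq_len(n_steps)) {
    slot <- (k - 1L) %% L + 1L
    due <- ring[[slot]]
    if (length(due)) {
      ring[[slot]] <- integer(0)
      s[due] <- s[due] + cn$syn$peak[due]
    }
    if (ne) s <- s * syn_decay

    t_prev <- (k - 1L) * dt
    fired_nodes <- integer(0)

    if (length(cn$reg$idx)) {
      reg_tsf <- reg_tsf + dt
      f <- reg_tsf > cn$reg$period
      if (any(f)) {
        reg_tsf[f] <- 0
        fired_nodes <- c(fired_nodes, cn$reg$idx[f])
      }
    }
    if (length(cn$stoch$idx)) {
      if (!all_static) {
        dyn <- which(!cn$stoch$static)
        for (j in dyn) {
          stoch_p[j] <- visual_step_probability(cn$stoch$nodes[[j]], t_prev, dt)
        }
      }
      f <- stats::runif(length(cn$stoch$idx)) < stoch_p
      if (any(f)) fired_nodes <- c(fired_nodes, cn$stoch$idx[f])
    }
    if (length(cn$ev$idx)) {
      for (j in seq_along(cn$ev$idx)) {
        if (k %in% ev_fire_steps[[j]]) {
          fired_nodes <- c(fired_nodes, cn$ev$idx[j])
        }
      }
    }

    if (nn) {
      I_syn <- numeric(nn)
      if (ne) {
        agg <- rowsum(s, syn_grp, reorder = TRUE)
        I_syn[syn_grp_u] <- agg[, 1L]
      }
      I_inj <- I_dc
      if (length(ac_tgt)) {
        ac_now <- ac_amp * sin(2 * pi * ac_freq * t_prev)
        for (j in seq_along(ac_tgt)) {
          I_inj[ac_tgt[j]] <- I_inj[ac_tgt[j]] + ac_now[j]
        }
      }
      g <- g * g_decay
      in_refr <- refr > 0
      Vn <- V + dt_over_Cm *
        (-(V - Vr) / Rm + I_syn + I_inj - g * (V - Vr))
      if (clamp$enabled) Vn <- pmin(pmax(Vn, clamp$v_min), clamp$v_max)
      Vn[in_refr] <- Vreset[in_refr]
      if (any(!is.finite(Vn))) {
        bad <- cn$ids[cn$neurons$node_idx[which(!is.finite(Vn))[1]]]
        stop("numerical blow-up at node '", bad, "', step ", k,
             ": membrane potential is not finite")
      }
      volt[k + 1L, ] <- Vn
      fired <- !in_refr & Vn >= Vthres
      refr[in_refr] <- pmax(0, refr[in_refr] - dt)
      if (any(fired)) {
        Vn[fired] <- Vreset[fired]
        refr[fired] <- tau_r[fired]
        g[fired] <- g[fired] + dga[fired]
        fired_nodes <- c(fired_nodes, cn$neurons$node_idx[fired])
      }
      V <- Vn
    }

    if (length(fired_nodes)) {
      fired_nodes <- sort(fired_nodes)  # fixed tie-break order
      push_fires(fired_nodes, k)
      for (ni in fired_nodes) {
        out <- cn$outgoing[[ni]]
        if (length(out)) {
          for (j in out) {
            dslot <- (k + cn$syn$delay[j] - 1L) %% L + 1L
            ring[[dslot]] <- c(ring[[dslot]], j)
          }
        }
      }
    }
  }

  length(fire_steps) <- n_fires
  length(fire_nodes) <- n_fires
  spiking <- which(cn$kinds %in% SPIKING_KINDS)
  spikes <- stats::setNames(vector("list", length(spiking)),
                            cn$ids[spiking])
  for (j in seq_along(spiking)) {
    spikes[[j]] <- fire_steps[fire_nodes == spiking[j]] * dt
  }

  times <- (0:n_steps) * dt
  labels <- stats::setNames(
    vapply(net$nodes, function(n) n$label %||% NA_character_, character(1)),
    cn$ids)

  rates <- list()
  for (se in cn$sensor_edges) {
    if (cn$kinds[se$sensor] != "firing_rate_meter") next
    mid <- cn$ids[se$sensor]
    if (is.null(rates[[mid]])) rates[[mid]] <- list()
    rates[[mid]] <- c(rates[[mid]], list(cn$ids[se$src]))
  }
  rate_traces <- list()
  for (mid in names(rates)) {
    src_ids <- unlist(rates[[mid]])
    trains <- spikes[intersect(src_ids, names(spikes))]
    sigma_w <- net$nodes[[mid]]$params$sigma_w
    rate_traces[[mid]] <- gaussian_rate(trains, sigma_w, times)
  }

  rec <- structure(list(times = times, voltages = volt, spikes = spikes,
                        rates = rate_traces, labels = labels,
                        kinds = stats::setNames(cn$kinds, cn$ids),
                        dt = dt, duration = cfg$duration, seed = cfg$seed),
                   class = "lif_recordings")
  if (!identical(cfg$record, "all")) {
    keep <- cfg$record
    rec$voltages <- rec$voltages[, intersect(colnames(rec$voltages), keep),
                                 drop = FALSE]
    rec$spikes <- rec$spikes[intersect(names(rec$spikes), keep)]
    rec$rates <- rec$rates[intersect(names(rec$rates), keep)]
  }
  rec
}

#' @export
print.lif_recordings <- function(x, ...) {
  cat("<lif_recordings> ", length(x$times), " samples, dt = ", x$dt,
      " s, duration = ", x$duration, " s, seed = ", x$seed, "\n", sep = "")
  cat("  voltage traces: ", ncol(x$voltages), "; spike trains: ",
      length(x$spikes), " (", sum(lengths(x$spikes)), " spikes); ",
      "rate traces: ", length(x$rates), "\n", sep = "")
  invisible(x)
}
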