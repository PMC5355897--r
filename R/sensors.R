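#' Firing-rate meter parameters
#'
#' @param sigma_w Width of the Gaussian smoothing window (second), `> 0`.
#' @param rate_min,rate_max Display bounds (Hz) used only when rendering or
#'   reporting; stored rate values are never clipped.
#' @return An object of class `lif_rate_meter_params`.
#' @export
rate_meter_params <- function(sigma_w = 0.1, rate_min = 0, rate_max = 100) {
  stopifnot(sigma_w > 0, rate_min < rate_max)
  structure(list(sigma_w = sigma_w, rate_min = rate_min, rate_max = rate_max),
            class = "lif_rate_meter_params")
}

#' Gaussian-window firing-rate estimate
#'
#' Population firing rate at times `t`: each spike contributes a normalized
#' Gaussian kernel of width `sigma_w` (unit time-integral per spike, so a
#' regular f Hz train reads f Hz), and the contributions are averaged — not
#' summed — over the supplied trains. The kernel is truncated at
#' `+/- 5 sigma_w`; the truncated mass is below 1e-6 per spike.
#'
#' @param spike_trains A list of numeric spike-time vectors (one per neuron),
#'   or a single numeric vector.
#' @param sigma_w Gaussian window width (second), `> 0`.
#' @param t Evaluation times (second); vectorized.
#' @return Rate estimate (Hz), same length as `t`.
#' @export
#' @examples
#' gaussian_rate(list(c(0.5)), sigma_w = 0.1, t = 0.5)  # peak: 1/(sqrt(2*pi)*0.1)
gaussian_rate <- function(spike_trains, sigma_w, t) {
  if (is.numeric(spike_trains)) spike_trains <- list(spike_trains)
  stopifnot(sigma_w > 0)
  n_trains <- length(spike_trains)
  if (n_trains == 0) stop("rate meter is not connected to any spike train")
  out <- numeric(length(t))
  cut <- 5 * sigma_w
  for (sp in unlist(spike_trains, use.names = FALSE)) {
    d <- t - sp
    m <- abs(d) <= cut
    if (any(m)) out[m] <- out[m] + stats::dnorm(d[m], sd = sigma_w)
  }
  out / n_trains
}

#' Spike raster rows
#'
#' Extracts per-neuron spike-time rows from a recording, in the given order,
#' restricted to the trailing time window. Rows are named by the node's
#' label when present, otherwise by its id.
#'
#' @param recordings A `lif_recordings` from [run_network()].
#' @param ids Node ids to extract (row order preserved).
#' @param window Trailing window length (second); only spikes in
#'   `[t_end - window, t_end]` are kept. Default keeps everything.
#' @return A named list of spike-time vectors, one row per id.
#' @export
spike_raster <- function(recordings, ids, window = Inf) {
  rows <- vector("list", length(ids))
  t_end <- recordings$times[length(recordings$times)]
  for (j in seq_along(ids)) {
    id <- ids[j]
    if (!id %in% names(recordings$spikes)) {
      stop("no recorded spike train for node id '", id, "'")
    }
    sp <- recordings$spikes[[id]]
    rows[[j]] <- sp[sp >= t_end - window]
  }
  names(rows) <- display_names(recordings, ids)
  rows
}

#' Voltage trace rows
#'
#' @param recordings A `lif_recordings` from [run_network()].
#' @param ids Neuron ids to extract (row order preserved).
#' @return A named list of voltage series (volt), one per id, named by label
#'   when present, otherwise by id; the shared time grid is attached as
#'   `attr(, "times")`.
#' @export
voltage_rows <- function(recordings, ids) {
  missing <- setdiff(ids, colnames(recordings$voltages))
  if (length(missing)) {
    stop("no recorded voltage trace for node id '", missing[1], "'")
  }
  rows <- lapply(ids, function(id) recordings$voltages[, id])
  names(rows) <- display_names(recordings, ids)
  attr(rows, "times") <- recordings$times
  rows
}

display_names <- function(recordings, ids) {
  labs <- recordings$labels[ids]
  ifelse(is.na(labs), ids, labs)
}

#' Write recorded voltages to CSV
#'
#' One wide table: a `time` column (second) plus one column per recorded
#' neuron (volt), headed by the node label when present, otherwise the id.
#'
#' @param recordings A `lif_recordings`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_voltages_csv <- function(recordings, path) {
  ids <- colnames(recordings$voltages)
  df <- data.frame(time = recordings$times, recordings$voltages,
                   check.names = FALSE)
  names(df) <- c("time", display_names(recordings, ids))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write recorded spikes to CSV
#'
#' Long two-column format: `node_id`, `time` (second), ordered by node then
#' time.
#'
#' @param recordings A `lif_recordings`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_spikes_csv <- function(recordings, path) {
  df <- data.frame(
    node_id = rep(names(recordings$spikes), lengths(recordings$spikes)),
    time = unlist(recordings$spikes, use.names = FALSE)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write firing-rate traces to CSV
#'
#' A `time` column plus one column (Hz) per rate meter.
#'
#' @param recordings A `lif_recordings`.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_rates_csv <- function(recordings, path) {
  df <- data.frame(time = recordings$times)
  for (mid in names(recordings$rates)) df[[mid]] <- recordings$rates[[mid]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
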