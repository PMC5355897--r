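# JSON serialization of networks.
#
# Document envelope (version 3):
#   { "fileFormatVersion": 3, "edges": [...], "nodes": [...],
#     "workspace": {...} }
#
# Each node entry carries its id, kind, optional label, and a "properties"
# object holding only the parameters that differ from the kind's defaults
# (defaults fill omitted properties on load). Edge entries carry source,
# target, and non-default synapse properties. The workspace object is
# free-form metadata (view state, positions); it is preserved verbatim and
# ignored by the engine, except for a "units": "SI" marker added on save.
# Serialization is canonical — fixed key order, alphabetical property names —
# so save -> load -> save is byte-identical.

FILE_FORMAT_VERSION <- 3L

serialize_params <- function(kind, params) {
  defaults <- node_defaults(kind)
  out <- list()
  for (nm in sort(names(params))) {
    val <- params[[nm]]
    if (identical(val, defaults[[nm]])) next
    if (nm == "kernel" && !is.null(val)) val <- serialize_kernel(val)
    if (nm == "stimulus" && !is.null(val)) val <- serialize_stimulus(val)
    out[[nm]] <- val
  }
  out
}

serialize_kernel <- function(kernel) {
  if (inherits(kernel, "lif_rf_kernel")) {
    k <- unclass(kernel)
    k$H <- nrow(kernel$grid)
    k$W <- ncol(kernel$grid)
    k$grid <- NULL
    kernel <- k
  }
  kernel[sort(names(kernel))]
}

serialize_stimulus <- function(stim) {
  if (is.matrix(stim)) return(unclass(stim))
  lapply(stim, unclass)  # list of frames
}

serialize_synapse <- function(syn) {
  if (is.null(syn)) return(list())
  defaults <- unclass(synapse_params())
  out <- list()
  for (nm in sort(names(syn))) {
    if (!identical(syn[[nm]], defaults[[nm]])) out[[nm]] <- syn[[nm]]
  }
  out
}

network_document <- function(net) {
  validate_network(net)
  nodes <- lapply(net$nodes, function(n) {
    entry <- list(id = n$id, kind = n$kind)
    if (!is.null(n$label)) entry$label <- n$label
    props <- serialize_params(n$kind, n$params)
    if (length(props)) entry$properties <- props
    entry
  })
  edges <- lapply(net$edges, function(e) {
    entry <- list(source = e$source, target = e$target)
    props <- serialize_synapse(e$synapse)
    if (length(props)) entry$properties <- props
    entry
  })
  workspace <- net$workspace
  if (is.null(workspace$units)) workspace$units <- "SI"
  workspace <- workspace[sort(names(workspace))]
  list(fileFormatVersion = FILE_FORMAT_VERSION,
       edges = unname(edges),
       nodes = unname(nodes),
       workspace = workspace)
}

document_to_json <- function(doc) {
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, digits = NA,
                   null = "null")
}

#' Save a network as a JSON document
#'
#' Emits the versioned four-key envelope (`fileFormatVersion`, `edges`,
#' `nodes`, `workspace`) with `fileFormatVersion = 3`. Only properties that
#' differ from each kind's defaults are serialized; key order is canonical so
#' repeated saves of equivalent networks are byte-identical.
#'
#' @param net A valid [network()].
#' @param destination Output file path, or `NULL` to skip writing.
#' @return The document, invisibly, as a named list; its canonical JSON text
#'   is attached as `attr(, "json")`.
#' @export
#' @examples
#' net <- add_node(network(), "neuron", Rm = 2e8)
#' doc <- save_network(net)
#' doc$fileFormatVersion
save_network <- function(net, destination = NULL) {
  doc <- network_document(net)
  json <- document_to_json(doc)
  if (!is.null(destination)) {
    con <- file(destination, open = "wb")
    on.exit(close(con))
    writeLines(json, con, useBytes = TRUE)
  }
  attr(doc, "json") <- as.character(json)
  invisible(doc)
}

deserialize_stimulus <- function(stim) {
  if (length(stim) == 0) return(NULL)
  if (is.list(stim[[1]])) {
    if (is.list(stim[[1]][[1]])) {
      return(lapply(stim, json_matrix))  # list of frames
    }
    return(json_matrix(stim))
  }
  json_matrix(stim)
}

json_matrix <- function(rows) {
  do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
}

deserialize_params <- function(kind, props) {
  if (is.null(props)) return(list())
  out <- list()
  for (nm in names(props)) {
    val <- props[[nm]]
    val <- switch(nm,
      activation_times = as.numeric(unlist(val)),
      stimulus = deserialize_stimulus(val),
      kernel = lapply(val, function(v) if (is.list(v)) unlist(v) else v),
      adaptive = isTRUE(val),
      on_center = isTRUE(val),
      {
        v <- if (is.list(val)) unlist(val) else val
        # JSON integers arrive as R integers; parameters are doubles
        if (is.integer(v)) as.numeric(v) else v
      })
    out[[nm]] <- val
  }
  out
}

#' Load a network from a JSON document
#'
#' Reconstructs a [network()] from a document written by [save_network()].
#' Omitted properties are filled with the kind defaults; unknown workspace
#' content is preserved opaquely and written back on save. Documents with an
#' unrecognized `fileFormatVersion` are rejected outright — never silently
#' misread — as are dangling edge endpoints and unknown node kinds.
#'
#' @param source Path to a JSON file, or a JSON string.
#' @return A `lif_network`.
#' @export
load_network <- function(source) {
  txt <- if (length(source) == 1 && !grepl("[{]", source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else {
    paste(source, collapse = "\n")
  }
  doc <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expected <- c("fileFormatVersion", "edges", "nodes", "workspace")
  if (!setequal(names(doc), expected)) {
    stop("malformed document: top-level keys must be exactly {",
         paste(expected, collapse = ", "), "}; found {",
         paste(names(doc), collapse = ", "), "}")
  }
  ver <- doc$fileFormatVersion
  if (!identical(as.integer(ver), FILE_FORMAT_VERSION)) {
    stop("unsupported fileFormatVersion: ", ver,
         " (supported: ", FILE_FORMAT_VERSION, ")")
  }
  net <- network()
  for (nd in doc$nodes) {
    if (is.null(nd$kind) || !nd$kind %in% NODE_KINDS) {
      stop("unknown node kind: '", nd$kind %||% "<missing>", "'")
    }
    params <- deserialize_params(nd$kind, nd$properties)
    net <- do.call(add_node,
                   c(list(net = net, kind = nd$kind, label = nd$label,
                          id = nd$id), params))
  }
  for (ed in doc$edges) {
    for (endpoint in c(ed$source, ed$target)) {
      if (!endpoint %in% names(net$nodes)) {
        stop("edge references missing node id: '", endpoint, "'")
      }
    }
    syn_props <- ed$properties %||% list()
    syn <- do.call(synapse_params, lapply(syn_props, function(v) v))
    net <- connect(net, ed$source, ed$target, synapse = syn,
                   allow_self_loop = TRUE)
  }
  ws <- doc$workspace
  net$workspace <- ws
  validate_network(net)
  net
}
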