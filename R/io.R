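# Persistence: a network bundle is a directory of plain-text files — a
# JSON header (schema version, config, scalar parameters, state vectors)
# plus one CSV of weights per pathway. Everything needed to reproduce
# inference (weights, homeostatic thresholds, assignment) round-trips
# exactly.

BUNDLE_SCHEMA <- 1L

#' Save / load a reservoir network bundle
#'
#' `save_state()` writes a directory with `header.json` (schema version,
#' topology config, neuron/plasticity parameters, dynamic state including
#' the learned homeostatic thresholds) and `weights_<pathway>.csv` files;
#' optionally an `assignment.csv`. `load_state()` reconstructs the network
#' and verifies the schema version; a corrupted or partial bundle raises
#' an error without returning partial state.
#'
#' @param network a `reservoir_network`.
#' @param path bundle directory.
#' @param assignment optional `assignment_map` saved alongside.
#' @return `save_state` returns `path` invisibly; `load_state` returns a
#'   list with `network` and (if present) `assignment`.
#' @export
save_state <- function(network, path, assignment = NULL) {
  stopifnot(inherits(network, "reservoir_network"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  # state vectors are serialized as %.17g strings so that doubles
  # round-trip bit-exactly through JSON
  state_txt <- lapply(network$state, function(x)
    if (is.double(x)) sprintf("%.17g", x) else x)
  header <- list(
    schema = BUNDLE_SCHEMA,
    config = unclass(network$topology$config),
    exc = unclass(network$exc), inh = unclass(network$inh),
    plast = unclass(network$plast), gains = network$gains,
    tau_syn_e = network$tau_syn_e, tau_syn_i = network$tau_syn_i,
    state = state_txt)
  jsonlite::write_json(header, file.path(path, "header.json"),
                       auto_unbox = TRUE, digits = NA)
  for (nm in names(network$topology$pathways)) {
    g <- network$topology$pathways[[nm]]
    write.csv(data.frame(pre = g$pre, post = g$post,
                         w = sprintf("%.17g", g$w)),
              file.path(path, paste0("weights_", nm, ".csv")),
              row.names = FALSE)
  }
  if (!is.null(assignment))
    write.csv(data.frame(neuron = seq_along(assignment$neuron_label),
                         label = assignment$neuron_label),
              file.path(path, "assignment.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_state
#' @export
load_state <- function(path) {
  hf <- file.path(path, "header.json")
  if (!file.exists(hf)) stop("not a network bundle: missing header.json")
  header <- tryCatch(jsonlite::read_json(hf, simplifyVector = TRUE),
                     error = function(e)
                       stop("corrupted bundle header: ", conditionMessage(e)))
  if (is.null(header$schema) || header$schema != BUNDLE_SCHEMA)
    stop(sprintf("schema mismatch: bundle has %s, package expects %d",
                 as.character(header$schema %||% "none"), BUNDLE_SCHEMA))
  cfg <- header$config
  config <- topology_config(cfg$n_inputs, cfg$n_reservoir, cfg$exc_fraction,
                            cfg$p_in, cfg$p_ee, cfg$p_ei, cfg$p_ie, cfg$p_ii,
                            cfg$rng_seed)
  topo <- build_topology(config)
  exc <- do.call(neuron_params, header$exc)
  inh <- do.call(neuron_params, header$inh)
  plast <- do.call(plasticity_params, header$plast)
  # stored gains are the effective (already size-scaled) values, so the
  # constructor must not rescale them again
  net <- new_network(topo, exc = exc, inh = inh, plast = plast,
                     gains = unlist(header$gains),
                     tau_syn_e = header$tau_syn_e,
                     tau_syn_i = header$tau_syn_i,
                     gain_ref_n = cfg$n_reservoir)
  for (nm in names(net$topology$pathways)) {
    f <- file.path(path, paste0("weights_", nm, ".csv"))
    if (!file.exists(f)) stop("corrupted bundle: missing ", basename(f))
    d <- read.csv(f)
    g <- net$topology$pathways[[nm]]
    if (nrow(d) != length(g$pre)) stop("bundle does not match its config seed")
    ord <- order(d$pre, d$post)
    net$topology$pathways[[nm]]$w <- as.numeric(d$w[ord])
  }
  st <- header$state
  st$last_spike_flags <- as.logical(st$last_spike_flags)
  for (nm in setdiff(names(st), "last_spike_flags"))
    st[[nm]] <- as.numeric(st[[nm]])
  net$state <- st
  out <- list(network = net)
  af <- file.path(path, "assignment.csv")
  if (file.exists(af)) {
    d <- read.csv(af, stringsAsFactors = FALSE)
    lab <- as.character(d$label[order(d$neuron)])
    labels <- sort(unique(lab[!is.na(lab)]))
    resp <- matrix(0, length(lab), length(labels),
                   dimnames = list(NULL, labels))
    for (l in labels) resp[which(lab == l), l] <- 1
    out$assignment <- suppressWarnings(assignment_from_response(resp, labels))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
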