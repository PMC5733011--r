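#' Topology configuration for a two-layer reservoir
#'
#' Describes an input layer of `n_inputs` Poisson channels connected to a
#' reservoir of `n_reservoir` LIF neurons, of which a fraction `exc_fraction`
#' are excitatory. Recurrent pathways are drawn as independent Bernoulli edges
#' with per-pathway probabilities. The excitatory/inhibitory balance rule
#' `p_ee < p_ei * p_ie` is enforced: with 4:1 E/I counts, inhibition must be
#' effectively stronger than recurrent excitation for the reservoir to show
#' irregular, Poisson-like spontaneous activity rather than a runaway drift
#' of membrane potentials toward threshold.
#'
#' @param n_inputs number of input channels (one per image pixel; 784 for
#'   28x28 glyphs).
#' @param n_reservoir total number of reservoir neurons (N).
#' @param exc_fraction fraction of excitatory neurons (default 0.8, the
#'   cortical 4:1 ratio).
#' @param p_in connection probability input -> excitatory (default 0.3).
#' @param p_ee,p_ei,p_ie,p_ii recurrent connection probabilities. Defaults
#'   (0.1, 0.3, 0.4, 0.1) are sparse and satisfy the balance rule.
#' @param rng_seed integer seed used by [build_topology()].
#' @return an object of class `topology_config`.
#' @seealso [check_balance()], [build_topology()]
#' @export
topology_config <- function(n_inputs = 784L, n_reservoir = 500L,
                            exc_fraction = 0.8, p_in = 0.3,
                            p_ee = 0.1, p_ei = 0.3, p_ie = 0.4, p_ii = 0.1,
                            rng_seed = 1L) {
  probs <- c(p_in = p_in, p_ee = p_ee, p_ei = p_ei, p_ie = p_ie, p_ii = p_ii)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("connection probabilities must lie in [0, 1]")
  if (n_inputs < 1L || n_reservoir < 2L)
    stop("n_inputs >= 1 and n_reservoir >= 2 required")
  if (exc_fraction <= 0 || exc_fraction >= 1)
    stop("exc_fraction must lie in (0, 1)")
  cfg <- list(n_inputs = as.integer(n_inputs),
              n_reservoir = as.integer(n_reservoir),
              exc_fraction = exc_fraction,
              p_in = p_in, p_ee = p_ee, p_ei = p_ei, p_ie = p_ie, p_ii = p_ii,
              rng_seed = as.integer(rng_seed))
  cfg$n_exc <- as.integer(round(n_reservoir * exc_fraction))
  cfg$n_inh <- cfg$n_reservoir - cfg$n_exc
  if (cfg$n_exc < 1L || cfg$n_inh < 1L)
    stop("both populations must be non-empty")
  class(cfg) <- "topology_config"
  bal <- check_balance(cfg)
  if (!bal$pass)
    stop(sprintf(
      "E/I balance violated: p_ee (%.4g) must be < p_ei * p_ie (%.4g)",
      bal$lhs, bal$rhs))
  cfg
}

#' Check the excitatory/inhibitory balance rule
#'
#' Passes iff `p_ee < p_ei * p_ie`. When excitation dominates the reverse
#' inequality, the mean membrane potential drifts toward threshold and the
#' reservoir locks into a regular firing trajectory; the balanced regime
#' yields irregular Poisson-like activity.
#'
#' @param config a `topology_config` or any list with `p_ee`, `p_ei`, `p_ie`.
#' @return list with `pass` (logical), `lhs` (p_ee) and `rhs` (p_ei * p_ie).
#' @export
check_balance <- function(config) {
  probs <- c(config$p_ee, config$p_ei, config$p_ie)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  lhs <- config$p_ee
  rhs <- config$p_ei * config$p_ie
  list(pass = lhs < rhs, lhs = lhs, rhs = rhs)
}

# Internal: sparse pathway container. Edges are kept sorted by (pre, post)
# with 0-based CSR/CSC index arrays ready for the C++ engine.
new_synapse_group <- function(pre, post, w, n_pre, n_post, pathway,
                              plastic, rule, w_max) {
  stopifnot(length(pre) == length(post), length(w) == length(pre))
  if (any(w < 0)) stop("stored weights must be non-negative (sign is carried by pathway type)")
  ord <- order(pre, post)
  pre <- as.integer(pre[ord]); post <- as.integer(post[ord]); w <- as.numeric(w[ord])
  csr_ptr <- c(0L, cumsum(tabulate(pre, nbins = n_pre)))
  ord2 <- order(post, pre)
  csc_perm <- as.integer(ord2 - 1L)
  csc_ptr <- c(0L, cumsum(tabulate(post, nbins = n_post)))
  structure(list(pathway = pathway, n_pre = as.integer(n_pre),
                 n_post = as.integer(n_post),
                 pre = pre, post = post, w = w,
                 csr_ptr = as.integer(csr_ptr),
                 pre0 = pre - 1L, post0 = post - 1L,
                 csc_ptr = as.integer(csc_ptr), csc_perm = csc_perm,
                 plastic = plastic, rule = rule, w_max = w_max),
            class = "synapse_group")
}

# Internal: Bernoulli edge draw for one pathway; no self-connections when
# pre and post index the same population.
draw_edges <- function(n_pre, n_post, p, self_loops = TRUE) {
  if (p <= 0 || n_pre == 0L || n_post == 0L)
    return(list(pre = integer(0), post = integer(0)))
  m <- matrix(runif(n_pre * n_post) < p, n_pre, n_post)
  if (!self_loops) diag(m) <- FALSE
  idx <- which(m, arr.ind = TRUE)
  list(pre = idx[, 1L], post = idx[, 2L])
}

#' Build a random two-layer reservoir topology
#'
#' Draws every potential edge of the five pathways (In->E, E->E, E->I, I->E,
#' I->I) as an independent Bernoulli variable, assigns initial weights, and
#' marks the plastic pathways. Only connections onto excitatory neurons
#' (In->E and E->E) are plastic; all other pathways keep their initial
#' values. Self-connections are excluded in all recurrent pathways. The
#' result is deterministic for a fixed `rng_seed`.
#'
#' Initial weights: In->E uniform on `[0, 0.3 * w_max_in]`; E->E uniform on
#' `[0, w_max_ee]` so that the untrained reservoir starts in the strongly
#' recurrent (chaotic) regime that learning subsequently contracts. The
#' fixed pathways receive random uniform weights whose upper bounds are
#' chosen per pathway so that every recurrent block has the same per-entry
#' variance as the initial E->E block: with homogeneous block variances
#' the untrained eigenvalue spectrum is a Girko disc (plus the handful of
#' outliers from the E/I mean structure), and the E->E block - the only
#' one learning changes - carries the dominant share of the spectral
#' variance. Pathway strength in the dynamics is carried by the gains
#' ([default_gains()]), which are calibrated to the fixed-pathway means.
#'
#' Input synapses onto each excitatory neuron carry a fixed total-weight
#' budget: the column sum of In->E weights is held at `w_norm_mean` times
#' the neuron's fan-in (divisive normalization, re-applied during training
#' after every presentation). The budget forces competition among a
#' neuron's input synapses, so potentiating one character's pixels must
#' come at the expense of others — the mechanism by which single-character
#' receptive fields differentiate.
#'
#' @param config a [topology_config()].
#' @param w_max_in,w_max_ee plastic weight bounds (defaults 1.0 and 0.5).
#' @param w_norm_mean per-synapse mean of the In->E weight budget.
#' @return an object of class `network_topology`: a list of five
#'   `synapse_group`s plus population index ranges and the config.
#' @export
build_topology <- function(config, w_max_in = 1.0, w_max_ee = 0.5,
                           w_norm_mean = 0.2) {
  stopifnot(inherits(config, "topology_config"))
  bal <- check_balance(config)
  if (!bal$pass)
    stop(sprintf("balance violation: p_ee = %.4g >= p_ei * p_ie = %.4g",
                 bal$lhs, bal$rhs))
  nE <- config$n_exc; nI <- config$n_inh; nIn <- config$n_inputs
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$rng_seed)

  e <- draw_edges(nIn, nE, config$p_in)
  in_e <- new_synapse_group(e$pre, e$post,
                            runif(length(e$pre), 0, 0.3 * w_max_in),
                            nIn, nE, "in_e", TRUE, "eq1", w_max_in)
  # fixed per-neuron input-weight budget; initial weights scaled onto it
  fanin <- diff(in_e$csc_ptr)
  in_e$colsum_target <- w_norm_mean * fanin
  colsum <- vapply(seq_len(nE), function(j) {
    idx <- in_e$csc_perm[seq.int(in_e$csc_ptr[j] + 1L,
                                 length.out = fanin[j])] + 1L
    sum(in_e$w[idx])
  }, numeric(1))
  scale <- ifelse(colsum > 0, in_e$colsum_target / colsum, 1)
  for (j in seq_len(nE)) {
    idx <- in_e$csc_perm[seq.int(in_e$csc_ptr[j] + 1L,
                                 length.out = fanin[j])] + 1L
    in_e$w[idx] <- pmin(w_max_in, in_e$w[idx] * scale[j])
  }
  e <- draw_edges(nE, nE, config$p_ee, self_loops = FALSE)
  e_e <- new_synapse_group(e$pre, e$post,
                           runif(length(e$pre), 0, w_max_ee),
                           nE, nE, "e_e", TRUE, "eq2+eq3", w_max_ee)
  # per-entry variance of the initial E->E block, including absent edges
  v_ref <- config$p_ee * w_max_ee^2 / 3 - (config$p_ee * w_max_ee / 2)^2
  # uniform upper bound giving a Bernoulli(p) x U[0, b] entry that
  # variance-matches the E->E block
  vb <- function(p) if (p <= 0) w_max_ee else
    sqrt(v_ref / (p / 3 - p^2 / 4))
  e <- draw_edges(nE, nI, config$p_ei)
  e_i <- new_synapse_group(e$pre, e$post,
                           runif(length(e$pre), 0, vb(config$p_ei)),
                           nE, nI, "e_i", FALSE, "fixed", Inf)
  e <- draw_edges(nI, nE, config$p_ie)
  i_e <- new_synapse_group(e$pre, e$post,
                           runif(length(e$pre), 0, vb(config$p_ie)),
                           nI, nE, "i_e", FALSE, "fixed", Inf)
  e <- draw_edges(nI, nI, config$p_ii, self_loops = FALSE)
  i_i <- new_synapse_group(e$pre, e$post,
                           runif(length(e$pre), 0, vb(config$p_ii)),
                           nI, nI, "i_i", FALSE, "fixed", Inf)

  structure(list(config = config,
                 n_exc = nE, n_inh = nI, n_inputs = nIn,
                 exc_ids = seq_len(nE), inh_ids = nE + seq_len(nI),
                 pathways = list(in_e = in_e, e_e = e_e, e_i = e_i,
                                 i_e = i_e, i_i = i_i)),
            class = "network_topology")
}

# save/restore the global RNG state so builders are seed-local
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Compose the signed recurrent weight matrix
#'
#' Assembles the four recurrent pathways into one square matrix over all N
#' reservoir neurons: entry (j, i) holds the i -> j weight, positive when the
#' pre neuron is excitatory and negative when inhibitory; absent edges are 0.
#' This is the matrix whose eigenvalue spectrum diagnoses chaotic modes
#' ([eigen_spectrum()]): before learning the eigenvalues fill a disc per
#' Girko's circle law, and the disc contracts as the E->E block is learned.
#'
#' @param topology a `network_topology` (its current pathway weights are
#'   used) or a `reservoir_network`.
#' @return an N x N numeric matrix.
#' @export
compose_signed_matrix <- function(topology) {
  if (inherits(topology, "reservoir_network")) topology <- topology$topology
  stopifnot(inherits(topology, "network_topology"))
  nE <- topology$n_exc; nI <- topology$n_inh; n <- nE + nI
  W <- matrix(0, n, n)
  p <- topology$pathways
  if (any(!is.finite(p$e_e$w)) || any(!is.finite(p$i_e$w)))
    stop("non-finite weights")
  add <- function(W, g, pre_off, post_off, sign) {
    if (length(g$pre) > 0)
      W[cbind(post_off + g$post, pre_off + g$pre)] <-
        W[cbind(post_off + g$post, pre_off + g$pre)] + sign * g$w
    W
  }
  W <- add(W, p$e_e, 0L, 0L, +1)
  W <- add(W, p$e_i, 0L, nE, +1)
  W <- add(W, p$i_e, nE, 0L, -1)
  W <- add(W, p$i_i, nE, nE, -1)
  W
}

#' @export
print.network_topology <- function(x, ...) {
  cat(sprintf("<network_topology> %d inputs -> %d E + %d I neurons\n",
              x$n_inputs, x$n_exc, x$n_inh))
  for (g in x$pathways)
    cat(sprintf("  %-5s %6d edges  plastic=%s rule=%s\n",
                g$pathway, length(g$pre), g$plastic, g$rule))
  invisible(x)
}

#' Write / read a topology as an edge-list CSV plus JSON header
#'
#' The CSV has columns `pre_id`, `post_id`, `pathway`, `weight`, `plastic`;
#' the JSON sidecar records the config (including the seed) so a topology
#' file is self-describing.
#'
#' @param topology a `network_topology`.
#' @param path CSV path; the header is written to `<path>.json`.
#' @return `write_topology_csv` returns `path` invisibly; `read_topology_csv`
#'   returns a `network_topology`.
#' @export
write_topology_csv <- function(topology, path) {
  stopifnot(inherits(topology, "network_topology"))
  rows <- do.call(rbind, lapply(topology$pathways, function(g) {
    if (length(g$pre) == 0) return(NULL)
    data.frame(pre_id = g$pre, post_id = g$post, pathway = g$pathway,
               weight = g$w, plastic = g$plastic)
  }))
  write.csv(rows, path, row.names = FALSE)
  cfg <- unclass(topology$config)
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_topology_csv
#' @export
read_topology_csv <- function(path) {
  cfg <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- topology_config(cfg$n_inputs, cfg$n_reservoir, cfg$exc_fraction,
                            cfg$p_in, cfg$p_ee, cfg$p_ei, cfg$p_ie, cfg$p_ii,
                            cfg$rng_seed)
  topo <- build_topology(config)
  rows <- read.csv(path)
  for (nm in names(topo$pathways)) {
    g <- topo$pathways[[nm]]
    sub <- rows[rows$pathway == g$pathway, , drop = FALSE]
    if (nrow(sub) != length(g$pre)) stop("edge list does not match config seed")
    ord <- order(sub$pre_id, sub$post_id)
    topo$pathways[[nm]]$w <- as.numeric(sub$weight[ord])
  }
  topo
}
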