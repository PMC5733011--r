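#' Construct a reservoir network ready for simulation
#'
#' Bundles a topology with neuron, synapse and plasticity parameters and a
#' fresh resting state (membrane potentials at rest, zero homeostatic
#' offsets, empty traces).
#'
#' @param topology a `network_topology` from [build_topology()].
#' @param exc,inh `neuron_params` for the two populations.
#' @param plast `plasticity_params`.
#' @param gains named per-pathway current gains, see [default_gains()].
#' @param gain_ref_n reference reservoir size at which the recurrent gains
#'   were calibrated; recurrent (not input) gains are scaled by
#'   `gain_ref_n / n_reservoir` so per-group recurrent drive is invariant
#'   to reservoir size.
#' @param tau_syn_e,tau_syn_i synaptic current decay constants (ms):
#'   current-based exponential synapses; the excitatory constant (5 ms)
#'   also sets how far a character group's firing tail extends across a
#'   character boundary, the window in which consecutive characters
#'   associate.
#' @return object of class `reservoir_network`.
#' @export
new_network <- function(topology, exc = neuron_params(),
                        inh = neuron_params_inh(),
                        plast = plasticity_params(),
                        gains = default_gains(),
                        tau_syn_e = 5, tau_syn_i = 2,
                        gain_ref_n = 200) {
  stopifnot(inherits(topology, "network_topology"))
  # recurrent fan-in grows with N, so recurrent gains scale as 1/N to keep
  # the calibrated per-group drive invariant across reservoir sizes
  gains <- as.list(gains)
  f <- gain_ref_n / (topology$n_exc + topology$n_inh)
  for (nm in c("e_e", "e_i", "i_e", "i_i")) gains[[nm]] <- gains[[nm]] * f
  net <- structure(list(topology = topology, exc = exc, inh = inh,
                        plast = plast, gains = gains,
                        tau_syn_e = tau_syn_e, tau_syn_i = tau_syn_i,
                        state = NULL),
                   class = "reservoir_network")
  reset_state(net)
}

#' Reset the dynamic state of a network
#'
#' Returns membrane potentials, refractory counters, synaptic currents and
#' traces to rest. The homeostatic thresholds `theta` are preserved unless
#' `reset_theta = TRUE` — theta is the one variable that persists across
#' rest phases and words.
#'
#' @param network a `reservoir_network`.
#' @param reset_theta also zero the homeostatic offsets.
#' @return the network with a fresh state.
#' @export
reset_state <- function(network, reset_theta = is.null(network$state)) {
  topo <- network$topology
  nE <- topo$n_exc; nI <- topo$n_inh; n <- nE + nI
  theta <- if (reset_theta || is.null(network$state)) rep(0, nE)
           else network$state$theta
  network$state <- list(
    v = c(rep(network$exc$v_rest, nE), rep(network$inh$v_rest, nI)),
    theta = theta,
    refrac_remaining = rep(0, n),
    ge = rep(0, n), gi = rep(0, n),
    last_spike_flags = rep(FALSE, n),
    x_pre_in = rep(0, topo$n_inputs),
    x_pre_fast = rep(0, nE), x_post = rep(0, nE))
  network
}

#' @export
print.reservoir_network <- function(x, ...) {
  cat(sprintf("<reservoir_network> %d inputs -> %d E + %d I\n",
              x$topology$n_inputs, x$topology$n_exc, x$topology$n_inh))
  cat(sprintf("  mean w_in = %.4f, mean w_ee = %.4f, mean theta = %.3f mV\n",
              mean(x$topology$pathways$in_e$w),
              mean(x$topology$pathways$e_e$w), mean(x$state$theta)))
  invisible(x)
}

# Internal: engine parameter list.
engine_params <- function(network) {
  list(dt = NULL,  # filled by run_segment
       exc = unclass(network$exc), inh = unclass(network$inh),
       tau_syn_e = network$tau_syn_e, tau_syn_i = network$tau_syn_i,
       gain_in = network$gains$in_e, gain_ee = network$gains$e_e,
       gain_ei = network$gains$e_i, gain_ie = network$gains$i_e,
       gain_ii = network$gains$i_i,
       plast = unclass(network$plast))
}

# Internal: normalize the input argument for the engine.
engine_input <- function(input, n_inputs) {
  if (is.null(input)) {
    list(mode = "rates", rates = rep(0, n_inputs))
  } else if (inherits(input, "spike_raster")) {
    if (input$n_channels != n_inputs) stop("raster channel count mismatch")
    list(mode = "raster", step0 = input$step - 1L, chan0 = input$channel - 1L)
  } else if (inherits(input, "rate_profile")) {
    list(mode = "rates", rates = input$rates)
  } else if (is.numeric(input)) {
    if (length(input) != n_inputs) stop("rate vector length mismatch")
    list(mode = "rates", rates = as.numeric(input))
  } else stop("input must be NULL, a rate vector/profile or a spike_raster")
}

#' Advance a network over one stimulus segment
#'
#' Runs the C++ simulation engine for `n_steps` steps of `dt` ms. Input can
#' be a per-channel rate vector (Hz; Poisson spikes are drawn inside the
#' engine from `seed`), a pre-drawn [encode_poisson()] raster (frozen input
#' realization), or `NULL` for a silent rest segment.
#'
#' @param network a `reservoir_network`.
#' @param input input specification (see above).
#' @param n_steps number of steps.
#' @param dt step (ms).
#' @param plastic enable the two STDP rules (input and E->E).
#' @param eq3_on enable the non-Hebbian decay (only meaningful while
#'   `plastic` learning is on; may be disabled for ablations).
#' @param theta_adapt adapt homeostatic thresholds (disable for inference).
#' @param noise_n0 Gaussian current noise amplitude N0.
#' @param seed engine RNG seed (input Poisson draws and noise); drawn from
#'   R's RNG when `NULL`.
#' @param record_raster also return spike times.
#' @return list with the updated `network`, integer `counts` (spikes per
#'   reservoir neuron), `rate_hz` (population mean rates), and optionally
#'   `raster` (data.frame `step`, `neuron`).
#' @export
run_segment <- function(network, input, n_steps, dt = 0.5,
                        plastic = TRUE, eq3_on = plastic,
                        theta_adapt = plastic, noise_n0 = 0,
                        seed = NULL, record_raster = FALSE) {
  stopifnot(inherits(network, "reservoir_network"))
  topo <- network$topology
  if (is.null(seed)) seed <- as.integer(floor(runif(1) * 2147483647))
  par <- engine_params(network); par$dt <- dt
  flags <- list(plastic_in = isTRUE(plastic), plastic_ee = isTRUE(plastic),
                eq3_on = isTRUE(eq3_on), theta_adapt = isTRUE(theta_adapt),
                record_raster = isTRUE(record_raster),
                noise_n0 = noise_n0, seed = as.double(seed))
  p <- topo$pathways
  res <- cpp_run_segment(network$state, p$in_e, p$e_e, p$e_i, p$i_e, p$i_i,
                         engine_input(input, topo$n_inputs),
                         as.integer(n_steps), par, flags)
  network$state <- res$state
  network$topology$pathways$in_e$w <- res$w_in
  network$topology$pathways$e_e$w <- res$w_ee
  dur_s <- n_steps * dt / 1000
  nE <- topo$n_exc
  out <- list(network = network, counts = res$counts,
              rate_hz = c(exc = mean(res$counts[seq_len(nE)]) / dur_s,
                          inh = mean(res$counts[nE + seq_len(topo$n_inh)]) /
                            dur_s))
  if (record_raster)
    out$raster <- data.frame(step = res$raster_step + 1L,
                             neuron = res$raster_id + 1L)
  out
}

# Internal: dense matrix view of a sparse group (pre x post).
group_dense <- function(g) {
  m <- matrix(0, g$n_pre, g$n_post)
  if (length(g$pre) > 0) m[cbind(g$pre, g$post)] <- g$w
  m
}

#' Pure-R reference simulation of one segment
#'
#' Step-by-step mirror of the C++ engine, written with dense matrices and
#' the exported rule functions' formulas. Supports raster or silent input
#' and no noise (so no RNG is consumed and results are directly comparable
#' to the engine). Used as the in-package correctness oracle; far too slow
#' for real experiments.
#'
#' @inheritParams run_segment
#' @param input a `spike_raster` or `NULL`.
#' @return list with `network`, `counts`.
#' @export
run_segment_r <- function(network, input, n_steps, dt = 0.5,
                          plastic = TRUE, eq3_on = plastic,
                          theta_adapt = plastic) {
  stopifnot(inherits(network, "reservoir_network"))
  topo <- network$topology
  nE <- topo$n_exc; nI <- topo$n_inh; n <- nE + nI
  exc <- network$exc; inh <- network$inh; pl <- network$plast
  gains <- network$gains
  st <- network$state
  p <- topo$pathways
  W_in <- group_dense(p$in_e); W_ee <- group_dense(p$e_e)
  M_in <- W_in * 0; if (length(p$in_e$pre)) M_in[cbind(p$in_e$pre, p$in_e$post)] <- 1
  M_ee <- W_ee * 0; if (length(p$e_e$pre)) M_ee[cbind(p$e_e$pre, p$e_e$post)] <- 1
  W_ei <- group_dense(p$e_i); W_ie <- group_dense(p$i_e); W_ii <- group_dense(p$i_i)

  raster <- if (is.null(input)) NULL else {
    stopifnot(inherits(input, "spike_raster"))
    input
  }
  d_ge <- exp(-dt / network$tau_syn_e); d_gi <- exp(-dt / network$tau_syn_i)
  em_e <- exp(-dt / exc$tau_m); em_i <- exp(-dt / inh$tau_m)
  ik_e <- exc$tau_m * (1 - em_e); ik_i <- inh$tau_m * (1 - em_i)
  counts <- integer(n)
  prev <- st$last_spike_flags
  v_thr_ref <- abs(exc$v_thresh)

  for (t in seq_len(n_steps)) {
    st$ge <- st$ge * d_ge; st$gi <- st$gi * d_gi
    in_spk <- if (is.null(raster)) integer(0) else
      raster$channel[raster$step == t]
    if (length(in_spk) > 0) {
      add <- colSums(W_in[in_spk, , drop = FALSE])
      st$ge[seq_len(nE)] <- st$ge[seq_len(nE)] + gains$in_e * add
    }
    pe <- which(prev[seq_len(nE)]); pi <- which(prev[nE + seq_len(nI)])
    if (length(pe) > 0) {
      st$ge[seq_len(nE)] <- st$ge[seq_len(nE)] +
        gains$e_e * colSums(W_ee[pe, , drop = FALSE])
      st$ge[nE + seq_len(nI)] <- st$ge[nE + seq_len(nI)] +
        gains$e_i * colSums(W_ei[pe, , drop = FALSE])
    }
    if (length(pi) > 0) {
      st$gi[seq_len(nE)] <- st$gi[seq_len(nE)] +
        gains$i_e * colSums(W_ie[pi, , drop = FALSE])
      st$gi[nE + seq_len(nI)] <- st$gi[nE + seq_len(nI)] +
        gains$i_i * colSums(W_ii[pi, , drop = FALSE])
    }
    st$x_pre_in <- st$x_pre_in * exp(-dt / pl$tau_pre_in)
    st$x_pre_fast <- st$x_pre_fast * exp(-dt / pl$tau_pre_fast)
    st$x_post <- st$x_post * exp(-dt / pl$tau_post)

    spikes <- logical(n)
    for (i in seq_len(n)) {
      if (st$refrac_remaining[i] > 0) {
        st$refrac_remaining[i] <- st$refrac_remaining[i] - dt
        next
      }
      is_e <- i <= nE
      I <- st$ge[i] - st$gi[i]
      if (is_e) {
        st$v[i] <- exc$v_rest + (st$v[i] - exc$v_rest) * em_e + I * ik_e
        if (st$v[i] >= exc$v_thresh + st$theta[i]) {
          st$v[i] <- exc$v_reset; st$refrac_remaining[i] <- exc$t_refrac
          spikes[i] <- TRUE
          if (theta_adapt) st$theta[i] <- st$theta[i] + exc$theta_plus
        }
      } else {
        st$v[i] <- inh$v_rest + (st$v[i] - inh$v_rest) * em_i + I * ik_i
        if (st$v[i] >= inh$v_thresh) {
          st$v[i] <- inh$v_reset; st$refrac_remaining[i] <- inh$t_refrac
          spikes[i] <- TRUE
        }
      }
    }
    e_spk <- which(spikes[seq_len(nE)])

    if (plastic && length(e_spk) > 0) {
      for (j in e_spk) {
        sel <- M_in[, j] > 0
        dw <- pl$eta_in * (st$x_pre_in[sel] - pl$offset) *
          (pl$w_max_in - W_in[sel, j])^pl$mu
        W_in[sel, j] <- pmin(pl$w_max_in, pmax(0, W_in[sel, j] + dw))
      }
      for (i in e_spk) {  # depression
        sel <- M_ee[i, ] > 0
        w <- W_ee[i, sel]; xp <- st$x_post[which(sel)]
        w <- w - pl$eta1 * xp * w^pl$mu
        W_ee[i, sel] <- pmax(0, w)
      }
      for (j in e_spk) {  # potentiation
        if (st$x_post[j] <= 0) next
        sel <- M_ee[, j] > 0
        w <- W_ee[sel, j]
        dw <- pl$eta2 * st$x_post[j] * st$x_pre_fast[sel] *
          (pl$w_max_ee - w)^pl$mu
        W_ee[sel, j] <- pmin(pl$w_max_ee, w + dw)
      }
    }
    if (eq3_on) {
      gamma <- pl$k_decay * st$x_post^2 * (1 + st$theta / v_thr_ref)
      if (any(gamma * dt >= 1)) stop("unstable decay step: gamma * dt >= 1")
      for (j in which(gamma > 0)) {
        sel <- M_ee[, j] > 0
        W_ee[sel, j] <- W_ee[sel, j] - gamma[j] * dt * (W_ee[sel, j] - pl$w0)
      }
    }
    if (length(in_spk) > 0) {
      tab <- tabulate(in_spk, nbins = topo$n_inputs)
      st$x_pre_in <- st$x_pre_in + tab
    }
    st$x_pre_fast[e_spk] <- st$x_pre_fast[e_spk] + 1
    st$x_post[e_spk] <- st$x_post[e_spk] + 1
    if (theta_adapt) st$theta <- st$theta * exp(-dt / exc$tau_theta)
    counts <- counts + spikes
    prev <- spikes
  }
  if (plastic && !is.null(p$in_e$colsum_target)) {
    colsum <- colSums(W_in)
    f <- ifelse(colsum > 0, p$in_e$colsum_target / colsum, 1)
    W_in <- pmin(pl$w_max_in, sweep(W_in, 2, f, `*`)) * M_in
  }
  st$last_spike_flags <- prev
  network$state <- st
  network$topology$pathways$in_e$w <- W_in[cbind(p$in_e$pre, p$in_e$post)]
  network$topology$pathways$e_e$w <- W_ee[cbind(p$e_e$pre, p$e_e$post)]
  list(network = network, counts = counts)
}
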