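#' Plasticity parameters
#'
#' Constants of the three learning rules:
#'
#' * Input -> excitatory synapses use a power-law weight-dependent STDP
#'   rule, applied when the post neuron spikes:
#'   `dw = eta_in * (x_pre - offset) * (w_max_in - w)^mu`. The pre trace
#'   `x_pre` decays with `tau_pre_in = 30` ms; a recent pre spike
#'   (`x_pre > offset`) potentiates, otherwise the synapse depresses.
#' * E -> E synapses use an exponential weight-dependent STDP rule with
#'   faster traces (`tau_pre_fast = 10` ms pre, `tau_post = 20` ms post):
#'   depression `-eta1 * x_post * w^mu` on a pre spike, potentiation
#'   `+eta2 * x_post * x_pre_fast * (w_max_ee - w)^mu` on a post spike.
#' * E -> E synapses additionally undergo a non-Hebbian decay toward the
#'   baseline `w0` at every simulation step: `dw/dt = -gamma(t) (w - w0)`
#'   with `gamma = k_decay * x_post^2 * (1 + theta / |v_thresh|)`. The rate
#'   grows with the squared post trace (hyperactivity) and with the
#'   homeostatic threshold, so neurons that fire because of strong feedback
#'   loops have their recurrent weights relaxed, suppressing dominant
#'   attractors.
#'
#' @param eta_in input-synapse learning rate (0.05).
#' @param w_max_in input-synapse weight bound (1.0).
#' @param offset pre-trace threshold separating potentiation from
#'   depression in the input rule (0.4: synapses depress unless the pre
#'   neuron fired within roughly one trace time constant).
#' @param eta1,eta2 E->E depression / potentiation rates (0.002, 0.01).
#' @param w_max_ee E->E weight bound (0.5).
#' @param mu weight-dependence exponent (0.9, shared by both STDP rules).
#' @param w0 decay baseline (0.2).
#' @param k_decay decay proportionality constant (per ms; default 3e-5,
#'   calibrated so a hyperactive post neuron relaxes its recurrent weights
#'   on the few-hundred-millisecond scale once the threshold factor is
#'   included).
#' @param decay_every_step apply the decay at each simulation step (default
#'   `TRUE`).
#' @param tau_pre_in,tau_pre_fast,tau_post trace time constants (ms).
#' @return object of class `plasticity_params`.
#' @export
plasticity_params <- function(eta_in = 0.05, w_max_in = 1.0, offset = 0.4,
                              eta1 = 0.002, eta2 = 0.01, w_max_ee = 0.5,
                              mu = 0.9, w0 = 0.2, k_decay = 3e-5,
                              decay_every_step = TRUE,
                              tau_pre_in = 30, tau_pre_fast = 10,
                              tau_post = 20) {
  for (r in c(eta_in, eta1, eta2))
    if (r < 0 || r > 1) stop("learning rates must lie in [0, 1] (0 disables)")
  if (w0 < 0 || w0 >= w_max_ee) stop("0 <= w0 < w_max_ee required")
  if (mu <= 0 || mu > 1) stop("mu must lie in (0, 1]")
  if (k_decay < 0) stop("k_decay must be >= 0")
  structure(list(eta_in = eta_in, w_max_in = w_max_in, offset = offset,
                 eta1 = eta1, eta2 = eta2, w_max_ee = w_max_ee, mu = mu,
                 w0 = w0, k_decay = k_decay,
                 decay_every_step = isTRUE(decay_every_step),
                 tau_pre_in = tau_pre_in, tau_pre_fast = tau_pre_fast,
                 tau_post = tau_post),
            class = "plasticity_params")
}

#' Create an empty trace set
#'
#' @param n_inputs,n_exc sizes of the input layer and the excitatory
#'   population.
#' @return object of class `trace_set` with `x_pre` (input pre traces,
#'   stored per input neuron: every synapse sharing a pre neuron sees the
#'   same trace), `x_pre_fast` (fast E pre traces) and `x_post` (E post
#'   traces).
#' @export
new_traces <- function(n_inputs, n_exc) {
  structure(list(x_pre = rep(0, n_inputs),
                 x_pre_fast = rep(0, n_exc),
                 x_post = rep(0, n_exc)),
            class = "trace_set")
}

#' Decay-then-increment update of synaptic traces
#'
#' Each trace decays exponentially at its own time constant over `dt`, then
#' increments by exactly 1 for every spike of its neuron at this step.
#'
#' @param traces a `trace_set`.
#' @param input_spikes,exc_spikes logical spike vectors for this step.
#' @param dt elapsed time (ms).
#' @param params `plasticity_params` (supplies the time constants).
#' @return the updated `trace_set`.
#' @export
update_traces <- function(traces, input_spikes, exc_spikes, dt,
                          params = plasticity_params()) {
  stopifnot(inherits(traces, "trace_set"))
  if (dt <= 0) stop("dt must be > 0")
  if (any(traces$x_pre < 0, traces$x_pre_fast < 0, traces$x_post < 0))
    stop("negative trace state")
  traces$x_pre <- traces$x_pre * exp(-dt / params$tau_pre_in) + input_spikes
  traces$x_pre_fast <- traces$x_pre_fast * exp(-dt / params$tau_pre_fast) +
    exc_spikes
  traces$x_post <- traces$x_post * exp(-dt / params$tau_post) + exc_spikes
  traces
}

#' Power-law STDP update for input synapses
#'
#' Weight change applied when the post-synaptic neuron fires:
#' `dw = eta_in * (x_pre - offset) * (w_max_in - w)^mu`. Positive when the
#' pre trace exceeds `offset` (recent pre spike, causal pairing), negative
#' otherwise; the returned weight is clipped to `[0, w_max_in]`.
#'
#' @param w current weight(s) in `[0, w_max_in]`.
#' @param x_pre pre-synaptic trace value(s).
#' @param params `plasticity_params`.
#' @return list with `delta` (unclipped weight change) and `w` (clipped
#'   updated weight).
#' @export
eq1_update <- function(w, x_pre, params = plasticity_params()) {
  if (any(w < 0 | w > params$w_max_in)) stop("w outside [0, w_max_in]")
  delta <- params$eta_in * (x_pre - params$offset) *
    (params$w_max_in - w)^params$mu
  list(delta = delta, w = pmin(params$w_max_in, pmax(0, w + delta)))
}

#' Exponential weight-dependent STDP update for E->E synapses
#'
#' On a pre-synaptic spike the synapse depresses by
#' `eta1 * x_post * w^mu`; on a post-synaptic spike it potentiates by
#' `eta2 * x_post * x_pre_fast * (w_max_ee - w)^mu`. Traces are read before
#' this step's increments, so `x_post` reflects strictly earlier post
#' spikes. Results are clipped to `[0, w_max_ee]`.
#'
#' @param w current weight(s) in `[0, w_max_ee]`.
#' @param x_post post trace value(s) (tau 20 ms).
#' @param x_pre_fast fast pre trace value(s) (tau 10 ms); ignored for the
#'   pre-spike branch.
#' @param event `"pre"` or `"post"`.
#' @param params `plasticity_params`.
#' @return list with `delta` and clipped `w`.
#' @export
eq2_update <- function(w, x_post, x_pre_fast = NULL,
                       event = c("pre", "post"),
                       params = plasticity_params()) {
  if (length(event) != 1 || !event %in% c("pre", "post"))
    stop("unknown event tag: must be \"pre\" or \"post\"")
  if (any(w < 0 | w > params$w_max_ee)) stop("w outside [0, w_max_ee]")
  delta <- if (event == "pre") {
    -params$eta1 * x_post * w^params$mu
  } else {
    if (is.null(x_pre_fast)) stop("x_pre_fast required for post-spike events")
    params$eta2 * x_post * x_pre_fast * (params$w_max_ee - w)^params$mu
  }
  list(delta = delta, w = pmin(params$w_max_ee, pmax(0, w + delta)))
}

#' Non-Hebbian adaptive decay of E->E weights
#'
#' One forward step of `dw/dt = -gamma(t) (w - w0)` with
#' `gamma = k_decay * x_post^2 * (1 + theta / |v_thresh|)`:
#' `w <- w - dt * gamma * (w - w0)`. The update moves the weight toward the
#' baseline `w0` from either side and has its fixed point at `w0`. Silent
#' neurons (`x_post = 0`) decay not at all; hyperactive neurons and neurons
#' with a high homeostatic threshold decay fastest.
#'
#' @param w current weight(s).
#' @param x_post post-synaptic trace value(s).
#' @param theta homeostatic threshold offset(s) (mV).
#' @param params `plasticity_params`.
#' @param dt step (ms).
#' @param v_thresh_ref reference threshold magnitude (mV) used to make the
#'   theta factor dimensionless (default 52, the excitatory threshold
#'   distance scale).
#' @return updated weight(s).
#' @export
eq3_decay <- function(w, x_post, theta = 0, params = plasticity_params(),
                      dt = 0.5, v_thresh_ref = 52) {
  gamma <- params$k_decay * x_post^2 * (1 + theta / abs(v_thresh_ref))
  if (any(gamma * dt >= 1))
    stop("unstable decay step: gamma * dt >= 1")
  w - dt * gamma * (w - params$w0)
}

#' Net weight-change rate: exponential STDP alone vs. combined with decay
#'
#' Diagnostic reproducing the qualitative picture of how the non-Hebbian
#' decay regulates over-potentiation: a single synapse is simulated with
#' independent Poisson pre and post spike trains; for each post rate the
#' mean weight change per second is measured under the exponential STDP
#' rule alone and under STDP combined with the adaptive decay. For weights
#' above baseline and high post rates the combined curve lies strictly
#' below the STDP-only curve (the decay term is negative there), which is
#' what prevents strong attractor dynamics.
#'
#' @param post_rates post-neuron firing rates to sweep (Hz).
#' @param pre_rate fixed pre-neuron rate (Hz).
#' @param w weight at which the rate of change is probed.
#' @param duration_ms simulated duration per rate (ms).
#' @param dt step (ms).
#' @param params `plasticity_params`.
#' @param theta homeostatic offset used in the decay term.
#' @param seed RNG seed.
#' @return data.frame with columns `post_rate`, `dw_stdp`, `dw_combined`
#'   (mean weight change per second).
#' @export
hebbian_vs_combined_rate <- function(post_rates = c(0, 5, 10, 20, 40, 80),
                                     pre_rate = 10, w = 0.4,
                                     duration_ms = 20000, dt = 0.5,
                                     params = plasticity_params(),
                                     theta = 0, seed = 1L) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_steps <- round(duration_ms / dt)
  out <- lapply(post_rates, function(rate) {
    pre_sp <- runif(n_steps) < pre_rate * dt / 1000
    post_sp <- runif(n_steps) < rate * dt / 1000
    run <- function(with_decay) {
      wv <- w; xpost <- 0; xpre <- 0
      for (s in seq_len(n_steps)) {
        xpost <- xpost * exp(-dt / params$tau_post)
        xpre <- xpre * exp(-dt / params$tau_pre_fast)
        if (pre_sp[s]) wv <- eq2_update(wv, xpost, event = "pre",
                                        params = params)$w
        if (post_sp[s]) wv <- eq2_update(wv, xpost, xpre, event = "post",
                                         params = params)$w
        if (with_decay) wv <- eq3_decay(wv, xpost, theta, params, dt)
        xpost <- xpost + post_sp[s]
        xpre <- xpre + pre_sp[s]
      }
      (wv - w) / (duration_ms / 1000)
    }
    c(dw_stdp = run(FALSE), dw_combined = run(TRUE))
  })
  data.frame(post_rate = post_rates,
             dw_stdp = vapply(out, `[[`, numeric(1), "dw_stdp"),
             dw_combined = vapply(out, `[[`, numeric(1), "dw_combined"))
}

#' Gini coefficient of a weight vector
#'
#' Concentration measure used to quantify "weight crowding": STDP without
#' the non-Hebbian decay over-potentiates synapses inside feedback loops,
#' concentrating mass on few weights (higher Gini), while the combined rule
#' keeps the distribution homogeneous.
#'
#' @param w non-negative weights.
#' @return Gini coefficient in \[0, 1\].
#' @export
weight_gini <- function(w) {
  if (any(w < 0)) stop("weights must be non-negative")
  w <- sort(as.numeric(w))
  n <- length(w)
  if (n == 0 || sum(w) == 0) return(0)
  sum((2 * seq_len(n) - n - 1) * w) / (n * sum(w))
}
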