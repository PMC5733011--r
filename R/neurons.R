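#' LIF neuron parameters
#'
#' Constants of the leaky integrate-and-fire model with a homeostatic
#' adaptive threshold. A neuron spikes when its membrane potential reaches
#' `v_thresh + theta` (theta is the per-neuron homeostatic offset, always 0
#' for inhibitory neurons), then resets to `v_reset` and is refractory for
#' `t_refrac` ms. `theta` grows by `theta_plus` on every spike and decays
#' exponentially with constant `tau_theta`, so chronically active neurons
#' become harder to drive and no single neuron dominates the population
#' response.
#'
#' Defaults follow standard unsupervised-SNN settings: excitatory neurons
#' `v_rest = v_reset = -65`, `v_thresh = -52` mV, `tau_m = 100` ms,
#' `t_refrac = 5` ms; inhibitory neurons are faster and have no homeostasis.
#' The homeostatic constants (`theta_plus = 0.01` mV, `tau_theta = 3e5` ms)
#' give an equilibrium threshold proportional to a neuron's firing rate and
#' duty cycle, equalizing duty across the population while leaving winner
#' groups firing at the tens of Hz the fast STDP traces require; see the
#' methods vignette for the calibration.
#'
#' @param v_rest,v_reset,v_thresh potentials (mV), `v_reset < v_thresh`.
#' @param tau_m membrane time constant (ms), > 0.
#' @param t_refrac absolute refractory period (ms).
#' @param theta_plus homeostatic threshold increment per spike (mV); must be
#'   0 for inhibitory neurons.
#' @param tau_theta decay constant of theta (ms).
#' @param population_tag `"excitatory"` or `"inhibitory"`.
#' @return object of class `neuron_params`.
#' @export
neuron_params <- function(v_rest = -65, v_reset = -65, v_thresh = -52,
                          tau_m = 100, t_refrac = 5,
                          theta_plus = 0.01, tau_theta = 3e5,
                          population_tag = c("excitatory", "inhibitory")) {
  population_tag <- match.arg(population_tag)
  if (!(v_reset < v_thresh)) stop("v_reset must be < v_thresh")
  if (tau_m <= 0) stop("tau_m must be > 0")
  if (theta_plus < 0) stop("theta_plus must be >= 0")
  if (population_tag == "inhibitory" && theta_plus != 0)
    stop("homeostasis applies to excitatory neurons only (theta_plus must be 0)")
  structure(list(v_rest = v_rest, v_reset = v_reset, v_thresh = v_thresh,
                 tau_m = tau_m, t_refrac = t_refrac,
                 theta_plus = theta_plus, tau_theta = tau_theta,
                 population_tag = population_tag),
            class = "neuron_params")
}

#' Default inhibitory neuron parameters
#' @inheritParams neuron_params
#' @export
neuron_params_inh <- function(v_rest = -60, v_reset = -60, v_thresh = -40,
                              tau_m = 10, t_refrac = 2) {
  neuron_params(v_rest, v_reset, v_thresh, tau_m, t_refrac,
                theta_plus = 0, tau_theta = 1e7,
                population_tag = "inhibitory")
}

#' Simulation timing parameters
#'
#' @param dt simulation step (ms); all durations must be integer multiples.
#' @param presentation_ms stimulus presentation duration (default 350 ms).
#' @param rest_ms inter-word rest duration with silent inputs (default 300
#'   ms), during which all state except the adaptive threshold relaxes.
#' @param noise_amplitude Gaussian current noise amplitude N0 (same units as
#'   summed synaptic current).
#' @param rng_seed integer seed.
#' @return object of class `sim_params`.
#' @export
sim_params <- function(dt = 0.5, presentation_ms = 350, rest_ms = 300,
                       noise_amplitude = 0, rng_seed = 1L) {
  if (dt <= 0) stop("dt must be > 0")
  if (noise_amplitude < 0) stop("noise_amplitude must be >= 0")
  for (d in c(presentation_ms, rest_ms))
    if (abs(d / dt - round(d / dt)) > 1e-9)
      stop("durations must be integer multiples of dt")
  structure(list(dt = dt, presentation_ms = presentation_ms,
                 rest_ms = rest_ms, noise_amplitude = noise_amplitude,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_params")
}

#' Create a reservoir state at rest
#'
#' @param n_exc,n_inh population sizes.
#' @param exc,inh `neuron_params` for the two populations.
#' @return object of class `reservoir_state` with membrane potentials `v`,
#'   homeostatic offsets `theta` (excitatory only), refractory countdowns,
#'   synaptic currents `ge`/`gi` and the last step's spike flags.
#' @export
new_state <- function(n_exc, n_inh, exc = neuron_params(),
                      inh = neuron_params_inh()) {
  n <- n_exc + n_inh
  structure(list(v = c(rep(exc$v_rest, n_exc), rep(inh$v_rest, n_inh)),
                 theta = rep(0, n_exc),
                 refrac_remaining = rep(0, n),
                 ge = rep(0, n), gi = rep(0, n),
                 last_spike_flags = rep(FALSE, n),
                 n_exc = as.integer(n_exc), n_inh = as.integer(n_inh)),
            class = "reservoir_state")
}

#' Advance the LIF membrane dynamics by one step
#'
#' Exponential leak toward `v_rest` plus integration of the (piecewise
#' constant over the step) input current: `v <- v_rest + (v - v_rest) *
#' exp(-dt/tau_m) + I * tau_m * (1 - exp(-dt/tau_m))`. A neuron spikes iff it
#' is not refractory and `v >= v_thresh + theta` (theta = 0 for inhibitory
#' neurons); spiking neurons reset to `v_reset`, enter the refractory
#' period, and have theta incremented by `theta_plus`. Theta decays
#' exponentially with `tau_theta` every step.
#'
#' This is the reference (pure R) implementation of one integration step;
#' the C++ engine used by [run_segment()] performs the identical update.
#'
#' @param state a `reservoir_state`.
#' @param input_current current vector over all reservoir neurons (mV/ms).
#' @param exc,inh `neuron_params` per population.
#' @param dt step (ms).
#' @param theta_adapt if `FALSE`, theta is frozen (inference mode).
#' @return list with the updated `state` and logical `spikes`.
#' @export
step_neurons <- function(state, input_current, exc = neuron_params(),
                         inh = neuron_params_inh(), dt = 0.5,
                         theta_adapt = TRUE) {
  stopifnot(inherits(state, "reservoir_state"))
  n <- state$n_exc + state$n_inh
  if (length(input_current) != n) stop("current vector length mismatch")
  if (any(!is.finite(input_current))) stop("non-finite input current")
  if (dt <= 0) stop("dt must be > 0")
  eidx <- seq_len(state$n_exc); iidx <- state$n_exc + seq_len(state$n_inh)

  v_rest <- c(rep(exc$v_rest, state$n_exc), rep(inh$v_rest, state$n_inh))
  v_reset <- c(rep(exc$v_reset, state$n_exc), rep(inh$v_reset, state$n_inh))
  tau_m <- c(rep(exc$tau_m, state$n_exc), rep(inh$tau_m, state$n_inh))
  t_ref <- c(rep(exc$t_refrac, state$n_exc), rep(inh$t_refrac, state$n_inh))
  thresh <- c(rep(exc$v_thresh, state$n_exc) + state$theta,
              rep(inh$v_thresh, state$n_inh))

  refrac <- state$refrac_remaining > 0
  em <- exp(-dt / tau_m)
  v <- state$v
  v[!refrac] <- v_rest[!refrac] + (v[!refrac] - v_rest[!refrac]) * em[!refrac] +
    input_current[!refrac] * tau_m[!refrac] * (1 - em[!refrac])
  state$refrac_remaining[refrac] <- pmax(0, state$refrac_remaining[refrac] - dt)

  spikes <- !refrac & v >= thresh
  v[spikes] <- v_reset[spikes]
  state$refrac_remaining[spikes] <- t_ref[spikes]
  state$v <- v
  if (theta_adapt) {
    state$theta[spikes[eidx]] <- state$theta[spikes[eidx]] + exc$theta_plus
    state$theta <- state$theta * exp(-dt / exc$tau_theta)
  }
  state$last_spike_flags <- spikes
  list(state = state, spikes = spikes)
}

#' Add Gaussian current noise
#'
#' Implements the noisy post-synaptic current `I_post = sum_i W_i Input_i +
#' N0 * randn(i)`: each neuron receives an independent standard-normal draw
#' scaled by the noise amplitude `N0`, every step. Draws come from R's RNG,
#' so results are reproducible under a fixed seed.
#'
#' @param currents current vector.
#' @param n0 noise amplitude, >= 0 (same units as the summed current).
#' @return the noisy current vector.
#' @export
inject_noise <- function(currents, n0) {
  if (!is.numeric(n0) || length(n0) != 1 || is.na(n0) || n0 < 0)
    stop("noise amplitude N0 must be a single number >= 0")
  if (n0 == 0) return(currents)
  currents + n0 * rnorm(length(currents))
}

#' Accumulate synaptic current from pre-synaptic spikes
#'
#' Current-based exponential synapses: excitatory pathways add to a positive
#' current trace `ge` (decay constant `tau_syn_e`, default 1 ms), inhibitory
#' pathways to `gi` (`tau_syn_i`, default 2 ms); the net current delivered
#' to the membrane is `ge - gi`. Each pre-synaptic spike increments the
#' post-neuron's trace by `gain * w`. Traces decay first, then this step's
#' spikes are delivered.
#'
#' @param state a `reservoir_state` (its `ge`/`gi` fields are updated).
#' @param spikes_pre named list of logical pre-spike vectors, keyed by
#'   pathway name (`in_e`, `e_e`, `e_i`, `i_e`, `i_i`).
#' @param pathways named list of `synapse_group`s matching `spikes_pre`.
#' @param gains named numeric vector of per-pathway current gains.
#' @param tau_syn_e,tau_syn_i synaptic decay constants (ms).
#' @param dt step (ms).
#' @return the updated `reservoir_state`.
#' @export
accumulate_synaptic_current <- function(state, spikes_pre, pathways,
                                        gains = default_gains(),
                                        tau_syn_e = 1, tau_syn_i = 2,
                                        dt = 0.5) {
  stopifnot(inherits(state, "reservoir_state"))
  nE <- state$n_exc
  state$ge <- state$ge * exp(-dt / tau_syn_e)
  state$gi <- state$gi * exp(-dt / tau_syn_i)
  for (nm in names(spikes_pre)) {
    g <- pathways[[nm]]
    if (is.null(g)) stop("unknown pathway: ", nm)
    sp <- spikes_pre[[nm]]
    if (length(sp) != g$n_pre) stop("pre-spike vector length mismatch for ", nm)
    if (any(g$w < 0)) stop("negative stored weights in ", nm)
    if (!any(sp)) next
    sel <- sp[g$pre]
    if (!any(sel)) next
    contrib <- gains[[nm]] * g$w[sel]
    post <- g$post[sel]
    inhib <- nm %in% c("i_e", "i_i")
    post_off <- if (nm %in% c("e_i", "i_i")) nE else 0L
    acc <- tapply(contrib, post, sum)
    ids <- post_off + as.integer(names(acc))
    if (inhib) state$gi[ids] <- state$gi[ids] + as.numeric(acc)
    else state$ge[ids] <- state$ge[ids] + as.numeric(acc)
  }
  state
}

#' Default per-pathway current gains
#'
#' Gains convert stored (unitless) weights into current amplitudes (mV/ms
#' per spike, before the synaptic-trace integration). They are the declared
#' unit choice of the package, calibrated once to the operating point the
#' method requires: the untrained reservoir exceeds the 15-20 Hz probe
#' floor under ~45 Hz Poisson input; the E->I gain recruits the inhibitory
#' population from a single active character group without driving it to
#' its refractory ceiling; the I->E return gives soft winner-take-all
#' competition; and the E->E gain makes learned associations strong enough
#' to prime successor groups. See the methods vignette.
#'
#' @return named numeric vector with entries `in_e`, `e_e`, `e_i`, `i_e`,
#'   `i_i`.
#' @export
default_gains <- function() {
  # fixed-pathway weight means (variance-matched draws): e_i ~ 0.157,
  # i_e ~ 0.143, i_i ~ 0.25; gains keep the mean synaptic charge of the
  # calibrated operating point (products 3.0, 2.5 and 0.4 respectively)
  c(in_e = 2.0, e_e = 10.0, e_i = 19.0, i_e = 17.4, i_i = 1.6)
}
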