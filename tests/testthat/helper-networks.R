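# Shared fixtures: small networks and corpora built in code.

tiny_config <- function(n_inputs = 64L, n_reservoir = 50L, seed = 42L)
  topology_config(n_inputs = n_inputs, n_reservoir = n_reservoir,
                  rng_seed = seed)

tiny_network <- function(seed = 42L, ...)
  new_network(build_topology(tiny_config(seed = seed)), ...)

# Brute-force trace oracle: recompute a trace from the full spike history
# (decay-then-increment; value as of just after step `t`).
trace_from_history <- function(spike_steps, t, tau, dt) {
  s <- spike_steps[spike_steps <= t]
  if (length(s) == 0) return(0)
  sum(exp(-(t - s) * dt / tau))
}
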