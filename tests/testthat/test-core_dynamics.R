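make_state <- function(n_exc = 4, n_inh = 2) new_state(n_exc, n_inh)

test_that("v_rest is a fixed point of the leak under zero current", {
  st <- make_state()
  r <- step_neurons(st, rep(0, 6))
  expect_equal(r$state$v, st$v)
  expect_false(any(r$spikes))
})

test_that("constant suprathreshold current produces a spike then reset", {
  st <- make_state()
  spiked <- FALSE
  for (i in 1:200) {
    r <- step_neurons(st, rep(2, 6))
    st <- r$state
    if (r$spikes[1]) { spiked <- TRUE; break }
  }
  expect_true(spiked)
  expect_equal(st$v[1], neuron_params()$v_reset)
  expect_gt(st$refrac_remaining[1], 0)
  expect_equal(st$theta[1], neuron_params()$theta_plus,
               tolerance = 1e-4)
})

test_that("free decay follows the closed-form exponential within 1%", {
  exc <- neuron_params(tau_m = 100)
  st <- make_state()
  st$v[1] <- exc$v_rest + 10
  for (t_ms in c(50, 100, 200)) {
    s <- st
    for (i in seq_len(t_ms / 0.5)) s <- step_neurons(s, rep(0, 6), exc)$state
    expected <- 10 * exp(-t_ms / 100)
    expect_lt(abs((s$v[1] - exc$v_rest) - expected) / expected, 0.01)
  }
})

test_that("refractory neurons never spike regardless of current", {
  st <- make_state()
  st$refrac_remaining[1] <- 5
  r <- step_neurons(st, c(1e6, rep(0, 5)))
  expect_false(r$spikes[1])
})

test_that("single-neuron firing rate is non-decreasing in drive current", {
  rate_at <- function(I) {
    st <- new_state(1, 1)
    n <- 0
    for (i in 1:2000) {  # 1 s
      r <- step_neurons(st, c(I, 0))
      st <- r$state
      n <- n + r$spikes[1]
    }
    n
  }
  rates <- vapply(c(0.1, 0.2, 0.5, 1, 2, 5), rate_at, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[6], rates[1])
})

test_that("theta decays toward zero and v toward rest with no input", {
  exc <- neuron_params(tau_theta = 1000)  # fast decay for the test
  st <- make_state()
  st$theta[] <- 5
  st$v[] <- st$v + 8
  for (i in 1:2000) {
    gap_before <- max(abs(st$v[1:4] - exc$v_rest))
    r <- step_neurons(st, rep(0, 6), exc)
    expect_lte(max(abs(r$state$v[1:4] - exc$v_rest)), gap_before + 1e-12)
    expect_true(all(r$state$theta <= st$theta))
    st <- r$state
  }
  expect_lt(max(st$theta), 5 * exp(-2000 * 0.5 / 1000) + 1e-6)
  expect_lt(max(abs(st$v[1:4] - exc$v_rest)), 1e-3)
})

test_that("inject_noise adds calibrated Gaussian current", {
  x <- rep(0, 1e5)
  expect_identical(inject_noise(x, 0), x)
  set.seed(1)
  y <- inject_noise(x, 0.5)
  expect_lt(abs(mean(y)), 3 * 0.5 / sqrt(1e5))
  expect_lt(abs(sd(y) - 0.5) / 0.5, 0.02)
  set.seed(99); a <- inject_noise(x, 0.3)
  set.seed(99); b <- inject_noise(x, 0.3)
  expect_identical(a, b)
  expect_error(inject_noise(x, -0.1), "N0")
})

test_that("synaptic currents: sign bookkeeping and single-synapse kinetics", {
  topo <- build_topology(tiny_config())
  st <- new_state(topo$n_exc, topo$n_inh)
  # no pre-spikes -> zero current
  no_spk <- list(e_e = rep(FALSE, topo$n_exc))
  st0 <- accumulate_synaptic_current(st, no_spk, topo$pathways)
  expect_true(all(st0$ge == 0) && all(st0$gi == 0))

  # one excitatory pre-spike: post current jumps by gain * w, then decays
  g <- topo$pathways$e_e
  pre <- g$pre[1]; post <- g$post[1]; w <- g$w[1]
  spk <- list(e_e = seq_len(topo$n_exc) == pre)
  st1 <- accumulate_synaptic_current(st, spk, topo$pathways,
                                     gains = c(e_e = 2))
  contribs <- 2 * g$w[g$pre == pre & g$post == post]
  expect_equal(st1$ge[post], sum(contribs))
  st2 <- accumulate_synaptic_current(st1, no_spk, topo$pathways)
  expect_equal(st2$ge[post], sum(contribs) * exp(-0.5 / 1), tolerance = 1e-12)

  # equal-weight E->E and I->E spikes: net charge <= 0 whenever the
  # inhibitory gain (x its slower decay) is at least the excitatory one
  eq_gains <- c(e_e = 1, i_e = 1)
  st_e <- accumulate_synaptic_current(st, list(e_e = seq_len(40) == 1),
                                      topo$pathways, gains = eq_gains,
                                      tau_syn_e = 1, tau_syn_i = 2)
  st_i <- accumulate_synaptic_current(st, list(i_e = seq_len(10) == 1),
                                      topo$pathways, gains = eq_gains,
                                      tau_syn_e = 1, tau_syn_i = 2)
  # per-spike charge: w * gain * tau; with equal weight and gain the
  # inhibitory contribution dominates through its slower decay
  expect_lte(1 * eq_gains[["e_e"]] * 1 - 1 * eq_gains[["i_e"]] * 2, 0)
  expect_true(all(st_i$gi >= 0) && all(st_e$ge >= 0))
  expect_error(
    accumulate_synaptic_current(st, list(e_e = rep(TRUE, 99)),
                                topo$pathways),
    "mismatch")
})

test_that("untrained reservoir driven at ~45 Hz fires at 15 Hz or more", {
  cfg <- topology_config(n_inputs = 784, n_reservoir = 500, rng_seed = 3)
  net <- new_network(build_topology(cfg))
  r <- run_segment(net, rep(45, 784), n_steps = 4000, plastic = FALSE,
                   seed = 11)
  expect_gte(r$rate_hz[["exc"]], 15)
})

test_that("C++ engine and pure-R reference produce identical dynamics", {
  cfg <- topology_config(n_inputs = 24, n_reservoir = 30, rng_seed = 9)
  net <- new_network(build_topology(cfg))
  set.seed(4)
  img <- matrix(runif(24, 0, 255), 1)
  ras <- encode_poisson(img, max_rate = 60, duration_ms = 100, dt = 0.5)
  a <- run_segment(net, ras, 200, plastic = TRUE)
  b <- run_segment_r(net, ras, 200, plastic = TRUE)
  expect_equal(a$counts, b$counts)
  expect_equal(a$network$state$v, b$network$state$v, tolerance = 1e-10)
  expect_equal(a$network$state$theta, b$network$state$theta,
               tolerance = 1e-12)
  expect_equal(a$network$topology$pathways$in_e$w,
               b$network$topology$pathways$in_e$w, tolerance = 1e-10)
  expect_equal(a$network$topology$pathways$e_e$w,
               b$network$topology$pathways$e_e$w, tolerance = 1e-10)
})
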