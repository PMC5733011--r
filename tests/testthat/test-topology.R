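test_that("population split matches the 4:1 cortical ratio", {
  cfg <- topology_config(n_inputs = 784, n_reservoir = 500, rng_seed = 1)
  topo <- build_topology(cfg)
  expect_equal(topo$n_exc, 400L)
  expect_equal(topo$n_inh, 100L)
  cfg2 <- topology_config(n_reservoir = 200, rng_seed = 1)
  expect_equal(cfg2$n_exc, 160L)
  expect_equal(cfg2$n_inh, 40L)
})

test_that("balance rule p_ee < p_ei * p_ie is checked and enforced", {
  pass <- check_balance(list(p_ee = 0.1, p_ei = 0.3, p_ie = 0.4))
  expect_true(pass$pass)
  expect_equal(pass$lhs, 0.1)
  expect_equal(pass$rhs, 0.12)
  fail <- check_balance(list(p_ee = 0.2, p_ei = 0.3, p_ie = 0.4))
  expect_false(fail$pass)
  # p_ee = 0 always passes for nonzero partners
  expect_true(check_balance(list(p_ee = 0, p_ei = 0.01, p_ie = 0.01))$pass)
  expect_error(topology_config(p_ee = 0.2, p_ei = 0.3, p_ie = 0.4),
               "balance")
  expect_error(check_balance(list(p_ee = -0.1, p_ei = 0.3, p_ie = 0.4)),
               "\\[0, 1\\]")
})

test_that("realized densities fall within 3 binomial sd of their targets", {
  ee_edges <- 0; indeg <- integer(0)
  for (seed in 1:5) {
    cfg <- topology_config(n_inputs = 784, n_reservoir = 200,
                           rng_seed = seed)
    topo <- build_topology(cfg)
    ee_edges <- ee_edges + length(topo$pathways$e_e$pre)
    indeg <- c(indeg, tabulate(topo$pathways$in_e$post,
                               nbins = topo$n_exc))
  }
  n_pairs <- 5 * 160 * 159  # no self-connections
  expect_lt(abs(ee_edges - n_pairs * 0.1),
            3 * sqrt(n_pairs * 0.1 * 0.9))
  # per-neuron In->E in-degree mean near 784 * 0.3 = 235.2
  expect_lt(abs(mean(indeg) - 235.2),
            3 * sqrt(784 * 0.3 * 0.7 / length(indeg)))
})

test_that("no self-connections in recurrent pathways; plastic flags correct", {
  topo <- build_topology(tiny_config())
  expect_false(any(topo$pathways$e_e$pre == topo$pathways$e_e$post))
  expect_false(any(topo$pathways$i_i$pre == topo$pathways$i_i$post))
  plastic <- vapply(topo$pathways, `[[`, logical(1), "plastic")
  expect_equal(unname(plastic),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))  # in_e, e_e only
})

test_that("builds are deterministic per seed and differ across seeds", {
  t1 <- build_topology(tiny_config(seed = 7))
  t2 <- build_topology(tiny_config(seed = 7))
  t3 <- build_topology(tiny_config(seed = 8))
  expect_identical(t1$pathways$e_e$pre, t2$pathways$e_e$pre)
  expect_identical(t1$pathways$in_e$w, t2$pathways$in_e$w)
  expect_false(identical(t1$pathways$e_e$pre, t3$pathways$e_e$pre))
})

test_that("p_in = 0 gives an empty input pathway", {
  cfg <- topology_config(n_inputs = 16, n_reservoir = 20, p_in = 0,
                         rng_seed = 1)
  topo <- build_topology(cfg)
  expect_equal(length(topo$pathways$in_e$pre), 0L)
})

test_that("input weight budget: column sums equal the normalization target", {
  topo <- build_topology(tiny_config(), w_norm_mean = 0.2)
  g <- topo$pathways$in_e
  sums <- tapply(g$w, g$post, sum)
  fanin <- tabulate(g$post, nbins = g$n_post)
  expect_equal(as.numeric(sums),
               as.numeric(0.2 * fanin[as.integer(names(sums))]),
               tolerance = 1e-10)
})

test_that("compose_signed_matrix matches naive edge-by-edge assembly", {
  topo <- build_topology(tiny_config())
  W <- compose_signed_matrix(topo)
  nE <- topo$n_exc
  # naive oracle
  W2 <- matrix(0, 50, 50)
  p <- topo$pathways
  for (k in seq_along(p$e_e$pre))
    W2[p$e_e$post[k], p$e_e$pre[k]] <- p$e_e$w[k]
  for (k in seq_along(p$e_i$pre))
    W2[nE + p$e_i$post[k], p$e_i$pre[k]] <- p$e_i$w[k]
  for (k in seq_along(p$i_e$pre))
    W2[p$i_e$post[k], nE + p$i_e$pre[k]] <- -p$i_e$w[k]
  for (k in seq_along(p$i_i$pre))
    W2[nE + p$i_i$post[k], nE + p$i_i$pre[k]] <- -p$i_i$w[k]
  expect_equal(W, W2)
  # excitatory columns nonnegative, inhibitory columns nonpositive
  expect_true(all(W[, seq_len(nE)] >= 0))
  expect_true(all(W[, nE + seq_len(topo$n_inh)] <= 0))
})

test_that("single E->E edge appears as exactly one positive entry", {
  topo <- build_topology(tiny_config())
  topo$pathways$e_e$w[] <- 0
  topo$pathways$e_e$w[1] <- 0.3
  topo$pathways$e_i$w[] <- 0
  topo$pathways$i_e$w[] <- 0
  topo$pathways$i_i$w[] <- 0
  W <- compose_signed_matrix(topo)
  expect_equal(sum(W != 0), 1L)
  expect_equal(max(W), 0.3)
  ev <- eigen_spectrum(0 * W)
  expect_equal(ev$spectral_radius, 0)
})

test_that("topology round-trips through the edge-list CSV", {
  topo <- build_topology(tiny_config(n_inputs = 16, n_reservoir = 20))
  path <- tempfile(fileext = ".csv")
  write_topology_csv(topo, path)
  topo2 <- read_topology_csv(path)
  expect_equal(topo$pathways$e_e$w, topo2$pathways$e_e$w)
  expect_equal(topo$pathways$in_e$pre, topo2$pathways$in_e$pre)
  unlink(c(path, paste0(path, ".json")))
})
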