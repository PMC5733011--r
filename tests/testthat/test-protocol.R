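# Hand-wired fixture: three groups respond to the L, O, T images (chosen
# for their nearly disjoint glyphs) via crafted input weights in the
# rate-sensitive regime; a secondary drive ladder (O responds weakly to
# L's image, T to O's) makes the top-2 label walk L -> O -> T, and
# nothing is primed after T, so the top-2 gap jumps past the threshold
# and the trial terminates.
word_fixture <- function(w_primary = 0.05, w_secondary = 0.03) {
  cfg <- topology_config(n_inputs = 784, n_reservoir = 60, rng_seed = 21)
  topo <- build_topology(cfg)
  corpus <- make_charset("LOT", n_train_reps = 1, n_test_reps = 5,
                         variability = glyph_variability(scale = 0),
                         rng_seed = 1)
  groups <- list(L = 1:16, O = 17:32, T = 33:48)
  on_px <- lapply(corpus$templates, function(tm) which(as.numeric(tm) > 0))
  g <- topo$pathways$in_e
  w <- numeric(length(g$pre))
  for (lab in names(groups))
    w[g$post %in% groups[[lab]] & g$pre %in% on_px[[lab]]] <- w_primary
  sel <- g$post %in% groups$O & g$pre %in% on_px$L
  w[sel] <- pmax(w[sel], w_secondary)
  sel <- g$post %in% groups$T & g$pre %in% on_px$O
  w[sel] <- pmax(w[sel], w_secondary)
  topo$pathways$in_e$w <- w
  topo$pathways$in_e$colsum_target <- NULL
  topo$pathways$e_e$w[] <- 0
  topo$pathways$i_e$w[] <- 0
  topo$pathways$i_i$w[] <- 0
  net <- new_network(topo)
  resp <- matrix(0, 48, 3, dimnames = list(NULL, c("L", "O", "T")))
  resp[groups$L, "L"] <- 1; resp[groups$O, "O"] <- 1; resp[groups$T, "T"] <- 1
  list(net = net, asg = assignment_from_response(resp), corpus = corpus)
}

test_that("argmax assignment matches hand computation on a printed table", {
  resp <- matrix(c(5, 0.1, 2,    # label X
                   1, 4,   2),   # label Y
                 nrow = 3, dimnames = list(NULL, c("X", "Y")))
  asg <- assignment_from_response(resp)
  expect_equal(unname(asg$neuron_label), c("X", "Y", "X"))  # tie -> lowest
  expect_equal(unname(asg$group_sizes), c(2L, 1L))
  expect_length(asg$unassignable, 0)
})

test_that("all-zero responses leave every label unassignable", {
  resp <- matrix(0, 4, 2, dimnames = list(NULL, c("A", "B")))
  expect_warning(asg <- assignment_from_response(resp), "no responsive")
  expect_true(all(is.na(asg$neuron_label)))
  expect_equal(asg$unassignable, c("A", "B"))
  expect_error(group_rates(rep(0, 4), asg), "empty assignment")
})

test_that("group_rates tallies counts and is invariant to group size", {
  resp <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4,
                 dimnames = list(NULL, c("A", "B")))
  asg <- assignment_from_response(resp)
  counts <- c(3L, 5L, 2L, 2L)
  gr <- group_rates(counts, asg)
  expect_equal(unname(gr), c(4, 2))
  expect_equal(unname(group_rates(integer(4), asg)), c(0, 0))
  # duplicating every neuron (same counts) leaves the per-neuron mean alone
  asg2 <- assignment_from_response(rbind(resp, resp))
  expect_equal(group_rates(c(counts, counts), asg2), gr)
})

test_that("hand-wired ladder network generates its word end to end", {
  fx <- word_fixture()
  set.seed(5)
  g <- generate_sequence(fx$net, fx$asg, "L", fx$corpus)
  expect_equal(g$sequence, "LOT")
  expect_equal(g$termination, "gap-threshold")
  expect_true(all(g$evidence$gap >= 0))
  expect_gt(g$evidence$gap[3], 10)
  expect_lt(max(g$evidence$gap[1:2]), 10)
})

test_that("generation degenerate cases: zero threshold and length cap", {
  fx <- word_fixture()
  set.seed(5)
  g0 <- generate_sequence(fx$net, fx$asg, "L", fx$corpus, gap_threshold = 0)
  expect_equal(g0$sequence, "L")
  expect_equal(g0$termination, "gap-threshold")
  set.seed(5)
  g2 <- generate_sequence(fx$net, fx$asg, "L", fx$corpus, length_cap = 2)
  expect_lte(nchar(g2$sequence), 2)
  expect_error(generate_sequence(fx$net, fx$asg, "L", fx$corpus,
                                 gap_threshold = -1), ">= 0")
})

test_that("evaluation arithmetic matches the worked example", {
  rep <- evaluate_generation(c("CAT", "COT", "CRAFT"),
                             c("CAT", "CAT", "CRT"))
  expect_equal(rep$n_correct, 2L)
  expect_equal(rep$accuracy, 200 / 3, tolerance = 1e-10)
  expect_equal(names(rep$garbage), "CRT")
  expect_equal(as.integer(rep$word_counts[c("CAT", "COT", "CRAFT")]),
               c(2L, 0L, 0L))
  all_good <- evaluate_generation("CAT", c("CAT", "CAT"))
  expect_equal(all_good$accuracy, 100)
  none <- evaluate_generation(character(0), c("CAT"))
  expect_equal(none$accuracy, 0)
  expect_equal(length(none$garbage), 1L)
  expect_error(evaluate_generation("CAT", character(0)), "nonempty")
})

test_that("training changes nothing when all rates and the decay are zero", {
  corpus <- make_charset("AT", n_train_reps = 2, n_test_reps = 2,
                         rng_seed = 3)
  cfg <- topology_config(n_inputs = 784, n_reservoir = 40, rng_seed = 2)
  net <- new_network(build_topology(cfg),
                     plast = plasticity_params(eta_in = 0, eta1 = 0,
                                               eta2 = 0, k_decay = 0))
  tr <- train_reservoir(net, corpus, seed = 4, log_every = 1)
  expect_equal(tr$network$topology$pathways$in_e$w,
               net$topology$pathways$in_e$w, tolerance = 1e-12)
  expect_equal(tr$network$topology$pathways$e_e$w,
               net$topology$pathways$e_e$w, tolerance = 1e-12)
})

test_that("training log is reproducible under a fixed seed", {
  corpus <- make_charset("AT", n_train_reps = 2, n_test_reps = 2,
                         rng_seed = 3)
  cfg <- topology_config(n_inputs = 784, n_reservoir = 40, rng_seed = 2)
  net <- new_network(build_topology(cfg))
  t1 <- train_reservoir(net, corpus, seed = 9, log_every = 1)
  t2 <- train_reservoir(net, corpus, seed = 9, log_every = 1)
  expect_identical(t1$log, t2$log)
  expect_identical(t1$network$topology$pathways$in_e$w,
                   t2$network$topology$pathways$in_e$w)
})
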