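#' Train a reservoir on a word corpus
#'
#' The two-phase learning loop: word instances are presented in randomized
#' order; each character of a word is Poisson-encoded and shown for the
#' presentation duration with all three rules active simultaneously (the
#' power-law STDP on input synapses, the exponential STDP and the
#' non-Hebbian decay on E->E synapses), then a silent rest phase lets all
#' state except the adaptive threshold relax. Membrane potentials are not
#' reset between the characters of a word, which is what lets the E->E
#' connections pick up the correlation between consecutive characters.
#'
#' @param network a `reservoir_network`.
#' @param corpus a [make_charset()] corpus.
#' @param sim a [sim_params()].
#' @param max_rate Poisson encoder full-intensity rate (Hz).
#' @param epochs passes over the shuffled corpus (default 1).
#' @param eq3_on enable the non-Hebbian decay (disable for ablations).
#' @param log_every record a log row every this many words.
#' @param abort_rate_hz abort with a diagnostic if the excitatory
#'   population rate of a presentation exceeds this (divergence guard).
#' @param seed RNG seed for presentation order and Poisson draws.
#' @return list with the trained `network` and a `log` data.frame
#'   (`word_index`, `word`, `exc_rate_hz`, `mean_w_in`, `mean_w_ee`).
#' @export
train_reservoir <- function(network, corpus, sim = sim_params(),
                            max_rate = 63.75, epochs = 1L, eq3_on = TRUE,
                            log_every = 50L, abort_rate_hz = 500,
                            seed = 1L) {
  stopifnot(inherits(network, "reservoir_network"),
            inherits(corpus, "character_corpus"))
  bal <- check_balance(network$topology$config)
  if (!bal$pass) stop("balance check failed; refusing to train")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pres_steps <- round(sim$presentation_ms / sim$dt)
  rest_steps <- round(sim$rest_ms / sim$dt)
  log <- list()
  n_seen <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(corpus$train))
    for (wi in ord) {
      imgs <- corpus$train[[wi]]
      rate_acc <- 0
      for (img in imgs) {
        r <- run_segment(network, image_rates(img, max_rate), pres_steps,
                         dt = sim$dt, plastic = TRUE, eq3_on = eq3_on,
                         theta_adapt = TRUE)
        network <- r$network
        rate_acc <- max(rate_acc, r$rate_hz["exc"])
        if (r$rate_hz["exc"] > abort_rate_hz)
          stop(sprintf(
            "divergent activity: excitatory rate %.0f Hz > %.0f Hz at word %d",
            r$rate_hz["exc"], abort_rate_hz, wi))
      }
      r <- run_segment(network, NULL, rest_steps, dt = sim$dt,
                       plastic = TRUE, eq3_on = eq3_on, theta_adapt = TRUE)
      network <- r$network
      n_seen <- n_seen + 1L
      if (n_seen %% log_every == 0L || n_seen == length(corpus$train) * epochs)
        log[[length(log) + 1L]] <- data.frame(
          word_index = n_seen, word = corpus$train_words[wi],
          exc_rate_hz = as.numeric(rate_acc),
          mean_w_in = mean(network$topology$pathways$in_e$w),
          mean_w_ee = mean(network$topology$pathways$e_e$w),
          mean_theta = mean(network$state$theta))
    }
  }
  list(network = network, log = do.call(rbind, log))
}

#' Derive a neuron -> character assignment from a response matrix
#'
#' Each excitatory neuron is assigned the label for which its mean firing
#' was maximal; ties break toward the lowest label index. Neurons that
#' never responded get `NA`.
#'
#' @param response numeric matrix, neurons x labels (mean spike counts).
#' @param labels column labels.
#' @return object of class `assignment_map`: list with `neuron_label`
#'   (character, `NA` for unresponsive), `labels`, `group_sizes`,
#'   `unassignable` (labels with no neuron) and the `response` matrix.
#' @export
assignment_from_response <- function(response, labels = colnames(response)) {
  response <- as.matrix(response)
  if (is.null(labels)) stop("labels required")
  colnames(response) <- labels
  neuron_label <- apply(response, 1, function(r) {
    if (all(r == 0)) NA_character_ else labels[which.max(r)]
  })
  group_sizes <- vapply(labels, function(l)
    sum(neuron_label == l, na.rm = TRUE), integer(1))
  unassignable <- labels[group_sizes == 0]
  if (length(unassignable) > 0)
    warning("labels with no responsive neuron: ",
            paste(unassignable, collapse = ", "))
  structure(list(neuron_label = neuron_label, labels = labels,
                 group_sizes = group_sizes, unassignable = unassignable,
                 response = response),
            class = "assignment_map")
}

#' Assign excitatory neurons to character labels
#'
#' Presents every test variant of every character to the trained network
#' with plasticity and threshold adaptation frozen (transient state is
#' reset before each variant; the homeostatic thresholds learned during
#' training are kept). Each excitatory neuron is assigned the label for
#' which its mean spike count was maximal.
#'
#' @param network a trained `reservoir_network`.
#' @param corpus the corpus whose `test` variants are presented.
#' @param sim a [sim_params()].
#' @param max_rate Poisson encoder full-intensity rate (Hz).
#' @param n_variants number of test variants per label to use (default all).
#' @param seed RNG seed for the Poisson draws.
#' @return an `assignment_map` (see [assignment_from_response()]).
#' @export
assign_neurons <- function(network, corpus, sim = sim_params(),
                           max_rate = 63.75, n_variants = NULL, seed = 1L) {
  stopifnot(inherits(network, "reservoir_network"),
            inherits(corpus, "character_corpus"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pres_steps <- round(sim$presentation_ms / sim$dt)
  nE <- network$topology$n_exc
  labels <- corpus$labels
  response <- matrix(0, nE, length(labels), dimnames = list(NULL, labels))
  for (li in seq_along(labels)) {
    variants <- corpus$test[[labels[li]]]
    if (!is.null(n_variants)) variants <- head(variants, n_variants)
    acc <- numeric(nE)
    for (img in variants) {
      network <- reset_state(network, reset_theta = FALSE)
      r <- run_segment(network, image_rates(img, max_rate), pres_steps,
                       dt = sim$dt, plastic = FALSE, eq3_on = FALSE,
                       theta_adapt = FALSE)
      network <- r$network
      acc <- acc + r$counts[seq_len(nE)]
    }
    response[, li] <- acc / length(variants)
  }
  assignment_from_response(response, labels)
}

#' @export
print.assignment_map <- function(x, ...) {
  cat("<assignment_map>", sum(!is.na(x$neuron_label)), "assigned neurons\n")
  print(x$group_sizes)
  invisible(x)
}

#' Per-label mean spike counts over a presentation window
#'
#' Averages the spike count of the neurons assigned to each label: the
#' "spiking activity" of a character group. With a fixed assignment this is
#' invariant to group size (it is a per-neuron mean).
#'
#' @param counts integer spike counts per excitatory neuron over the window.
#' @param assignment an `assignment_map`.
#' @return named numeric vector, one mean count per label.
#' @export
group_rates <- function(counts, assignment) {
  stopifnot(inherits(assignment, "assignment_map"))
  lab <- assignment$neuron_label
  if (all(is.na(lab))) stop("empty assignment: no neuron carries a label")
  if (length(counts) != length(lab)) stop("counts length mismatch")
  vapply(assignment$labels, function(l) {
    sel <- !is.na(lab) & lab == l
    if (!any(sel)) return(0)
    mean(counts[sel])
  }, numeric(1))
}

#' Generate a character sequence from top-2 group activity
#'
#' The readout-free inference loop: the first character is presented for
#' one window; the per-label group activities are ranked; if the gap
#' between the top-1 and top-2 activities exceeds `gap_threshold` the word
#' is considered complete (a large top-2 gap signals that the last
#' character was recognized and no successor is primed), otherwise the
#' top-2 label names the next character, whose image is presented next.
#' Membrane state carries over between presentations within a trial; the
#' trial hard-stops at `length_cap` characters. If the top-2 label equals
#' the just-presented character the top-3 label is used instead (the
#' scheme cannot represent immediate repetition).
#'
#' @param network trained `reservoir_network` (plasticity is frozen here).
#' @param assignment an `assignment_map`.
#' @param first_char starting character label.
#' @param corpus corpus supplying test variants of each character.
#' @param gap_threshold termination gap in mean spikes per neuron per
#'   window (default 10).
#' @param length_cap maximum emitted length (default 10).
#' @param sim a [sim_params()].
#' @param max_rate Poisson encoder full-intensity rate (Hz).
#' @param noise_n0 Gaussian current noise amplitude during testing.
#' @param frozen_rasters optional named list of `spike_raster`s, one per
#'   label: when given, the same frozen input realization is used for a
#'   character on every presentation (the control used in noise sweeps).
#' @param reset also reset transient state before the trial (default TRUE).
#' @return object of class `generation_result`: `sequence` (string),
#'   `evidence` (data.frame `position`, `shown`, `top1`, `top2`, `gap`),
#'   `termination` (`"gap-threshold"` or `"length-cap"`).
#' @export
generate_sequence <- function(network, assignment, first_char, corpus,
                              gap_threshold = 10, length_cap = 10L,
                              sim = sim_params(), max_rate = 63.75,
                              noise_n0 = 0, frozen_rasters = NULL,
                              reset = TRUE) {
  stopifnot(inherits(assignment, "assignment_map"))
  if (gap_threshold < 0) stop("gap_threshold must be >= 0")
  if (first_char %in% assignment$unassignable)
    stop("unassignable starting label: ", first_char)
  pres_steps <- round(sim$presentation_ms / sim$dt)
  if (reset) network <- reset_state(network, reset_theta = FALSE)
  current <- first_char
  emitted <- first_char
  evidence <- list()
  termination <- "length-cap"
  repeat {
    input <- if (!is.null(frozen_rasters)) {
      frozen_rasters[[current]]
    } else {
      variants <- corpus$test[[current]]
      if (is.null(variants)) stop("no test variants for label ", current)
      image_rates(variants[[sample.int(length(variants), 1L)]], max_rate)
    }
    r <- run_segment(network, input, pres_steps, dt = sim$dt,
                     plastic = FALSE, eq3_on = FALSE, theta_adapt = FALSE,
                     noise_n0 = noise_n0)
    network <- r$network
    rates <- group_rates(r$counts[seq_len(network$topology$n_exc)],
                         assignment)
    ord <- order(rates, decreasing = TRUE)
    top1 <- assignment$labels[ord[1L]]
    top2 <- assignment$labels[ord[2L]]
    gap <- rates[ord[1L]] - rates[ord[2L]]
    evidence[[length(evidence) + 1L]] <- data.frame(
      position = length(evidence) + 1L, shown = current,
      top1 = top1, top2 = top2, gap = as.numeric(gap))
    if (gap > gap_threshold) { termination <- "gap-threshold"; break }
    if (nchar(emitted) >= length_cap) { termination <- "length-cap"; break }
    nxt <- if (top2 != current) top2 else assignment$labels[ord[3L]]
    if (is.na(nxt) || nxt %in% assignment$unassignable)
      stop("unassignable label encountered during generation: ", nxt)
    emitted <- paste0(emitted, nxt)
    current <- nxt
  }
  structure(list(sequence = emitted,
                 evidence = do.call(rbind, evidence),
                 termination = termination),
            class = "generation_result")
}

#' Score generated sequences against a dictionary
#'
#' A trial is correct iff its emitted sequence is a dictionary word. The
#' report breaks counts down by starting character and by word, lists the
#' garbage (non-dictionary) words, and gives the average accuracy over
#' starting characters (in percent).
#'
#' @param dictionary character vector of correct words.
#' @param trials list of `generation_result`s (or character vector of
#'   emitted sequences).
#' @return object of class `eval_report`: `n_trials`, `n_correct`,
#'   `accuracy` (overall percent), `avg_accuracy` (mean over starting
#'   characters), `per_first_char` (data.frame), `word_counts`,
#'   `garbage` (table of wrong sequences).
#' @export
evaluate_generation <- function(dictionary, trials) {
  seqs <- if (is.character(trials)) trials
          else vapply(trials, function(t) t$sequence, character(1))
  if (length(seqs) == 0) stop("trials must be nonempty")
  dictionary <- toupper(dictionary)
  correct <- seqs %in% dictionary
  first <- substr(seqs, 1, 1)
  per_first <- do.call(rbind, lapply(sort(unique(first)), function(f) {
    sel <- first == f
    data.frame(first_char = f, n = sum(sel), n_correct = sum(correct[sel]),
               accuracy = 100 * mean(correct[sel]))
  }))
  word_counts <- table(factor(seqs[correct], levels = sort(dictionary)))
  garbage <- sort(table(seqs[!correct]), decreasing = TRUE)
  structure(list(n_trials = length(seqs), n_correct = sum(correct),
                 accuracy = 100 * mean(correct),
                 avg_accuracy = if (nrow(per_first) > 0)
                   mean(per_first$accuracy) else 0,
                 per_first_char = per_first,
                 word_counts = word_counts, garbage = garbage),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d/%d correct (%.1f%%; avg over first chars %.1f%%)\n",
              x$n_correct, x$n_trials, x$accuracy, x$avg_accuracy))
  print(x$word_counts)
  if (length(x$garbage) > 0) {
    cat("garbage:\n"); print(head(x$garbage, 10))
  }
  invisible(x)
}

#' Mean E->E weight between consecutive-character neuron groups
#'
#' Diagnostic of the learned context: for every within-word consecutive
#' character pair (e.g. C->A and A->T for "CAT") the mean weight of E->E
#' synapses from the first group to the second is compared against the
#' mean over pairs of labels that are not consecutive in any word. After
#' successful training the consecutive-pair mean is a multiple of the
#' non-word mean.
#'
#' @param network trained `reservoir_network`.
#' @param assignment an `assignment_map`.
#' @param words dictionary words.
#' @return list with `word_pair_mean`, `nonword_pair_mean`, `ratio` and the
#'   per-pair table.
#' @export
association_weights <- function(network, assignment, words) {
  g <- network$topology$pathways$e_e
  lab <- assignment$neuron_label
  pairs <- unique(do.call(rbind, lapply(toupper(words), function(w) {
    s <- strsplit(w, "")[[1]]
    if (length(s) < 2) return(NULL)
    data.frame(from = s[-length(s)], to = s[-1])
  })))
  all_pairs <- expand.grid(from = assignment$labels, to = assignment$labels,
                           stringsAsFactors = FALSE)
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  key <- paste(pairs$from, pairs$to)
  all_pairs$in_word <- paste(all_pairs$from, all_pairs$to) %in% key
  pre_lab <- lab[g$pre]; post_lab <- lab[g$post]
  pair_mean <- function(f, t) {
    sel <- !is.na(pre_lab) & !is.na(post_lab) & pre_lab == f & post_lab == t
    if (!any(sel)) return(NA_real_)
    mean(g$w[sel])
  }
  all_pairs$mean_w <- mapply(pair_mean, all_pairs$from, all_pairs$to)
  wp <- mean(all_pairs$mean_w[all_pairs$in_word], na.rm = TRUE)
  np <- mean(all_pairs$mean_w[!all_pairs$in_word], na.rm = TRUE)
  list(word_pair_mean = wp, nonword_pair_mean = np, ratio = wp / np,
       pairs = all_pairs)
}
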