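#' Eigenvalue spectrum of the recurrent weight matrix
#'
#' Diagonalizes the signed recurrent matrix (all four pathways, excitatory
#' columns positive and inhibitory negative; see
#' [compose_signed_matrix()]). Each complex eigenvalue labels a dynamical
#' mode: the real part sets its decay/growth and the imaginary part its
#' oscillation frequency; modes with real part > 1 are the activated,
#' chaos-contributing ones. For an untrained sparse random reservoir the
#' eigenvalues fill a disc in the complex plane (Girko's circle law);
#' learning of the E->E block contracts the disc and depletes the unstable
#' modes.
#'
#' @param W square signed weight matrix, or a `reservoir_network` /
#'   `network_topology` (composed on the fly).
#' @param stage optional tag, e.g. `"before"` or `"after"` learning.
#' @return object of class `spectrum_report`: `eigenvalues` (complex),
#'   `spectral_radius` (max modulus), `n_unstable` (count with
#'   `Re > 1`), `stage`.
#' @export
eigen_spectrum <- function(W, stage = NA_character_) {
  if (!is.matrix(W)) W <- compose_signed_matrix(W)
  if (nrow(W) != ncol(W)) stop("matrix must be square")
  if (any(!is.finite(W))) stop("non-finite entries")
  ev <- eigen(W, only.values = TRUE)$values
  structure(list(eigenvalues = ev,
                 spectral_radius = max(Mod(ev)),
                 n_unstable = sum(Re(ev) > 1),
                 stage = stage),
            class = "spectrum_report")
}

#' @export
print.spectrum_report <- function(x, ...) {
  cat(sprintf("<spectrum_report%s> n = %d, radius = %.3f, Re > 1: %d\n",
              if (is.na(x$stage)) "" else paste0(" ", x$stage),
              length(x$eigenvalues), x$spectral_radius, x$n_unstable))
  invisible(x)
}

#' Plot an eigenvalue spectrum
#' @param x a `spectrum_report`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spectrum_report <- function(x, ...) {
  graphics::plot(Re(x$eigenvalues), Im(x$eigenvalues), pch = 16, cex = 0.5,
                 xlab = "Re", ylab = "Im", asp = 1, ...)
  graphics::abline(v = 1, lty = 2)
}

#' Circle-law uniformity check of a spectrum
#'
#' Under the circle law, eigenvalue moduli squared (normalized by the bulk
#' radius) are uniform on \[0, 1\]. The bulk radius is estimated as an
#' upper quantile of the moduli (default 0.95) so that the handful of
#' outlier modes induced by the excitatory/inhibitory mean structure, and
#' the smooth finite-size decay of the spectral density at the bulk edge,
#' do not distort the normalization; eigenvalues inside the bulk are
#' tested with a two-sided Kolmogorov-Smirnov test.
#'
#' @param spectrum a `spectrum_report` (or complex vector).
#' @param bulk_quantile quantile of the moduli used as the bulk radius.
#' @return list with `p_value`, `bulk_radius`, `n_bulk`.
#' @export
circle_law_check <- function(spectrum, bulk_quantile = 0.95) {
  ev <- if (inherits(spectrum, "spectrum_report")) spectrum$eigenvalues
        else spectrum
  m <- Mod(ev)
  r <- quantile(m, bulk_quantile, names = FALSE)
  u <- (m[m <= r] / r)^2
  kt <- suppressWarnings(ks.test(u, "punif"))
  list(p_value = kt$p.value, bulk_radius = r, n_bulk = length(u))
}

#' Principal-component trajectories of population activity
#'
#' Mean-centers the binned firing-rate matrix over time and projects the
#' population activity onto its leading principal components; in the
#' chaotic spontaneous regime the first few components carry most of the
#' variance, and noise-induced transformations of the trajectory are
#' visible as displaced paths in PC space.
#'
#' @param rate_matrix neurons x timebins firing-rate matrix (Hz).
#' @param n_components number of components to keep (default 3).
#' @return object of class `trajectory_bundle`: `projections` (timebins x
#'   components scores), `explained` (variance fractions, non-increasing),
#'   `rotation`.
#' @export
pca_trajectories <- function(rate_matrix, n_components = 3L) {
  x <- t(as.matrix(rate_matrix))  # timebins x neurons
  if (nrow(x) < 2) stop("need at least 2 timebins")
  if (all(apply(x, 2, stats::var) == 0))
    stop("constant activity: zero variance")
  n_components <- min(n_components, ncol(x), nrow(x) - 1L)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(projections = pc$x[, seq_len(n_components), drop = FALSE],
                 explained = expl,
                 rotation = pc$rotation[, seq_len(n_components),
                                        drop = FALSE]),
            class = "trajectory_bundle")
}

#' Bin a spike raster into smoothed firing rates
#'
#' 10 ms bins with a 50 ms boxcar smoothing by default.
#'
#' @param raster data.frame with columns `step`, `neuron` (as returned by
#'   [run_segment()] with `record_raster = TRUE`).
#' @param n_neurons number of neurons (rows of the output).
#' @param n_steps raster length in steps.
#' @param dt step (ms).
#' @param bin_ms bin width (ms).
#' @param smooth_ms boxcar smoothing window (ms); 0 disables.
#' @return neurons x bins matrix of rates (Hz).
#' @export
bin_rates <- function(raster, n_neurons, n_steps, dt = 0.5, bin_ms = 10,
                      smooth_ms = 50) {
  steps_per_bin <- round(bin_ms / dt)
  n_bins <- floor(n_steps / steps_per_bin)
  m <- matrix(0, n_neurons, n_bins)
  if (nrow(raster) > 0) {
    b <- pmin(n_bins, (raster$step - 1L) %/% steps_per_bin + 1L)
    keep <- raster$neuron <= n_neurons
    tab <- table(factor(raster$neuron[keep], levels = seq_len(n_neurons)),
                 factor(b[keep], levels = seq_len(n_bins)))
    m <- matrix(as.numeric(tab), n_neurons, n_bins)
  }
  m <- m / (bin_ms / 1000)
  if (smooth_ms > 0) {
    k <- max(1L, round(smooth_ms / bin_ms))
    kern <- rep(1 / k, k)
    m <- t(apply(m, 1, function(r)
      stats::filter(r, kern, sides = 2) |> (\(x) {
        x[is.na(x)] <- r[is.na(x)]; as.numeric(x) })()))
  }
  m
}

#' Diagonal-structure score of an input weight matrix
#'
#' Measures how strongly a learned inputs x neurons weight matrix
#' concentrates along a diagonal after sorting neurons by their preferred
#' input (weight centroid): the score is the fraction of total weight mass
#' within a band of +/- 10% of the input dimension around the diagonal of
#' the sorted matrix. A perfectly diagonal (identity-like) matrix scores
#' 1; a uniform matrix scores about the band-width fraction (0.2). The
#' score is invariant to neuron order. A high score is the signature of
#' the bell-shaped input ensemble being laid out topographically across
#' the reservoir (learned receptive fields).
#'
#' @param in_weights nonnegative inputs x neurons matrix.
#' @param band_frac half-width of the band as a fraction of the input
#'   dimension (default 0.1).
#' @return score in \[0, 1\].
#' @export
diagonal_structure_score <- function(in_weights, band_frac = 0.1) {
  W <- as.matrix(in_weights)
  if (any(W < 0)) stop("weights must be nonnegative")
  tot <- colSums(W)
  if (sum(W) == 0) stop("all-zero matrix")
  n_in <- nrow(W); n_nr <- ncol(W)
  centroid <- colSums(W * seq_len(n_in)) / ifelse(tot > 0, tot, 1)
  centroid[tot == 0] <- n_in / 2
  Ws <- W[, order(centroid), drop = FALSE]
  band <- band_frac * n_in
  diag_pos <- (seq_len(n_nr) - 0.5) / n_nr * n_in
  in_band <- outer(seq_len(n_in), diag_pos, function(i, d) abs(i - d) <= band)
  sum(Ws[in_band]) / sum(Ws)
}

#' Across-trial dispersion of rate trajectories
#'
#' The noise-robustness metric: for a set of per-trial rate matrices
#' (neurons x bins, identical shapes), computes the standard deviation
#' across trials per neuron and time bin and returns its mean — 0 iff all
#' trials are identical.
#'
#' @param rate_list list of neurons x bins matrices.
#' @return mean across time and neurons of the across-trial sd (Hz).
#' @export
trajectory_dispersion <- function(rate_list) {
  if (length(rate_list) < 2) stop("need at least 2 trials")
  a <- simplify2array(rate_list)
  mean(apply(a, c(1, 2), sd))
}

#' Noise-robustness sweep
#'
#' For each noise amplitude N0, runs generation trials with Gaussian
#' current noise injected into every neuron at every step while the input
#' spike realization of each character is frozen (the same pre-drawn
#' Poisson raster is replayed on every presentation of a character, so
#' any across-trial variability is caused by the noise alone). Reports the
#' dictionary accuracy and the across-trial trajectory dispersion of the
#' excitatory population during the first presentation window.
#'
#' @param network trained `reservoir_network`.
#' @param assignment an `assignment_map`.
#' @param corpus the character corpus (dictionary and test variants).
#' @param n0_grid noise amplitudes to sweep (default the standard grid).
#' @param trials_per_level generation trials per level.
#' @param first_chars starting characters (default: first letters of the
#'   dictionary words).
#' @param gap_threshold,length_cap,sim,max_rate passed to
#'   [generate_sequence()].
#' @param seed RNG seed (drives the frozen rasters and the per-trial noise
#'   streams).
#' @return object of class `noise_sweep`: data.frame `summary` with
#'   columns `n0`, `accuracy`, `dispersion`, plus per-level `reports`.
#' @export
noise_sweep <- function(network, assignment, corpus,
                        n0_grid = c(0, 0.3, 0.5, 0.7, 1.0),
                        trials_per_level = 20L, first_chars = NULL,
                        gap_threshold = 10, length_cap = 10L,
                        sim = sim_params(), max_rate = 63.75, seed = 1L) {
  if (length(n0_grid) == 0) stop("empty N0 grid")
  if (any(n0_grid < 0)) stop("noise amplitudes must be >= 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(first_chars))
    first_chars <- unique(substr(corpus$words, 1, 1))
  pres_steps <- round(sim$presentation_ms / sim$dt)
  # one frozen raster per character
  frozen <- lapply(stats::setNames(nm = corpus$labels), function(l)
    encode_poisson(corpus$test[[l]][[1]], max_rate,
                   sim$presentation_ms, sim$dt))
  nE <- network$topology$n_exc
  rows <- list(); reports <- list()
  for (n0 in n0_grid) {
    trials <- list(); rate_mats <- list(); trial_fc <- character(0)
    for (tr in seq_len(trials_per_level)) {
      fc <- first_chars[(tr - 1L) %% length(first_chars) + 1L]
      trial_fc[tr] <- fc
      net <- reset_state(network, reset_theta = FALSE)
      rfirst <- run_segment(net, frozen[[fc]], pres_steps, dt = sim$dt,
                            plastic = FALSE, eq3_on = FALSE,
                            theta_adapt = FALSE, noise_n0 = n0,
                            record_raster = TRUE,
                            seed = sample.int(2147483647, 1L))
      rate_mats[[tr]] <- bin_rates(rfirst$raster, nE, pres_steps, sim$dt)
      # continue the trial from the post-window state
      rates <- group_rates(rfirst$counts[seq_len(nE)], assignment)
      ord <- order(rates, decreasing = TRUE)
      gap <- rates[ord[1L]] - rates[ord[2L]]
      if (gap > gap_threshold) {
        trials[[tr]] <- fc
      } else {
        top2 <- assignment$labels[ord[2L]]
        nxt <- if (top2 != fc) top2 else assignment$labels[ord[3L]]
        g <- generate_sequence(rfirst$network, assignment, nxt, corpus,
                               gap_threshold, length_cap - 1L, sim,
                               max_rate, noise_n0 = n0,
                               frozen_rasters = frozen, reset = FALSE)
        trials[[tr]] <- paste0(fc, g$sequence)
      }
    }
    rep <- evaluate_generation(corpus$words, unlist(trials))
    reports[[as.character(n0)]] <- rep
    # dispersion within trials sharing a starting character (identical
    # frozen input), averaged over starting characters
    disp <- mean(vapply(unique(trial_fc), function(fc) {
      sel <- which(trial_fc == fc)
      if (length(sel) < 2) return(NA_real_)
      trajectory_dispersion(rate_mats[sel])
    }, numeric(1)), na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      n0 = n0, accuracy = rep$accuracy, dispersion = disp)
  }
  structure(list(summary = do.call(rbind, rows), reports = reports),
            class = "noise_sweep")
}

#' @export
print.noise_sweep <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
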