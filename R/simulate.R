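#' Specify a two-label ground-truth simulation
#'
#' Two coupled "labels" (source regions) oscillate at a common frequency with
#' a fixed phase lag: label-1 dipoles carry `amplitude * sin(2 pi f0 t)`,
#' label-2 dipoles `amplitude * sin(2 pi f0 t + phase_lag)`. Dipoles within a
#' label share one time course. The sources are mapped to sensors by a
#' mixing matrix (identity by default; a fixed 10 x 6 leakage matrix ships
#' with the package, see [leakage_mixing_matrix()]), Gaussian sensor noise is
#' added at a target SNR, trials are concatenated, and a trigger channel
#' marks each trial onset with event id 1.
#'
#' @param f0 oscillation frequency in Hz
#' @param phase_lag phase lead of label 2 over label 1, degrees (90 means
#'   label 2 is the cosine to label 1's sine)
#' @param n_dipoles_label1,n_dipoles_label2 dipoles per label
#' @param amplitude source amplitude in source units (nAm-like)
#' @param fs sampling rate in Hz
#' @param trial_length trial duration in seconds
#' @param n_trials number of trials
#' @param snr_db target per-channel SNR in dB (`Inf` = noiseless)
#' @param mixing `"identity"` or an `n_sensors x n_sources` matrix
#' @param phase_jitter add a common uniform random phase offset per trial
#'   (the lag between labels is preserved) to emulate rhythms that are not
#'   time-locked to the stimulus
#' @param seed RNG seed for the noise (and jitter)
#' @return object of class `simulation_spec`
#' @export
simulation_spec <- function(f0 = 18, phase_lag = 90,
                            n_dipoles_label1 = 2, n_dipoles_label2 = 4,
                            amplitude = 10, fs = 600, trial_length = 0.16,
                            n_trials = 200, snr_db = 11.85,
                            mixing = "identity", phase_jitter = FALSE,
                            seed = 1L) {
  if (f0 >= fs / 2) config_error("`f0` must be below the Nyquist frequency")
  if (round(trial_length * fs) < 2) config_error("trials must have >= 2 samples")
  if (n_trials < 1L) config_error("`n_trials` must be >= 1")
  structure(list(f0 = f0, phase_lag = phase_lag,
                 n_dipoles_label1 = n_dipoles_label1,
                 n_dipoles_label2 = n_dipoles_label2,
                 amplitude = amplitude, fs = fs, trial_length = trial_length,
                 n_trials = n_trials, snr_db = snr_db, mixing = mixing,
                 phase_jitter = isTRUE(phase_jitter), seed = as.integer(seed)),
            class = "simulation_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Add Gaussian noise at a target SNR
#'
#' Scales i.i.d. Gaussian noise per channel so that each channel's nominal
#' `10 * log10(P_signal / P_noise)` equals `snr_db` (powers are mean
#' squares); the across-channel mean in dB then equals `snr_db` as well.
#' `snr_db = Inf` returns the data unchanged.
#'
#' @param data numeric matrix `channels x samples`
#' @param snr_db target SNR in dB
#' @param seed optional RNG seed (restores the RNG state afterwards)
#' @return noisy matrix
#' @export
add_noise_to_snr <- function(data, snr_db, seed = NULL) {
  if (is.infinite(snr_db) && snr_db > 0) return(data)
  p_sig <- rowMeans(data^2)
  if (any(p_sig == 0)) data_error("zero-power signal channel; SNR undefined")
  sigma <- sqrt(p_sig / 10^(snr_db / 10))
  gen <- function() {
    noise <- matrix(rnorm(length(data)), nrow(data), ncol(data))
    data + noise * sigma
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' The fixed 10 x 6 leakage mixing matrix
#'
#' A random-but-fixed sensor mixing matrix shipped as a plain-text fixture
#' (`inst/extdata/mixing_10x6_synthetic.csv`). Every sensor picks up both
#' labels with different gains, emulating the instantaneous field spread that
#' produces spurious zero-lag connectivity.
#'
#' @return numeric 10 x 6 matrix
#' @export
leakage_mixing_matrix <- function() {
  read_operator(system.file("extdata", "mixing_10x6_synthetic.csv",
                            package = "connstream", mustWork = TRUE))
}

#' Simulate the two-label dataset
#'
#' @param spec a [simulation_spec()]
#' @param out_dir optional directory: when given, the stream is also written
#'   as a fixture via [write_fixture_stream()]
#' @param block_size samples per emitted stream block (default: one trial)
#' @return list with `blocks` (stream blocks incl. trigger row), `epochs`
#'   (the clean per-trial cut, `channels x samples` each), `truth`
#'   (ground-truth description with `connected_pairs`), and `spec`
#' @export
simulate_two_label_dataset <- function(spec, out_dir = NULL, block_size = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  ns <- as.integer(round(spec$trial_length * spec$fs))
  t <- (0:(ns - 1L)) / spec$fs
  lag <- spec$phase_lag * pi / 180
  n_src <- spec$n_dipoles_label1 + spec$n_dipoles_label2
  mix <- spec$mixing
  if (is.character(mix) && identical(mix, "identity")) mix <- diag(n_src)
  mix <- as.matrix(mix)
  if (ncol(mix) != n_src) {
    config_error(sprintf("mixing matrix has %d columns but there are %d sources",
                         ncol(mix), n_src))
  }
  n_sens <- nrow(mix)

  offsets <- if (spec$phase_jitter) {
    with_seed(spec$seed + 1L, runif(spec$n_trials, 0, 2 * pi))
  } else rep(0, spec$n_trials)

  sensors <- matrix(0, n_sens, ns * spec$n_trials)
  for (k in seq_len(spec$n_trials)) {
    s1 <- spec$amplitude * sin(2 * pi * spec$f0 * t + offsets[k])
    s2 <- spec$amplitude * sin(2 * pi * spec$f0 * t + offsets[k] + lag)
    src <- rbind(
      matrix(rep(s1, spec$n_dipoles_label1), nrow = spec$n_dipoles_label1,
             byrow = TRUE),
      matrix(rep(s2, spec$n_dipoles_label2), nrow = spec$n_dipoles_label2,
             byrow = TRUE))
    sensors[, (k - 1L) * ns + seq_len(ns)] <- mix %*% src
  }
  sensors <- add_noise_to_snr(sensors, spec$snr_db, seed = spec$seed)

  trigger <- numeric(ncol(sensors))
  trigger[(seq_len(spec$n_trials) - 1L) * ns + 1L] <- 1
  full <- rbind(sensors, trigger)
  ch_names <- c(paste0("sens", seq_len(n_sens)), "TRIG")

  bs <- block_size %||% ns
  blocks <- as_stream_blocks(full, fs = spec$fs, block_size = bs,
                             channel_names = ch_names,
                             trigger_row = n_sens + 1L)
  epochs <- lapply(seq_len(spec$n_trials), function(k) {
    sensors[, (k - 1L) * ns + seq_len(ns), drop = FALSE]
  })

  # ground truth: source-level label membership mapped through the mixing;
  # under identity mixing, sensor pairs across the two labels are the truly
  # coupled pairs
  lab <- rep(c(1L, 2L), c(spec$n_dipoles_label1, spec$n_dipoles_label2))
  truth_pairs <- if (all(dim(mix) == n_src) && all(mix == diag(n_src))) {
    pr <- pair_index(n_src)
    keep <- lab[pr$i] != lab[pr$j]
    tibble(node_i = pr$i[keep], node_j = pr$j[keep])
  } else {
    tibble(node_i = integer(), node_j = integer())
  }
  truth <- list(connected_pairs = truth_pairs, source_labels = lab,
                f0 = spec$f0, phase_lag = spec$phase_lag)

  if (!is.null(out_dir)) {
    write_fixture_stream(out_dir, full, fs = spec$fs,
                         channel_names = ch_names,
                         trigger_row = n_sens + 1L, block_size = bs)
  }
  list(blocks = blocks, epochs = epochs, truth = truth, spec = spec)
}

#' Trial-count convergence of the strongest edges
#'
#' Reproduces the standard convergence analysis: the network over all
#' `max(trial_counts)` epochs is computed and normalized, its `k` strongest
#' edges are fixed, and for every entry of `trial_counts` the network over
#' the *first* n epochs is recomputed (and normalized) and the mean weight of
#' those same k edges reported. The curve shows how quickly the final
#' detected structure is established — not whether it is correct.
#'
#' @param epochs list of epochs / matrices
#' @param metric metric name
#' @param fs sampling rate in Hz
#' @param nfft FFT length
#' @param fmin,fmax band in Hz
#' @param trial_counts increasing trial counts to evaluate
#' @param k number of strongest edges to track
#' @param window taper kind
#' @return tibble of class `conn_convergence` with columns `metric`,
#'   `n_trials`, `mean_top_weight`; attribute `top_edges` holds the tracked
#'   edge set
#' @export
convergence_experiment <- function(epochs, metric, fs, nfft,
                                   fmin = 0, fmax = fs / 2,
                                   trial_counts, k = 20,
                                   window = c("hanning", "ones")) {
  window <- match.arg(window)
  metric <- metric_id(metric)
  nmax <- max(trial_counts)
  if (nmax > length(epochs)) config_error("not enough epochs for max(trial_counts)")
  net_at <- function(n) {
    normalize_by_max(batch_connectivity(
      epochs[seq_len(n)], metric, fs = fs, nfft = nfft,
      fmin = fmin, fmax = fmax, window = window))
  }
  final <- net_at(nmax)
  if (k > nrow(final)) config_error("`k` exceeds the number of edges")
  ord <- order(-final$weight, final$node_i, final$node_j)[seq_len(k)]
  top <- as_tibble(final)[sort(ord), c("node_i", "node_j")]
  key <- paste(top$node_i, top$node_j)
  curve <- purrr::map_dbl(trial_counts, function(n) {
    net <- if (n == nmax) final else net_at(n)
    idx <- match(key, paste(net$node_i, net$node_j))
    mean(net$weight[idx])
  })
  out <- new_tibble(
    tibble(metric = metric, n_trials = as.integer(trial_counts),
           mean_top_weight = curve),
    top_edges = top, class = "conn_convergence")
  out
}

#' Trial count at which a convergence curve first reaches its final value
#'
#' The smallest evaluated trial count n at which the curve comes within
#' `tol` (relative) of its final value. Note that a curve may leave the
#' tolerance band again afterwards; this reports the first crossing, which is
#' how "reaching the final structure" is conventionally read off such plots.
#'
#' @param curve a [convergence_experiment()] result (one metric)
#' @param tol relative tolerance (default 0.05)
#' @return trial count (integer)
#' @export
convergence_trials <- function(curve, tol = 0.05) {
  v <- curve$mean_top_weight
  fin <- v[length(v)]
  curve$n_trials[which(abs(v - fin) <= tol * abs(fin))[1L]]
}

#' Plot convergence curves
#' @param object a `conn_convergence` tibble (several metrics may be bound
#'   together with `dplyr::bind_rows()`)
#' @param ... unused
#' @return a ggplot
#' @exportS3Method ggplot2::autoplot
autoplot.conn_convergence <- function(object, ...) {
  ggplot(object, aes(x = .data$n_trials, y = .data$mean_top_weight,
                     colour = .data$metric)) +
    geom_line() + geom_point() +
    labs(x = "number of trials", y = "mean weight of final top edges",
         colour = "metric") +
    theme_minimal()
}
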