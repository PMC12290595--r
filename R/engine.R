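#' Create an online connectivity engine
#'
#' The engine maintains the across-trial [spectral_accumulator()] and, with
#' storage mode on, a cache of per-trial tapered spectra (`channels x bins` —
#' O(C·F) per trial rather than per-pair CSDs at O(C²·F)) plus the raw
#' epochs. Every [add_trial()] computes the trial's spectra exactly once,
#' updates the sums, and returns the current band-averaged network, so the
#' per-trial cost is independent of how many trials came before. All
#' accumulator sums are always maintained (they are cheap relative to the
#' FFT), so switching between spectral metrics never needs cached data; the
#' cache is required only for the moving-average horizon and for the
#' time-domain metrics COR/XCOR.
#'
#' Determinism contract: trials are reduced in fixed arrival order, so the
#' result is bit-identical to a one-shot batch computation over the same
#' epochs regardless of how the work would be partitioned across workers.
#'
#' @param n_channels number of channels of incoming epochs
#' @param fs sampling rate in Hz
#' @param metric metric name (see [CONN_METRICS]); switch later with
#'   [switch_metric()]
#' @param fmin,fmax frequency band in Hz to average into edge weights
#' @param nfft FFT length in bins
#' @param window taper kind: `"hanning"` or `"ones"`
#' @param n_trials_target optional moving-average horizon: with more than
#'   this many accepted trials, only the most recent `n_trials_target`
#'   contribute (requires `storage_mode = TRUE`)
#' @param storage_mode cache per-trial spectra and epochs
#' @param channel_names optional node labels
#' @return mutable engine of class `conn_engine`
#' @export
connectivity_engine <- function(n_channels, fs, metric = "COH",
                                fmin = 0, fmax = fs / 2, nfft,
                                window = c("hanning", "ones"),
                                n_trials_target = NULL,
                                storage_mode = FALSE,
                                channel_names = NULL) {
  metric <- metric_id(metric)
  window <- match.arg(window)
  if (!is.null(n_trials_target)) {
    if (!storage_mode) {
      config_error("a moving-average horizon requires storage_mode = TRUE")
    }
    if (n_trials_target < 1L) config_error("`n_trials_target` must be >= 1")
  }
  if (metric %in% c("COR", "XCOR") && !storage_mode) {
    # time-domain metrics average per-trial estimates; incremental sums are
    # kept, but a later switch back needs the epochs, hence require storage
    config_error("COR/XCOR require storage_mode = TRUE")
  }
  band <- band_bins(fmin, fmax, fs, nfft)
  env <- new.env(parent = emptyenv())
  env$n_channels <- as.integer(n_channels)
  env$fs <- fs
  env$metric <- metric
  env$band <- band
  env$band_hz <- c(fmin, fmax)
  env$nfft <- as.integer(nfft)
  env$window_kind <- window
  env$storage_mode <- isTRUE(storage_mode)
  env$horizon <- if (is.null(n_trials_target)) Inf else as.integer(n_trials_target)
  env$channel_names <- channel_names %||% paste0("ch", seq_len(n_channels))
  env$acc <- spectral_accumulator(n_channels, nfft, env$channel_names)
  env$cached_spectra <- list()
  env$epoch_store <- list()
  env$n_seen <- 0L
  env$n_fft_columns <- 0L       # instrumentation: FFT columns computed
  env$fft_per_trial <- integer()
  env$td <- NULL                # running time-domain sums (COR/XCOR only)
  class(env) <- "conn_engine"
  env
}

# running time-domain state: per-trial contributions summed in trial order
td_init <- function(metric) {
  list(metric = metric, n = 0L, sum = NULL, degen = NULL, lag_axis = NULL)
}

td_update <- function(td, data, pr) {
  if (td$metric == "COR") {
    tc <- trial_cor(data, pr, "pearson")
    td$sum <- if (is.null(td$sum)) tc$r else td$sum + tc$r
    td$degen <- if (is.null(td$degen)) tc$degenerate else td$degen | tc$degenerate
  } else {
    tx <- trial_xcor(data, pr, demean = TRUE)
    if (!is.null(td$sum) && ncol(td$sum) != ncol(tx$fun)) {
      config_error("XCOR requires all epochs to have the same length")
    }
    td$sum <- if (is.null(td$sum)) tx$fun else td$sum + tx$fun
    td$degen <- if (is.null(td$degen)) tx$degenerate else td$degen | tx$degenerate
    td$lag_axis <- tx$lag_axis
  }
  td$n <- td$n + 1L
  td
}

td_rebuild <- function(metric, epochs, pr) {
  td <- td_init(metric)
  for (d in epochs) td <- td_update(td, d, pr)
  td
}

#' @export
print.conn_engine <- function(x, ...) {
  cat(sprintf(paste0("<conn_engine> metric=%s, %d ch, nfft=%d, band %g-%g Hz, ",
                     "N=%d trials, storage=%s%s\n"),
              x$metric, x$n_channels, x$nfft, x$band_hz[1L], x$band_hz[2L],
              x$acc$n_trials, if (x$storage_mode) "on" else "off",
              if (is.finite(x$horizon)) sprintf(", horizon=%d", x$horizon) else ""))
  invisible(x)
}

#' Add one trial to the engine
#'
#' Computes the trial's tapered spectra once, folds them into the
#' accumulator (dropping the oldest trial's contribution when a
#' moving-average horizon is exceeded), and returns the current connectivity
#' network.
#'
#' @param engine a [connectivity_engine()]
#' @param epoch a `conn_epoch` (or plain `channels x samples` matrix)
#'   matching the configured channel count
#' @return the current [conn_network()]
#' @export
add_trial <- function(engine, epoch) {
  data <- epoch_data(epoch)
  if (nrow(data) != engine$n_channels) {
    config_error(sprintf("epoch has %d channels; engine expects %d",
                         nrow(data), engine$n_channels))
  }
  win <- make_window(engine$window_kind, ncol(data))
  spec <- trial_spectra(data, win, engine$nfft, fs = engine$fs)
  engine$n_fft_columns <- engine$n_fft_columns + nrow(data)
  engine$fft_per_trial <- c(engine$fft_per_trial, nrow(data))
  engine$n_seen <- engine$n_seen + 1L

  slid <- FALSE
  if (engine$storage_mode) {
    engine$cached_spectra[[length(engine$cached_spectra) + 1L]] <- spec
    engine$epoch_store[[length(engine$epoch_store) + 1L]] <- data
    if (length(engine$cached_spectra) > engine$horizon) {
      # slide the window: rebuild sums from the cached spectra of the last
      # H trials in fixed order (bit-identical to a batch over those trials)
      slid <- TRUE
      engine$cached_spectra <- tail(engine$cached_spectra, engine$horizon)
      engine$epoch_store <- tail(engine$epoch_store, engine$horizon)
      acc <- spectral_accumulator(engine$n_channels, engine$nfft,
                                  engine$channel_names)
      for (s in engine$cached_spectra) acc <- accumulate_trial(acc, s)
      engine$acc <- acc
    } else {
      engine$acc <- accumulate_trial(engine$acc, spec)
    }
  } else {
    engine$acc <- accumulate_trial(engine$acc, spec)
  }
  if (engine$metric %in% c("COR", "XCOR")) {
    pr <- pair_index(engine$n_channels)
    engine$td <- if (slid) {
      td_rebuild(engine$metric, engine$epoch_store, pr)
    } else {
      td_update(engine$td %||% td_init(engine$metric), data, pr)
    }
  }
  current_network(engine)
}

#' Current network of an engine
#'
#' Builds the band-averaged, undirected all-to-all network from the current
#' accumulator (or epoch store for COR/XCOR) without adding data. An engine
#' that has seen no trials returns an empty network (all nodes, zero edges).
#'
#' @param engine a [connectivity_engine()]
#' @return a [conn_network()]
#' @export
current_network <- function(engine) {
  nodes <- tibble(id = seq_len(engine$n_channels),
                  label = engine$channel_names)
  empty <- conn_network(
    tibble(node_i = integer(), node_j = integer(), weight = numeric()),
    nodes, metric = engine$metric, band = engine$band_hz, n_trials = 0L)
  n <- engine$acc$n_trials
  if (n == 0L && engine$metric %in% spectral_metrics()) return(empty)
  if (engine$metric %in% c("USPLI", "DSWPLI") && n < 2L) {
    attr(empty, "flags") <- union(attr(empty, "flags"), "insufficient_trials")
    attr(empty, "n_trials") <- n
    return(empty)
  }
  if (engine$metric %in% c("COR", "XCOR")) {
    td <- engine$td
    if (is.null(td) || td$n == 0L) return(empty)
    pr <- pair_index(engine$n_channels)
    if (engine$metric == "COR") {
      r <- td$sum / td$n
      edges <- tibble(node_i = pr$i, node_j = pr$j,
                      weight = abs(r), signed_value = r)
    } else {
      pk <- xcor_peak(td$sum / td$n, td$lag_axis, td$degen)
      edges <- tibble(node_i = pr$i, node_j = pr$j,
                      weight = pk$value, lag = pk$lag)
    }
    flags <- if (any(td$degen)) "degenerate_pairs" else character()
    return(conn_network(edges, nodes, metric = engine$metric,
                        band = c(NA_real_, NA_real_), n_trials = td$n,
                        flags = flags))
  }
  network_from_acc(engine$acc, engine$metric, engine$band, nodes,
                   engine$band_hz)
}

network_from_acc <- function(acc, metric, band, nodes, band_hz) {
  vals <- metric_per_bin(acc, metric)
  degen <- attr(vals, "degenerate")
  avg <- band_average(unclass_attr(vals), band)
  if (is.complex(avg)) {            # COHY: magnitude weight, no scalar sign
    weight <- Mod(avg)
    signed <- NA_real_
  } else {
    weight <- abs(avg)
    signed <- avg
  }
  flags <- character()
  if (!is.null(degen) && any(degen)) flags <- "degenerate_bins"
  conn_network(
    tibble(node_i = acc$pair_i, node_j = acc$pair_j,
           weight = weight, signed_value = signed),
    nodes, metric = metric, band = band_hz, n_trials = acc$n_trials,
    flags = flags)
}

network_from_epochs <- function(epochs, metric, nodes, band_hz) {
  nc <- nrow(nodes)
  pr <- pair_index(nc)
  if (metric == "COR") {
    r <- correlation(epochs)
    flags <- if (any(attr(r, "degenerate"))) "degenerate_pairs" else character()
    edges <- tibble(node_i = pr$i, node_j = pr$j,
                    weight = abs(as.numeric(r)), signed_value = as.numeric(r))
  } else {
    xc <- cross_correlation(epochs)
    flags <- if (any(attr(xc, "degenerate"))) "degenerate_pairs" else character()
    edges <- tibble(node_i = xc$node_i, node_j = xc$node_j,
                    weight = xc$value, lag = xc$lag)
  }
  conn_network(edges, nodes, metric = metric,
               band = c(NA_real_, NA_real_),
               n_trials = length(epochs), flags = flags)
}

#' Switch the engine's metric on the fly
#'
#' Spectral metrics are recomputed directly from the always-maintained
#' accumulator — no raw data are touched. Switching to COR/XCOR needs the
#' epoch store (storage mode). The result is identical to a fresh engine fed
#' the same epochs; a round trip (e.g. COH to PLI and back) reproduces the
#' original network bit-identically.
#'
#' @param engine a [connectivity_engine()]
#' @param new_metric metric name
#' @return the current network under the new metric
#' @export
switch_metric <- function(engine, new_metric) {
  new_metric <- metric_id(new_metric)
  if (new_metric %in% c("COR", "XCOR")) {
    if (!engine$storage_mode) {
      config_error("switching to COR/XCOR requires storage_mode = TRUE")
    }
    if (!identical(engine$metric, new_metric)) {
      engine$td <- td_rebuild(new_metric, engine$epoch_store,
                              pair_index(engine$n_channels))
    }
  } else if (engine$metric %in% c("COR", "XCOR")) {
    engine$td <- NULL
  }
  engine$metric <- new_metric
  current_network(engine)
}

#' Reset an engine
#'
#' Zeroes all accumulators, caches and counters while keeping the
#' configuration (metric, band, window, storage mode, horizon).
#'
#' @param engine a [connectivity_engine()]
#' @return the engine, invisibly
#' @export
reset <- function(engine) UseMethod("reset")

#' @export
reset.conn_engine <- function(engine) {
  engine$acc <- spectral_accumulator(engine$n_channels, engine$nfft,
                                     engine$channel_names)
  engine$cached_spectra <- list()
  engine$epoch_store <- list()
  engine$n_seen <- 0L
  engine$n_fft_columns <- 0L
  engine$fft_per_trial <- integer()
  engine$td <- NULL
  invisible(engine)
}

#' One-row engine summary
#' @param x a [connectivity_engine()]
#' @param ... unused
#' @return tibble with configuration and instrumentation counters
#' @exportS3Method generics::glance
glance.conn_engine <- function(x, ...) {
  tibble(metric = x$metric, n_channels = x$n_channels, nfft = x$nfft,
         fmin = x$band_hz[1L], fmax = x$band_hz[2L],
         n_trials = x$acc$n_trials, n_seen = x$n_seen,
         storage_mode = x$storage_mode,
         horizon = if (is.finite(x$horizon)) x$horizon else NA_integer_,
         n_fft_columns = x$n_fft_columns)
}

#' One-shot batch connectivity over a set of epochs
#'
#' Computes the same network as feeding the epochs one by one to a
#' [connectivity_engine()] (bit-identical under the fixed-order contract):
#' spectra per trial, sums in trial order, metric formulas, band average.
#'
#' @param epochs list of epochs / matrices
#' @param metric metric name
#' @param fs sampling rate in Hz
#' @param nfft FFT length
#' @param fmin,fmax band in Hz
#' @param window taper kind
#' @param channel_names optional node labels
#' @return a [conn_network()]
#' @export
batch_connectivity <- function(epochs, metric, fs, nfft,
                               fmin = 0, fmax = fs / 2,
                               window = c("hanning", "ones"),
                               channel_names = NULL) {
  metric <- metric_id(metric)
  window <- match.arg(window)
  stopifnot(length(epochs) >= 1L)
  nc <- nrow(epoch_data(epochs[[1L]]))
  nodes <- tibble(id = seq_len(nc),
                  label = channel_names %||% paste0("ch", seq_len(nc)))
  if (metric %in% c("COR", "XCOR")) {
    return(network_from_epochs(lapply(epochs, epoch_data), metric, nodes,
                               c(NA_real_, NA_real_)))
  }
  band <- band_bins(fmin, fmax, fs, nfft)
  acc <- spectral_accumulator(nc, nfft, nodes$label)
  for (e in epochs) {
    d <- epoch_data(e)
    acc <- accumulate_trial(acc, trial_spectra(d, make_window(window, ncol(d)),
                                               nfft, fs = fs))
  }
  network_from_acc(acc, metric, band, nodes, c(fmin, fmax))
}

#' Cut a continuous stream into sliding-window pseudo-trials
#'
#' Spontaneous/resting-state blocks are handled as if they were multiple
#' trials: windows of `window_length` samples are emitted every `step`
#' samples over the concatenated stream. Block boundaries do not affect the
#' emitted windows.
#'
#' @param blocks list of [stream_block()] (or one matrix)
#' @param window_length pseudo-trial length in samples
#' @param step hop size in samples (`1 <= step <= window_length`)
#' @return list of `channels x window_length` matrices (empty if the stream
#'   is shorter than one window)
#' @export
stream_as_trials <- function(blocks, window_length, step = window_length) {
  if (step < 1L || step > window_length) {
    config_error("need 1 <= step <= window_length")
  }
  data <- if (is.matrix(blocks)) blocks else concat_blocks(blocks)
  total <- ncol(data)
  if (window_length > total) return(list())
  starts <- seq(0L, total - window_length, by = step)
  lapply(starts, function(s) {
    data[, (s + 1L):(s + window_length), drop = FALSE]
  })
}
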