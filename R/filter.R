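#' Design a linear-phase FIR filter (windowed sinc)
#'
#' Designs low-, high- or band-pass FIR taps as an ideal sinc truncated by a
#' raised-cosine (Hann) window — the "cosine" design. Taps are symmetric
#' (exactly linear phase) and the tap count is forced odd so the group delay
#' `(n_taps - 1) / 2` is an integer number of samples. Low-pass taps are
#' normalized to unit DC gain; high-pass taps are the spectral inversion of a
#' low-pass (zero DC gain); band-pass is the difference of two low-passes.
#'
#' @param kind one of `"lowpass"`, `"highpass"`, `"bandpass"`
#' @param cutoffs cutoff frequency in Hz (two values for `"bandpass"`)
#' @param fs sampling rate in Hz
#' @param n_taps requested tap count; rounded up to the next odd integer.
#'   If `NULL`, chosen from `transition_bw` as `ceiling(3.1 * fs /
#'   transition_bw)` (the Hann-window mainlobe rule), again forced odd.
#' @param transition_bw transition bandwidth in Hz (used only when `n_taps`
#'   is `NULL`)
#' @return numeric tap vector with attributes `kind`, `cutoffs`, `fs`
#' @export
design_fir <- function(kind = c("lowpass", "highpass", "bandpass"),
                       cutoffs, fs, n_taps = NULL, transition_bw = NULL) {
  kind <- match.arg(kind)
  if (any(cutoffs <= 0) || any(cutoffs >= fs / 2)) {
    config_error("cutoff frequencies must lie strictly inside (0, fs/2)")
  }
  if (is.null(n_taps)) {
    if (is.null(transition_bw) || transition_bw <= 0) {
      config_error("give either `n_taps` or a positive `transition_bw`")
    }
    n_taps <- ceiling(3.1 * fs / transition_bw)
  }
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L  # integer group delay
  if (n_taps < 1L) config_error("`n_taps` must be positive")

  lp <- function(fc) {
    m <- n_taps - 1L
    n <- 0:m
    x <- n - m / 2
    h <- 2 * fc / fs * sinc(2 * fc / fs * x)
    w <- hann_window(n_taps)
    h <- h * w
    h / sum(h)  # exact unit DC gain
  }
  taps <- switch(kind,
    lowpass = lp(cutoffs[1L]),
    highpass = {
      h <- -lp(cutoffs[1L])
      h[(n_taps + 1L) / 2L] <- h[(n_taps + 1L) / 2L] + 1
      h
    },
    bandpass = {
      if (length(cutoffs) != 2L || cutoffs[1L] >= cutoffs[2L]) {
        config_error("bandpass needs cutoffs c(flow, fhigh) with flow < fhigh")
      }
      lp(cutoffs[2L]) - lp(cutoffs[1L])
    })
  structure(taps, kind = kind, cutoffs = cutoffs, fs = fs)
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

hann_window <- function(L) {
  if (L == 1L) return(1)
  n <- 0:(L - 1L)
  0.5 * (1 - cos(2 * pi * n / (L - 1L)))
}

#' Create streaming FIR filter state
#'
#' The filter runs block-wise by overlap-add: each incoming block is convolved
#' with the taps and the convolution tail is carried into the next block. The
#' emitted stream is the full convolution of the concatenated input advanced
#' by the group delay `(n_taps - 1) / 2` samples, i.e. time-aligned with the
#' input; the first output block is correspondingly shorter, and
#' [fir_flush()] emits the trailing delay worth of samples.
#'
#' @param taps FIR taps, e.g. from [design_fir()]
#' @param n_channels number of channels each block must carry
#' @return mutable state of class `fir_state`
#' @export
fir_filter <- function(taps, n_channels) {
  m <- length(taps)
  env <- new.env(parent = emptyenv())
  env$taps <- as.numeric(taps)
  env$delay <- (m - 1L) %/% 2L
  env$n_channels <- n_channels
  env$tail <- matrix(0, n_channels, max(m - 1L, 0L))  # pending conv tail
  env$in_end <- 0L    # samples consumed
  env$out_end <- 0L   # aligned samples emitted
  env$fs <- NULL
  env$channel_names <- NULL
  class(env) <- "fir_state"
  env
}

conv_rows <- function(data, taps) {
  m <- length(taps)
  if (m == 1L) return(data * taps)
  out <- matrix(0, nrow(data), ncol(data) + m - 1L)
  for (ch in seq_len(nrow(data))) {
    out[ch, ] <- stats::convolve(data[ch, ], rev(taps), type = "open")
  }
  out
}

#' Filter one stream block (overlap-add)
#'
#' @param state a [fir_filter()] state
#' @param block a [stream_block()]
#' @return the aligned filtered output as a `stream_block` (possibly with
#'   zero samples while the filter delay fills)
#' @export
fir_filter_block <- function(state, block) {
  if (nrow(block$data) != state$n_channels) {
    config_error("block channel count differs from filter state")
  }
  if (block$first_sample != state$in_end) {
    data_error("non-contiguous block fed to filter")
  }
  state$fs <- block$fs
  state$channel_names <- block$channel_names
  L <- n_samples(block)
  m <- length(state$taps)
  cf <- conv_rows(block$data, state$taps)  # channels x (L + m - 1)
  if (m > 1L) {
    cf[, seq_len(m - 1L)] <- cf[, seq_len(m - 1L), drop = FALSE] + state$tail
    state$tail <- cf[, (L + 1L):(L + m - 1L), drop = FALSE]
  }
  yfull <- cf[, seq_len(L), drop = FALSE]  # conv outputs at [in_end, in_end+L)
  emit_aligned(state, yfull, L, block)
}

emit_aligned <- function(state, yfull, L, block) {
  d <- state$delay
  idx <- state$in_end + seq_len(L) - 1L   # absolute full-conv indices
  keep <- idx >= d                         # aligned sample = idx - d
  state$in_end <- state$in_end + L
  out <- yfull[, keep, drop = FALSE]
  if (ncol(out) == 0L) return(NULL)        # delay still filling
  first <- state$out_end
  state$out_end <- state$out_end + ncol(out)
  stream_block(out, fs = state$fs, first_sample = first,
               channel_names = state$channel_names, trigger_row = NULL)
}

#' Flush the trailing filter delay
#'
#' Pushes `(n_taps - 1) / 2` zero samples through the filter so the aligned
#' output covers the full input length.
#'
#' @param state a [fir_filter()] state
#' @return the final `stream_block`, or `NULL` if nothing is pending
#' @export
fir_flush <- function(state) {
  d <- state$delay
  if (d == 0L || is.null(state$fs)) return(NULL)
  m <- length(state$taps)
  cf <- conv_rows(matrix(0, state$n_channels, d), state$taps)
  cf[, seq_len(m - 1L)] <- cf[, seq_len(m - 1L), drop = FALSE] + state$tail
  state$tail <- cf[, (d + 1L):(d + m - 1L), drop = FALSE]
  yfull <- cf[, seq_len(d), drop = FALSE]
  emit_aligned(state, yfull, d, NULL)
}

#' Filter a whole block sequence
#'
#' Convenience wrapper: runs [fir_filter_block()] over all blocks and a final
#' [fir_flush()], returning the filtered, time-aligned blocks.
#'
#' @param blocks list of [stream_block()]
#' @param taps FIR taps
#' @return list of filtered `stream_block`s
#' @export
filter_stream <- function(blocks, taps) {
  state <- fir_filter(taps, nrow(blocks[[1L]]$data))
  out <- lapply(blocks, function(b) fir_filter_block(state, b))
  out <- c(out, list(fir_flush(state)))
  out[!vapply(out, is.null, logical(1))]
}

# running covariance --------------------------------------------------------

#' Create running covariance state
#'
#' Emits the sample covariance matrix (denominator `n - 1`, per-channel mean
#' removed) each time `n_target` new samples have accumulated, then restarts
#' the accumulation with any surplus samples.
#'
#' @param n_target samples per covariance estimate (>= 2)
#' @return mutable state of class `cov_state`
#' @export
running_covariance <- function(n_target) {
  if (n_target < 2L) config_error("`n_target` must be at least 2")
  env <- new.env(parent = emptyenv())
  env$n_target <- as.integer(n_target)
  env$buffer <- NULL
  class(env) <- "cov_state"
  env
}

#' Feed a block to the running covariance
#'
#' @param state a [running_covariance()] state
#' @param block a [stream_block()]
#' @return list of covariance matrices completed by this block (possibly empty)
#' @export
cov_update <- function(state, block) {
  state$buffer <- if (is.null(state$buffer)) block$data
                  else cbind(state$buffer, block$data)
  out <- list()
  while (ncol(state$buffer) >= state$n_target) {
    seg <- state$buffer[, seq_len(state$n_target), drop = FALSE]
    state$buffer <- state$buffer[, -seq_len(state$n_target), drop = FALSE]
    out[[length(out) + 1L]] <- stats::cov(t(seg))
  }
  out
}
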