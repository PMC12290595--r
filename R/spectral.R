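#' Taper window
#'
#' @param kind `"hanning"` (symmetric Hann, zero endpoints) or `"ones"`
#' @param length window length in samples
#' @return numeric vector of window values
#' @export
make_window <- function(kind = c("hanning", "ones"), length) {
  kind <- match.arg(kind)
  if (length < 1L) config_error("window length must be >= 1")
  switch(kind, ones = rep(1, length), hanning = hann_window(length))
}

#' One-sided tapered spectra of one trial
#'
#' Multiplies each channel by the taper window, zero-pads to `nfft` samples,
#' and returns the one-sided discrete Fourier transform (bins 0 ..
#' `floor(nfft/2)`; bin k maps to frequency `k * fs / nfft`). No additional
#' scaling is applied — all derived connectivity metrics are scale-free
#' ratios.
#'
#' @param epoch a `conn_epoch`, [stream_block()], or plain
#'   `channels x samples` matrix
#' @param window taper values (length = number of samples) or a kind string
#'   for [make_window()]
#' @param nfft FFT length in bins (>= number of samples; shorter epochs are
#'   zero-padded, longer ones are an error — no segmentation)
#' @param fs sampling rate in Hz (taken from `epoch` when available)
#' @return object of class `trial_spectra`: list with complex `coeffs`
#'   (`channels x n_bins`), `nfft`, `fs`, `n_bins`
#' @export
trial_spectra <- function(epoch, window = "hanning", nfft, fs = NULL) {
  data <- if (is.matrix(epoch)) epoch else epoch$data
  if (is.null(fs)) fs <- if (is.list(epoch)) epoch$fs else NA_real_
  ns <- ncol(data)
  if (ns > nfft) {
    config_error(sprintf("epoch (%d samples) longer than nfft (%d); no segmentation",
                         ns, nfft))
  }
  if (is.character(window)) window <- make_window(window, ns)
  if (length(window) != ns) {
    config_error("window length must equal the number of samples")
  }
  n_bins <- nfft %/% 2L + 1L
  x <- data * rep(window, each = nrow(data))
  xp <- matrix(0, nfft, nrow(data))
  xp[seq_len(ns), ] <- t(x)
  coeffs <- t(stats::mvfft(xp))[, seq_len(n_bins), drop = FALSE]
  structure(list(coeffs = coeffs, nfft = as.integer(nfft), fs = fs,
                 n_bins = n_bins),
            class = "trial_spectra")
}

#' Cross- and power spectral densities of one trial
#'
#' Sign convention: `S_xy(f) = X_i(f) * Conj(X_j(f))`, so a positive phase of
#' `S_xy` means channel `j` lags channel `i`.
#'
#' @param spec a [trial_spectra()]
#' @param i,j channel indices (1-based)
#' @return list with complex `s_xy` and real `s_xx`, `s_yy` per bin
#' @export
csd_psd <- function(spec, i, j) {
  xi <- spec$coeffs[i, ]
  xj <- spec$coeffs[j, ]
  list(s_xy = xi * Conj(xj), s_xx = Mod(xi)^2, s_yy = Mod(xj)^2)
}

# pair enumeration in ascending lexicographic (i, j) order, i < j
pair_index <- function(n_channels) {
  i <- rep(seq_len(n_channels - 1L), times = (n_channels - 1L):1L)
  j <- unlist(lapply(seq_len(n_channels - 1L), function(a) (a + 1L):n_channels))
  list(i = i, j = j, n = length(i))
}

#' Create an empty spectral accumulator
#'
#' The accumulator carries the across-trial sums every spectral metric needs,
#' per channel pair (i < j, lexicographic order) and frequency bin:
#' `sum_csd` (Σ S_xy), `sum_unit_csd` (Σ S_xy/|S_xy|, 0 when |S_xy| = 0),
#' `sum_sign_im` (Σ sign(Im S_xy), with sign(0) = 0), `sum_im`, `sum_im_sq`,
#' `sum_abs_im`, `sum_nonzero_im` (count of trials with Im S_xy != 0, needed
#' by the unbiased squared PLI), and per channel `sum_psd` (Σ S_xx). Only the
#' upper half of the pair matrix is stored; statistics for (j, i) follow by
#' conjugation/sign flip.
#'
#' @param n_channels number of channels
#' @param nfft FFT length the trials will use
#' @param channel_names optional channel names
#' @return object of class `spectral_accumulator`
#' @export
spectral_accumulator <- function(n_channels, nfft, channel_names = NULL) {
  if (n_channels < 2L) config_error("need at least 2 channels")
  n_bins <- nfft %/% 2L + 1L
  pr <- pair_index(n_channels)
  zc <- matrix(complex(real = 0, imaginary = 0), pr$n, n_bins)
  zr <- matrix(0, pr$n, n_bins)
  structure(
    list(n_trials = 0L, n_channels = as.integer(n_channels),
         nfft = as.integer(nfft), n_bins = n_bins,
         pair_i = pr$i, pair_j = pr$j,
         channel_names = channel_names %||% paste0("ch", seq_len(n_channels)),
         sum_csd = zc, sum_unit_csd = zc,
         sum_sign_im = zr, sum_im = zr, sum_im_sq = zr, sum_abs_im = zr,
         sum_nonzero_im = zr,
         sum_psd = matrix(0, n_channels, n_bins)),
    class = "spectral_accumulator")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.spectral_accumulator <- function(x, ...) {
  cat(sprintf("<spectral_accumulator> %d ch (%d pairs) x %d bins, N = %d trials\n",
              x$n_channels, length(x$pair_i), x$n_bins, x$n_trials))
  invisible(x)
}

# per-trial statistics for all pairs at once (internal)
trial_pair_stats <- function(acc, spec) {
  ci <- spec$coeffs[acc$pair_i, , drop = FALSE]
  cj <- spec$coeffs[acc$pair_j, , drop = FALSE]
  csd <- ci * Conj(cj)
  mag <- Mod(csd)
  unit <- csd
  nz <- mag > 0
  unit[nz] <- csd[nz] / mag[nz]
  unit[!nz] <- 0 + 0i
  im <- Im(csd)
  list(csd = csd, unit = unit, im = im,
       sgn = sign(im), psd = Mod(spec$coeffs)^2)
}

#' Add one trial's spectra to the accumulator
#'
#' All sums are updated in place (functionally: an updated copy is returned)
#' and the trial count incremented. Accumulation in a fixed trial order is
#' deterministic; accumulating trials one by one equals the element-wise sum
#' of single-trial accumulators.
#'
#' @param acc a [spectral_accumulator()]
#' @param spec a [trial_spectra()] with matching channel count and nfft
#' @return the updated accumulator
#' @export
accumulate_trial <- function(acc, spec) {
  if (nrow(spec$coeffs) != acc$n_channels || spec$n_bins != acc$n_bins) {
    config_error("trial spectra shape does not match accumulator")
  }
  st <- trial_pair_stats(acc, spec)
  acc$sum_csd <- acc$sum_csd + st$csd
  acc$sum_unit_csd <- acc$sum_unit_csd + st$unit
  acc$sum_sign_im <- acc$sum_sign_im + st$sgn
  acc$sum_im <- acc$sum_im + st$im
  acc$sum_im_sq <- acc$sum_im_sq + st$im^2
  acc$sum_abs_im <- acc$sum_abs_im + abs(st$im)
  acc$sum_nonzero_im <- acc$sum_nonzero_im + (st$im != 0)
  acc$sum_psd <- acc$sum_psd + st$psd
  acc$n_trials <- acc$n_trials + 1L
  acc
}

#' Combine two accumulators
#'
#' Element-wise sum of all statistics. The canonical fixed trial order is
#' strictly sequential accumulation; combining contiguous partial
#' accumulators in trial order reproduces it exactly for the integer-valued
#' sums and up to floating-point associativity for the real/complex sums.
#' Bit-identical parallelism is obtained by partitioning the pair space
#' instead, which is embarrassingly independent.
#'
#' @param a,b accumulators with identical shape
#' @return combined accumulator
#' @export
combine_accumulators <- function(a, b) {
  if (a$n_channels != b$n_channels || a$nfft != b$nfft) {
    config_error("accumulators have different shapes")
  }
  for (f in c("sum_csd", "sum_unit_csd", "sum_sign_im", "sum_im",
              "sum_im_sq", "sum_abs_im", "sum_nonzero_im", "sum_psd")) {
    a[[f]] <- a[[f]] + b[[f]]
  }
  a$n_trials <- a$n_trials + b$n_trials
  a
}

#' Map a frequency band in Hz to an inclusive bin range
#'
#' Bins are 0-based: bin k covers frequency `k * fs / nfft`. The band is the
#' inclusive range `[round(fmin * nfft / fs), round(fmax * nfft / fs)]`.
#'
#' @param fmin,fmax band edges in Hz (`0 <= fmin <= fmax <= fs/2`)
#' @param fs sampling rate in Hz
#' @param nfft FFT length in bins
#' @return list with `fmin_bin`, `fmax_bin` (0-based, inclusive) and `n_bins`
#'   in the band
#' @export
band_bins <- function(fmin, fmax, fs, nfft) {
  if (fmax > fs / 2) config_error("`fmax` exceeds the Nyquist frequency")
  if (fmin < 0 || fmin > fmax) config_error("need 0 <= fmin <= fmax")
  b0 <- as.integer(round(fmin * nfft / fs))
  b1 <- as.integer(round(fmax * nfft / fs))
  list(fmin_bin = b0, fmax_bin = b1, n_bins = b1 - b0 + 1L)
}

# checkpointing -------------------------------------------------------------

#' Save / load an accumulator checkpoint
#'
#' Binary checkpoint so an online session can resume. The format is private
#' but versioned.
#'
#' @param acc a [spectral_accumulator()]
#' @param path file path
#' @return `path` invisibly (`save`), the accumulator (`load`)
#' @export
save_accumulator <- function(acc, path) {
  saveRDS(list(format = "connstream-accumulator", version = 1L, acc = acc), path)
  invisible(path)
}

#' @rdname save_accumulator
#' @export
load_accumulator <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "connstream-accumulator")) {
    data_error("not a connstream accumulator checkpoint")
  }
  if (x$version != 1L) data_error(sprintf("unsupported checkpoint version %s", x$version))
  x$acc
}
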