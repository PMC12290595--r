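#' Connectivity metric identifiers
#'
#' The closed set of supported estimators. `metric_id()` normalizes a
#' user-supplied name (case-insensitive; `IMAGCOH` is accepted as an alias of
#' `IMAGCOHY`).
#'
#' @export
CONN_METRICS <- c("COR", "XCOR", "COHY", "COH", "IMAGCOHY", "PLV",
                  "PLI", "USPLI", "WPLI", "DSWPLI")

#' @rdname CONN_METRICS
#' @param name metric name, case-insensitive
#' @return canonical metric id
#' @export
metric_id <- function(name) {
  up <- toupper(trimws(name))
  if (up == "IMAGCOH") up <- "IMAGCOHY"
  if (!up %in% CONN_METRICS) {
    config_error(sprintf("unknown metric '%s'; choose one of %s",
                         name, paste(CONN_METRICS, collapse = ", ")))
  }
  up
}

spectral_metrics <- function() setdiff(CONN_METRICS, c("COR", "XCOR"))

# --- per-bin spectral metrics ----------------------------------------------
# All operate on the across-trial sums; values are n_pairs x n_bins matrices
# (complex for COHY, signed for IMAGCOHY/USPLI/DSWPLI). Degenerate
# denominators yield 0 and are marked in the logical "degenerate" attribute.

#' Coherency (complex) per pair and bin
#'
#' `COHY = sum_csd / sqrt(sum_psd_i * sum_psd_j)`. Bins where either channel
#' has zero accumulated power return 0 and are flagged.
#'
#' @param acc a [spectral_accumulator()] with at least one trial
#' @return complex matrix `n_pairs x n_bins` with attribute `degenerate`
#' @export
coherency <- function(acc) {
  stopifnot(acc$n_trials >= 1L)
  denom2 <- acc$sum_psd[acc$pair_i, , drop = FALSE] *
            acc$sum_psd[acc$pair_j, , drop = FALSE]
  bad <- denom2 <= 0
  denom <- sqrt(pmax(denom2, 0))
  out <- acc$sum_csd
  out[!bad] <- out[!bad] / denom[!bad]
  out[bad] <- 0 + 0i
  structure(out, degenerate = bad)
}

#' Coherence per pair and bin: `|COHY|`
#' @inheritParams coherency
#' @return real matrix `n_pairs x n_bins` in \[0, 1\]
#' @export
coh <- function(acc) {
  cy <- coherency(acc)
  structure(Mod(unclass_attr(cy)), degenerate = attr(cy, "degenerate"))
}

#' Imaginary part of coherency per pair and bin
#'
#' Signed value in \[-1, 1\]; suppresses zero-lag (instantaneous) coupling.
#' Network edge weights use `|Im(COHY)|`; the signed value is retained.
#'
#' @inheritParams coherency
#' @return real matrix `n_pairs x n_bins`
#' @export
imagcohy <- function(acc) {
  cy <- coherency(acc)
  structure(Im(unclass_attr(cy)), degenerate = attr(cy, "degenerate"))
}

unclass_attr <- function(x) { attributes(x) <- attributes(x)["dim"]; x }

#' Phase-locking value per pair and bin: `|sum_unit_csd| / N`
#' @inheritParams coherency
#' @return real matrix in \[0, 1\]
#' @export
plv <- function(acc) {
  stopifnot(acc$n_trials >= 1L)
  Mod(acc$sum_unit_csd) / acc$n_trials
}

#' Phase-lag index per pair and bin: `|sum sign(Im S_xy)| / N`
#' @inheritParams coherency
#' @return real matrix in \[0, 1\]
#' @export
pli <- function(acc) {
  stopifnot(acc$n_trials >= 1L)
  abs(acc$sum_sign_im) / acc$n_trials
}

#' Unbiased squared phase-lag index per pair and bin
#'
#' Estimates squared PLI without small-sample bias via the sum over distinct
#' ordered trial pairs: `sum_{j != k} s_j s_k / (N (N - 1))` with
#' `s = sign(Im S_xy)`, computed as `((Σs)² − Σs²) / (N(N−1))` where `Σs²`
#' is the number of trials with nonzero imaginary part.
#'
#' @inheritParams coherency
#' @return real matrix in \[-1/(N-1), 1\]
#' @export
uspli <- function(acc) {
  n <- acc$n_trials
  if (n < 2L) config_error("USPLI needs at least 2 trials")
  (acc$sum_sign_im^2 - acc$sum_nonzero_im) / (n * (n - 1))
}

#' Weighted phase-lag index per pair and bin: `|sum_im| / sum_abs_im`
#'
#' Bins with `sum_abs_im = 0` (no imaginary component in any trial) return 0
#' and are flagged.
#'
#' @inheritParams coherency
#' @return real matrix in \[0, 1\] with attribute `degenerate`
#' @export
wpli <- function(acc) {
  stopifnot(acc$n_trials >= 1L)
  bad <- acc$sum_abs_im == 0
  out <- abs(acc$sum_im)
  out[!bad] <- out[!bad] / acc$sum_abs_im[!bad]
  out[bad] <- 0
  structure(out, degenerate = bad)
}

#' Debiased squared weighted phase-lag index per pair and bin
#'
#' `(sum_im² − sum_im_sq) / (sum_abs_im² − sum_im_sq)`: the ratio of sums
#' over distinct trial pairs of `Im_j Im_k` and `|Im_j| |Im_k|`. Degenerate
#' denominators (<= 0) return 0 and are flagged.
#'
#' @inheritParams coherency
#' @return real matrix in \[-1, 1\] with attribute `degenerate`
#' @export
dswpli <- function(acc) {
  n <- acc$n_trials
  if (n < 2L) config_error("DSWPLI needs at least 2 trials")
  num <- acc$sum_im^2 - acc$sum_im_sq
  den <- acc$sum_abs_im^2 - acc$sum_im_sq
  bad <- den <= 0
  out <- num
  out[!bad] <- out[!bad] / den[!bad]
  out[bad] <- 0
  structure(out, degenerate = bad)
}

#' Per-bin values of any spectral metric
#'
#' @param acc a [spectral_accumulator()]
#' @param metric spectral metric name (see [CONN_METRICS]; not COR/XCOR)
#' @return `n_pairs x n_bins` matrix (complex for COHY)
#' @export
metric_per_bin <- function(acc, metric) {
  metric <- metric_id(metric)
  switch(metric,
    COHY = coherency(acc), COH = coh(acc), IMAGCOHY = imagcohy(acc),
    PLV = plv(acc), PLI = pli(acc), USPLI = uspli(acc),
    WPLI = wpli(acc), DSWPLI = dswpli(acc),
    config_error(sprintf("%s is a time-domain metric; compute it from epochs", metric)))
}

#' Band-average per-bin metric values
#'
#' Arithmetic mean of per-bin values over the inclusive bin range. Signed
#' (and complex) metrics are averaged signed; taking the magnitude for edge
#' weights happens afterwards, in the network constructor.
#'
#' @param values `n_pairs x n_bins` matrix from [metric_per_bin()]
#' @param band a [band_bins()] result (0-based inclusive bin range)
#' @return per-pair vector (complex for COHY)
#' @export
band_average <- function(values, band) {
  cols <- (band$fmin_bin:band$fmax_bin) + 1L
  if (length(cols) < 1L || max(cols) > ncol(values)) {
    config_error("band lies outside the available bins")
  }
  rowMeans(values[, cols, drop = FALSE])
}

# --- time-domain metrics ---------------------------------------------------

epoch_data <- function(e) if (is.matrix(e)) e else e$data

# one trial's correlation contribution for all pairs
trial_cor <- function(x, pr, mode) {
  if (mode == "pearson") {
    xc <- x - rowMeans(x)
    nrm <- sqrt(rowSums(xc^2))
    num <- rowSums(xc[pr$i, , drop = FALSE] * xc[pr$j, , drop = FALSE])
    den <- nrm[pr$i] * nrm[pr$j]
  } else {
    num <- rowSums(x[pr$i, , drop = FALSE] * x[pr$j, , drop = FALSE]) / ncol(x)
    den <- rep(1, pr$n)
  }
  bad <- den == 0
  r <- numeric(pr$n)
  r[!bad] <- num[!bad] / den[!bad]
  list(r = r, degenerate = bad)
}

# one trial's normalized cross-correlation functions (n_pairs x (2 ns - 1)),
# computed by zero-padded FFT convolution; lag axis -(ns-1)..(ns-1)
trial_xcor <- function(x, pr, demean) {
  nc <- nrow(x)
  ns <- ncol(x)
  len <- stats::nextn(2L * ns - 1L, 2)
  if (demean) x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  xp <- matrix(0, len, nc)
  xp[seq_len(ns), ] <- t(x)
  X <- stats::mvfft(xp)
  # c(tau) = sum_t x_t y_{t+tau} = ifft(Conj(X_i) * X_j)
  prod <- Conj(X[, pr$i, drop = FALSE]) * X[, pr$j, drop = FALSE]
  cc <- Re(stats::mvfft(prod, inverse = TRUE)) / len
  pos <- t(cc[seq_len(ns), , drop = FALSE])                 # lags 0..ns-1
  neg <- if (ns > 1L) t(cc[(len - ns + 2L):len, , drop = FALSE])
         else matrix(0, pr$n, 0L)                           # lags -(ns-1)..-1
  fun <- cbind(neg, pos)
  den <- nrm[pr$i] * nrm[pr$j]
  bad <- den == 0
  fun[!bad, ] <- fun[!bad, , drop = FALSE] / den[!bad]
  fun[bad, ] <- 0
  list(fun = fun, degenerate = bad, lag_axis = -(ns - 1L):(ns - 1L))
}

# turn an averaged cross-correlation function into (value, lag) per pair
xcor_peak <- function(avg, lag_axis, degen) {
  best <- apply(abs(avg), 1L, which.max)
  value <- abs(avg[cbind(seq_len(nrow(avg)), best)])
  lag <- lag_axis[best]
  value[degen] <- 0
  lag[degen] <- 0L
  list(value = value, lag = as.integer(lag))
}

#' Across-trial correlation per channel pair
#'
#' Per-trial correlation of each channel pair, averaged across trials. The
#' default mode is Pearson (demeaned, variance-normalized); `mode = "dot"`
#' is the raw dot product divided by the number of samples (no demeaning, no
#' variance normalization). Pairs with a zero-variance (or, for `"dot"`,
#' zero) channel in some trial contribute 0 for that trial and are flagged.
#'
#' @param epochs list of epochs (or matrices), all with the same channel count
#' @param mode `"pearson"` or `"dot"`
#' @return per-pair vector (lexicographic i < j order) with attribute
#'   `degenerate`
#' @export
correlation <- function(epochs, mode = c("pearson", "dot")) {
  mode <- match.arg(mode)
  stopifnot(length(epochs) >= 1L)
  nc <- nrow(epoch_data(epochs[[1L]]))
  pr <- pair_index(nc)
  total <- numeric(pr$n)
  degen <- logical(pr$n)
  for (e in epochs) {
    tc <- trial_cor(epoch_data(e), pr, mode)
    total <- total + tc$r
    degen <- degen | tc$degenerate
  }
  structure(total / length(epochs), degenerate = degen)
}

#' Across-trial cross-correlation per channel pair
#'
#' For each trial, the normalized cross-correlation function of each pair is
#' computed in the frequency domain (zero-padded FFT convolution, identical
#' to the direct sliding dot product), the functions are averaged across
#' trials, and the maximum absolute value with its signed lag is returned.
#' Positive lag means the second channel is delayed relative to the first.
#' Pairs with a zero-energy channel return value 0 at lag 0 and are flagged.
#'
#' @param epochs list of epochs (or matrices)
#' @param demean subtract per-channel trial means before correlating
#' @return tibble with `pair`, `node_i`, `node_j`, `value`, `lag` and
#'   attribute `degenerate`
#' @export
cross_correlation <- function(epochs, demean = TRUE) {
  stopifnot(length(epochs) >= 1L)
  nc <- nrow(epoch_data(epochs[[1L]]))
  ns <- ncol(epoch_data(epochs[[1L]]))
  pr <- pair_index(nc)
  total <- matrix(0, pr$n, 2L * ns - 1L)
  degen <- logical(pr$n)
  lag_axis <- -(ns - 1L):(ns - 1L)
  for (e in epochs) {
    x <- epoch_data(e)
    if (ncol(x) != ns) config_error("all epochs must have the same length")
    tx <- trial_xcor(x, pr, demean)
    total <- total + tx$fun
    degen <- degen | tx$degenerate
  }
  pk <- xcor_peak(total / length(epochs), lag_axis, degen)
  structure(tibble(pair = seq_len(pr$n), node_i = pr$i, node_j = pr$j,
                   value = pk$value, lag = pk$lag),
            degenerate = degen)
}
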