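# Shared fixtures and independent oracles, all built in code.

# random multichannel epochs with a fixed seed
random_epochs <- function(n_trials, n_channels, n_samples, seed = 42) {
  withr::with_seed(seed, lapply(seq_len(n_trials), function(i) {
    matrix(rnorm(n_channels * n_samples), n_channels, n_samples)
  }))
}

# two channels oscillating at f0 with a fixed phase lag (degrees), plus noise
lagged_pair_epochs <- function(n_trials, f0 = 18, fs = 600, n_samples = 600,
                               lag_deg = 90, noise_sd = 0, seed = 1) {
  t <- (0:(n_samples - 1)) / fs
  x <- sin(2 * pi * f0 * t)
  y <- sin(2 * pi * f0 * t + lag_deg * pi / 180)
  withr::with_seed(seed, lapply(seq_len(n_trials), function(i) {
    rbind(x, y) + if (noise_sd > 0) matrix(rnorm(2 * n_samples, sd = noise_sd),
                                           2, n_samples) else 0
  }))
}

# --- independent oracles ---------------------------------------------------

# direct-sum one-sided DFT (no fft())
brute_dft <- function(x, nfft) {
  n <- 0:(length(x) - 1)
  vapply(0:(nfft %/% 2), function(k) {
    sum(x * exp(-2i * pi * k * n / nfft))
  }, complex(1))
}

# direct full convolution
brute_conv <- function(x, h) {
  out <- numeric(length(x) + length(h) - 1)
  for (t in seq_along(out)) {
    for (k in seq_along(h)) {
      i <- t - k + 1
      if (i >= 1 && i <= length(x)) out[t] <- out[t] + h[k] * x[i]
    }
  }
  out
}

# sliding-dot-product cross-correlation, lag axis -(n-1)..(n-1),
# c(tau) = sum_t x_t y_{t+tau}, normalized by the product of norms
brute_xcorr <- function(x, y) {
  n <- length(x)
  xd <- x - mean(x); yd <- y - mean(y)
  lags <- -(n - 1):(n - 1)
  vals <- vapply(lags, function(tau) {
    tt <- seq_len(n)
    keep <- tt + tau >= 1 & tt + tau <= n
    sum(xd[tt[keep]] * yd[tt[keep] + tau])
  }, numeric(1))
  vals / sqrt(sum(xd^2) * sum(yd^2))
}

# brute-force unbiased squared PLI from per-trial signs
brute_uspli <- function(s) {
  n <- length(s)
  tot <- 0
  for (j in seq_len(n)) for (k in seq_len(n)) if (j != k) tot <- tot + s[j] * s[k]
  tot / (n * (n - 1))
}

# brute-force debiased squared WPLI from per-trial imaginary parts
brute_dswpli <- function(im) {
  n <- length(im)
  num <- 0; den <- 0
  for (j in seq_len(n)) for (k in seq_len(n)) if (j != k) {
    num <- num + im[j] * im[k]
    den <- den + abs(im[j]) * abs(im[k])
  }
  if (den <= 0) 0 else num / den
}

# build a 2-channel, single-pair accumulator whose per-trial CSD values at
# each bin are prescribed (for formula-level metric tests)
acc_from_csd <- function(csd_trials, psd_i = NULL, psd_j = NULL) {
  n_bins <- length(csd_trials[[1]])
  acc <- spectral_accumulator(2, 2 * (n_bins - 1))
  for (k in seq_along(csd_trials)) {
    csd <- matrix(csd_trials[[k]], 1, n_bins)
    mag <- Mod(csd)
    unit <- ifelse(mag > 0, csd / mag, 0 + 0i)
    im <- Im(csd)
    acc$sum_csd <- acc$sum_csd + csd
    acc$sum_unit_csd <- acc$sum_unit_csd + unit
    acc$sum_sign_im <- acc$sum_sign_im + sign(im)
    acc$sum_im <- acc$sum_im + im
    acc$sum_im_sq <- acc$sum_im_sq + im^2
    acc$sum_abs_im <- acc$sum_abs_im + abs(im)
    acc$sum_nonzero_im <- acc$sum_nonzero_im + (im != 0)
    acc$sum_psd <- acc$sum_psd +
      rbind(if (is.null(psd_i)) Mod(csd) else psd_i[[k]],
            if (is.null(psd_j)) Mod(csd) else psd_j[[k]])
    acc$n_trials <- acc$n_trials + 1L
  }
  acc
}

# trigger stream: multichannel noise plus a trigger row pulsing at given samples
trigger_stream <- function(n_channels, n_samples, event_samples, fs = 100,
                           event_values = 1, seed = 3) {
  data <- withr::with_seed(seed,
    matrix(rnorm(n_channels * n_samples), n_channels, n_samples))
  trig <- numeric(n_samples)
  trig[event_samples + 1] <- event_values
  unname(rbind(data, trig))
}
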