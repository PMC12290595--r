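make_acc <- function(epochs, nfft = 64, window = "ones") {
  acc <- spectral_accumulator(nrow(epochs[[1]]), nfft)
  for (e in epochs) acc <- accumulate_trial(acc, trial_spectra(e, window, nfft))
  acc
}

test_that("coherency is 1 for identical channels and +/- i at 90 degrees", {
  eps <- lapply(random_epochs(5, 1, 64, seed = 1), function(e) rbind(e, e))
  cy <- coherency(make_acc(eps))
  good <- !attr(cy, "degenerate")
  expect_equal(Re(cy[good]), rep(1, sum(good)), tolerance = 1e-9)
  expect_equal(Im(cy[good]), rep(0, sum(good)), tolerance = 1e-9)

  # a single trial is degenerate: |COHY| = 1 wherever there is power
  one <- make_acc(random_epochs(1, 2, 64, seed = 2))
  cy1 <- coherency(one)
  expect_equal(Mod(cy1[!attr(cy1, "degenerate")]),
               rep(1, sum(!attr(cy1, "degenerate"))), tolerance = 1e-9)

  # noise-free 90 degree lag at the signal bin -> -i (second channel leads)
  nfft <- 64; k <- 7; n <- 0:(nfft - 1)
  pair <- rbind(sin(2 * pi * k * n / nfft), cos(2 * pi * k * n / nfft))
  cyl <- coherency(make_acc(lapply(1:3, function(i) pair)))
  expect_equal(cyl[1, k + 1], complex(real = 0, imaginary = -1),
               tolerance = 1e-9)
  expect_equal(abs(imagcohy(make_acc(lapply(1:3, function(i) pair)))[1, k + 1]),
               1, tolerance = 1e-9)
})

test_that("zero-lag mixtures have zero imaginary coherency", {
  eps <- lapply(random_epochs(8, 1, 64, seed = 3), function(e) {
    rbind(e, 3 * e)  # instantaneous scaling, no lag
  })
  ic <- imagcohy(make_acc(eps))
  expect_lt(max(abs(ic[!attr(ic, "degenerate")])), 1e-9)
})

test_that("PLV matches its definition and the Rayleigh small-sample mean", {
  # constant phase difference across trials -> 1
  nfft <- 64; k <- 5; n <- 0:(nfft - 1)
  pair <- rbind(cos(2 * pi * k * n / nfft), cos(2 * pi * k * n / nfft - 1.1))
  expect_equal(plv(make_acc(lapply(1:6, function(i) pair)))[1, k + 1], 1,
               tolerance = 1e-9)
  # N = 1 is degenerate: always 1 at bins with power
  acc1 <- make_acc(random_epochs(1, 2, 64, seed = 4))
  expect_equal(max(abs(plv(acc1) - 1)), 0, tolerance = 1e-9)

  # i.i.d. phases: E[PLV] ~ sqrt(pi / (4 N))
  n_trials <- 16
  reps <- 60
  vals <- withr::with_seed(12, vapply(seq_len(reps), function(r) {
    csd <- lapply(seq_len(n_trials), function(i) {
      exp(2i * pi * runif(2))  # 2 bins, unit magnitude, random phase
    })
    mean(plv(acc_from_csd(csd)))
  }, numeric(1)))
  expect_equal(mean(vals), sqrt(pi / (4 * n_trials)), tolerance = 0.15)
})

test_that("PLI counts imaginary-sign consistency", {
  ims <- list(c(0.5, 0.2), c(1.0, -3), c(0.1, 0.4), c(2, -0.5))
  csd <- lapply(ims, function(v) complex(real = c(1, 1), imaginary = v))
  acc <- acc_from_csd(csd)
  # bin 1: signs all +1 -> 1; bin 2: (+,-,+,-) -> 0
  expect_equal(pli(acc)[1, ], c(1, 0))
  # zero imaginary part everywhere -> 0
  zero <- acc_from_csd(lapply(1:4, function(i) complex(real = c(1, 1))))
  expect_equal(pli(zero)[1, ], c(0, 0))
})

test_that("USPLI equals the brute-force pairwise sum", {
  expect_error(uspli(acc_from_csd(list(complex(real = 1, imaginary = 1)))),
               class = "connstream_config_error")
  # all signs positive, N = 5
  acc <- acc_from_csd(lapply(1:5, function(i) 1 + 2i))
  expect_equal(uspli(acc)[1, 1], 1)
  # half +1 half -1, N = 4 -> -1/3
  accm <- acc_from_csd(lapply(c(1, 1, -1, -1), function(s) {
    complex(real = 1, imaginary = s)
  }))
  expect_equal(uspli(accm)[1, 1], -1 / 3)
  expect_equal(brute_uspli(c(1, 1, -1, -1)), -1 / 3)
  # all zero imaginary parts -> 0
  z <- acc_from_csd(lapply(1:4, function(i) complex(real = 1)))
  expect_equal(uspli(z)[1, 1], 0)
  # random sign patterns, including zeros, against the brute force
  withr::with_seed(31, for (rep in 1:20) {
    s <- sample(c(-1, 0, 1), size = sample(2:9, 1), replace = TRUE)
    acc <- acc_from_csd(lapply(s, function(si) complex(real = 1, imaginary = si)))
    expect_equal(uspli(acc)[1, 1], brute_uspli(s), tolerance = 1e-12)
  })
})

test_that("WPLI weights by the magnitude of the imaginary part", {
  acc <- acc_from_csd(lapply(c(2, -1), function(v) {
    complex(real = 1, imaginary = v)
  }))
  expect_equal(wpli(acc)[1, 1], 1 / 3)  # |2 - 1| / (2 + 1)
  same <- acc_from_csd(lapply(c(0.5, 2, 0.01), function(v) {
    complex(real = 1, imaginary = v)
  }))
  expect_equal(wpli(same)[1, 1], 1)
  z <- acc_from_csd(lapply(1:3, function(i) complex(real = 1)))
  expect_equal(wpli(z)[1, 1], 0)
  expect_true(attr(wpli(z), "degenerate")[1, 1])
})

test_that("DSWPLI equals the brute-force pairwise ratio", {
  acc <- acc_from_csd(lapply(c(1, -1), function(v) {
    complex(real = 1, imaginary = v)
  }))
  expect_equal(dswpli(acc)[1, 1], -1)  # (0 - 2) / (4 - 2)
  pos <- acc_from_csd(lapply(c(0.3, 0.3, 0.3), function(v) {
    complex(real = 1, imaginary = v)
  }))
  expect_equal(dswpli(pos)[1, 1], 1)
  z <- acc_from_csd(lapply(1:3, function(i) complex(real = 1)))
  expect_equal(dswpli(z)[1, 1], 0)
  withr::with_seed(32, for (rep in 1:20) {
    im <- rnorm(sample(2:8, 1))
    acc <- acc_from_csd(lapply(im, function(v) complex(real = 1, imaginary = v)))
    expect_equal(dswpli(acc)[1, 1], brute_dswpli(im), tolerance = 1e-12)
  })
})

test_that("WPLI is 1 whenever PLI is 1 with all nonzero imaginary parts", {
  withr::with_seed(33, for (rep in 1:10) {
    im <- abs(rnorm(6)) + 0.01
    acc <- acc_from_csd(lapply(im, function(v) complex(real = 1, imaginary = v)))
    expect_equal(pli(acc)[1, 1], 1)
    expect_equal(wpli(acc)[1, 1], 1)
  })
})

test_that("metric bounds hold on random data for N in 1..50", {
  for (n in c(1, 2, 3, 7, 20, 50)) {
    acc <- make_acc(random_epochs(n, 3, 32, seed = 200 + n), nfft = 32)
    expect_true(all(coh(acc) <= 1 + 1e-9))
    expect_true(all(abs(imagcohy(acc)) <= 1 + 1e-9))
    expect_true(all(plv(acc) >= -1e-12 & plv(acc) <= 1 + 1e-9))
    expect_true(all(pli(acc) >= 0 & pli(acc) <= 1))
    w <- wpli(acc)
    expect_true(all(w >= 0 & w <= 1 + 1e-12))
    if (n >= 2) {
      u <- uspli(acc)
      expect_true(all(u >= -1 / (n - 1) - 1e-12 & u <= 1 + 1e-12))
      d <- dswpli(acc)
      expect_true(all(d >= -1 - 1e-9 & d <= 1 + 1e-9))
    }
    expect_true(all(Mod(coherency(acc)) <= 1 + 1e-9))
  }
})

test_that("spectral metrics are invariant to positive channel rescaling", {
  eps <- random_epochs(6, 3, 40, seed = 50)
  scaled <- lapply(eps, function(e) e * c(3.7, 0.01, 250))
  a1 <- make_acc(eps); a2 <- make_acc(scaled)
  for (m in c("COH", "IMAGCOHY", "PLV", "PLI", "WPLI", "USPLI", "DSWPLI")) {
    expect_equal(unclass(metric_per_bin(a1, m)), unclass(metric_per_bin(a2, m)),
                 tolerance = 1e-9, label = m)
  }
})

test_that("coherence of independent noise decreases with trial count", {
  mean_coh <- function(n) {
    acc <- make_acc(random_epochs(n, 2, 64, seed = 60))
    mean(coh(acc)[1, 2:32])
  }
  expect_gt(mean_coh(4), mean_coh(64))
  expect_lt(mean_coh(64), 0.35)
})

test_that("correlation averages per-trial Pearson values", {
  x <- rnorm(200)
  expect_equal(as.numeric(correlation(list(rbind(x, x)))), 1)
  expect_equal(as.numeric(correlation(list(rbind(x, -x)))), -1)
  # independent white noise: |r| < 0.1 with 1000 samples
  eps <- random_epochs(1, 2, 1000, seed = 70)
  expect_lt(abs(as.numeric(correlation(eps))), 0.1)
  # raw dot-product mode
  e <- matrix(c(1, 2, 2, 4, 3, 6), 2)
  expect_equal(as.numeric(correlation(list(e), mode = "dot")),
               sum(e[1, ] * e[2, ]) / 3)
  # zero-variance channel flagged
  r <- correlation(list(rbind(rep(1, 10), rnorm(10))))
  expect_equal(as.numeric(r), 0)
  expect_true(attr(r, "degenerate"))
})

test_that("FFT cross-correlation equals the sliding dot product", {
  eps <- random_epochs(1, 2, 73, seed = 80)
  xc <- cross_correlation(eps)
  oracle <- brute_xcorr(eps[[1]][1, ], eps[[1]][2, ])
  lag_axis <- -72:72
  expect_equal(xc$value, max(abs(oracle)), tolerance = 1e-9)
  expect_equal(xc$lag, lag_axis[which.max(abs(oracle))])

  # y = x delayed by 7 samples
  x <- withr::with_seed(81, rnorm(100))
  y <- c(rep(0, 7), x[1:93])
  d <- cross_correlation(list(rbind(x, y)))
  expect_equal(d$lag, 7L)
  expect_gt(d$value, 0.9)
  # identical signals peak at lag 0 with value 1
  s <- cross_correlation(list(rbind(x, x)))
  expect_equal(s$lag, 0L)
  expect_equal(s$value, 1, tolerance = 1e-9)
  # zero-energy channel -> (0, 0) with flag
  z <- cross_correlation(list(rbind(rep(0, 50), rnorm(50))))
  expect_equal(c(z$value, z$lag), c(0, 0))
  expect_true(attr(z, "degenerate"))
})

test_that("band averaging is the arithmetic mean over inclusive bins", {
  vals <- matrix(rep(c(0.4, 0.8), each = 5), nrow = 2, byrow = TRUE)
  vals <- rbind(vals[1, ], vals[2, ])
  band <- list(fmin_bin = 1L, fmax_bin = 3L)
  expect_equal(band_average(vals, band), c(0.4, 0.8))
  single <- list(fmin_bin = 2L, fmax_bin = 2L)
  expect_equal(band_average(matrix(1:10, 2, 5, byrow = TRUE), single),
               c(3, 8))
  m13 <- matrix(seq_len(31), 1)
  expect_equal(band_average(m13, list(fmin_bin = 18L, fmax_bin = 30L)),
               mean(19:31))
  expect_error(band_average(vals, list(fmin_bin = 3L, fmax_bin = 9L)),
               class = "connstream_config_error")
})

test_that("metric names resolve case-insensitively with the IMAGCOH alias", {
  expect_equal(metric_id("coh"), "COH")
  expect_equal(metric_id("ImagCoh"), "IMAGCOHY")
  expect_equal(metric_id("dswpli"), "DSWPLI")
  expect_error(metric_id("granger"), class = "connstream_config_error")
})
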