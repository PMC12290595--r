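test_that("rising-edge trigger detection finds events and honors prev_value", {
  mk <- function(trig, first = 0L, prev = 0) {
    b <- stream_block(rbind(0 * trig, trig), fs = 100, first_sample = first,
                      trigger_row = 2L)
    detect_events(b, prev_value = prev)
  }
  ev <- mk(c(0, 0, 5, 5, 0, 3))
  expect_equal(ev$sample, c(2L, 5L))
  expect_equal(ev$event_id, c(5L, 3L))

  expect_equal(nrow(mk(rep(0, 10))), 0L)
  # edge occurred in the prior block
  expect_equal(nrow(mk(c(2, 2, 0), prev = 2)), 0L)
  # a positive value at stream start counts
  expect_equal(mk(c(4, 4, 0))$sample, 0L)
  expect_error(detect_events(stream_block(matrix(0, 1, 3), 100), 0),
               class = "connstream_config_error")
})

test_that("event detection is invariant to how the stream is chunked", {
  full <- trigger_stream(2, 500, event_samples = c(0, 99, 101, 250, 499),
                         event_values = c(1, 2, 3, 1, 7))
  chunkings <- list(500L, c(100L, 100L, 100L, 100L, 100L),
                    c(1L, 99L, 250L, 150L), c(99L, 1L, 1L, 399L))
  ref <- NULL
  for (sizes in chunkings) {
    blocks <- as_stream_blocks(full, fs = 100, block_size = sizes,
                               trigger_row = 3L)
    prev <- 0
    evs <- list()
    for (b in blocks) {
      evs[[length(evs) + 1L]] <- detect_events(b, prev)
      prev <- b$data[3L, ncol(b$data)]
    }
    evs <- dplyr::bind_rows(evs)
    if (is.null(ref)) ref <- evs else expect_identical(evs, ref)
  }
  expect_equal(ref$sample, c(0L, 99L, 101L, 250L, 499L))
  expect_equal(ref$event_id, c(1L, 2L, 3L, 1L, 7L))
})

test_that("epoch windows follow the half-open round(t*fs) convention", {
  buf <- sample_buffer()
  blk <- stream_block(matrix(seq_len(2 * 400), 2, 400, byrow = TRUE), fs = 600)
  buffer_append(buf, blk)

  ep <- assemble_epoch(buf, list(sample = 100L, event_id = 1L),
                       tmin = -0.05, tmax = 0.16)
  expect_equal(ncol(ep$data), 126L)
  expect_equal(ep$data[1L, 1L], 71)  # absolute sample 70, 1-based col 71

  ep2 <- assemble_epoch(buf, list(sample = 100L, event_id = 1L), 0, 0.16)
  expect_equal(ncol(ep2$data), 96L)

  expect_error(assemble_epoch(buf, list(sample = 10L, event_id = 1L), -0.1, 0.1),
               class = "connstream_unavailable")
  expect_error(assemble_epoch(buf, list(sample = 390L, event_id = 1L), 0, 0.1),
               class = "connstream_not_ready")
})

test_that("baseline correction zeroes the baseline mean per channel", {
  ep <- structure(list(data = rbind(rep(5, 100), rnorm(100) + 3), fs = 100,
                       tmin = -0.5, event_id = 1L,
                       channel_names = c("a", "b"), baseline_applied = FALSE),
                  class = "conn_epoch")
  out <- baseline_correct(ep, -0.5, 0)
  expect_true(out$baseline_applied)
  expect_equal(out$data[1L, ], rep(0, 100))
  expect_equal(mean(out$data[2L, 1:50]), 0, tolerance = 1e-12)
  expect_error(baseline_correct(ep, -0.1, -0.1),
               class = "connstream_config_error")
})

test_that("amplitude rejection scans the subset outside the exclusion window", {
  mk_ep <- function(x) {
    structure(list(data = rbind(x, 0 * x), fs = 100, tmin = 0, event_id = 1L,
                   channel_names = c("eog", "meg"), baseline_applied = FALSE),
              class = "conn_epoch")
  }
  x <- rep(0.05, 100); x[30] <- 0.2
  expect_true(reject_epoch(mk_ep(x), threshold = 0.15, factor = 1,
                           channel_subset = "eog"))
  expect_false(reject_epoch(mk_ep(rep(0.05, 100)), 0.15, 1, "eog"))
  # sole suprathreshold sample sits inside the exclusion window
  expect_false(reject_epoch(mk_ep(x), 0.15, 1, "eog",
                            exclusion_window = c(0.29, 0.31)))
  # the threshold is on the scanned subset only
  expect_false(reject_epoch(mk_ep(x), 0.15, 1, "meg"))
  expect_error(reject_epoch(mk_ep(x), 0.15, 1, character()),
               class = "connstream_config_error")
})

test_that("streamed epoching equals offline epoching of the concatenation", {
  full <- trigger_stream(3, 2000, event_samples = c(150, 600, 1100, 1700),
                         fs = 200)
  run <- function(sizes) {
    blocks <- as_stream_blocks(full, fs = 200, block_size = sizes,
                               trigger_row = 4L)
    epoch_stream(blocks, tmin = -0.1, tmax = 0.4, baseline = c(-0.1, 0),
                 reject = list(threshold = 50, factor = 1))
  }
  offline <- run(2000L)
  streamed <- run(c(128L, 300L, 72L, 1000L, 500L))
  expect_equal(length(offline), 4L)
  expect_identical(lapply(streamed, `[[`, "data"),
                   lapply(offline, `[[`, "data"))
})

test_that("linear operators transform every sample column", {
  blk <- stream_block(matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12), 3, 4),
                      fs = 100)
  op <- matrix(c(1, 0, 0, 1, 1, 1), 2, 3)
  out <- apply_linear_operator(op, blk)
  expect_equal(out$data, op %*% blk$data)  # hand-checkable 2x4 product
  expect_equal(apply_linear_operator(diag(3), blk)$data, blk$data)
  expect_equal(apply_linear_operator(matrix(0, 2, 3), blk)$data,
               matrix(0, 2, 4))
  expect_error(apply_linear_operator(matrix(1, 2, 4), blk),
               class = "connstream_config_error")
})

test_that("operator files and fixture streams round-trip", {
  op <- matrix(round(rnorm(12), 4), 3, 4)
  f <- withr::local_tempfile(fileext = ".csv")
  write_operator(op, f)
  expect_equal(read_operator(f), op)

  d <- withr::local_tempdir()
  full <- trigger_stream(2, 300, event_samples = c(10, 200), fs = 128)
  write_fixture_stream(d, full, fs = 128, trigger_row = 3L, block_size = 100L)
  blocks <- read_fixture_stream(d)
  expect_length(blocks, 3L)
  expect_equal(blocks[[1L]]$fs, 128)
  expect_equal(blocks[[2L]]$first_sample, 100L)
  rebuilt <- do.call(cbind, lapply(blocks, function(b) b$data))
  expect_equal(rebuilt, full, tolerance = 1e-6)  # float32 storage
})

test_that("running covariance matches stats::cov per window and resets", {
  st <- running_covariance(50)
  x <- withr::with_seed(9, matrix(rnorm(3 * 130), 3, 130))
  blocks <- as_stream_blocks(x, fs = 100, block_size = c(30L, 80L, 20L))
  covs <- unlist(lapply(blocks, function(b) cov_update(st, b)),
                 recursive = FALSE)
  expect_length(covs, 2L)
  expect_equal(covs[[1L]], cov(t(x[, 1:50])))
  expect_equal(covs[[2L]], cov(t(x[, 51:100])))

  # constant channels -> zero matrix; identical channels -> correlation 1
  cst <- running_covariance(10)
  z <- cov_update(cst, stream_block(matrix(2, 3, 10), 100))[[1L]]
  expect_equal(z, matrix(0, 3, 3))
  two <- running_covariance(10)
  v <- rnorm(10)
  m <- cov_update(two, stream_block(rbind(v, v), 100))[[1L]]
  expect_equal(m[1, 2] / sqrt(m[1, 1] * m[2, 2]), 1)
  expect_error(running_covariance(1), class = "connstream_config_error")
})

test_that("sample covariance of white noise is near identity", {
  st <- running_covariance(10000)
  x <- withr::with_seed(11, matrix(rnorm(4 * 10000), 4, 10000))
  cv <- cov_update(st, stream_block(x, 1000))[[1L]]
  expect_lt(max(abs(cv - diag(4))), 0.1)
  # mean removal makes the estimate shift-invariant
  st2 <- running_covariance(10000)
  cv2 <- cov_update(st2, stream_block(x + c(100, -5, 0, 3), 1000))[[1L]]
  expect_equal(cv2, cv)
})
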