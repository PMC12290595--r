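#' Create a stream block
#'
#' A stream block is the unit of online processing: a contiguous chunk of
#' multichannel samples (`channels x samples`) with its absolute position in
#' the stream. Consecutive blocks from one source must have contiguous
#' `first_sample` (no gaps, no overlaps).
#'
#' @param data numeric matrix, `n_channels x n_samples`
#' @param fs sampling rate in Hz (> 0)
#' @param first_sample absolute 0-based index of the block's first sample
#' @param channel_names optional character vector of channel names
#' @param trigger_row optional 1-based row index of the integer trigger channel
#' @return an object of class `stream_block`
#' @export
stream_block <- function(data, fs, first_sample = 0L, channel_names = NULL,
                         trigger_row = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || ncol(data) < 1L) {
    config_error("`data` must be a numeric matrix with at least one sample")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    config_error("`fs` must be a single positive number")
  }
  if (first_sample < 0) config_error("`first_sample` must be >= 0")
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(rownames(data))) rownames(data)
                     else paste0("ch", seq_len(nrow(data)))
  }
  dimnames(data) <- NULL
  if (length(channel_names) != nrow(data)) {
    config_error("`channel_names` length must match the number of channels")
  }
  if (!is.null(trigger_row) &&
      (trigger_row < 1L || trigger_row > nrow(data))) {
    config_error("`trigger_row` out of range")
  }
  structure(
    list(data = data, fs = fs, first_sample = as.integer(first_sample),
         channel_names = channel_names,
         trigger_row = if (is.null(trigger_row)) NULL else as.integer(trigger_row)),
    class = "stream_block")
}

#' @export
print.stream_block <- function(x, ...) {
  cat(sprintf("<stream_block> %d ch x %d sp @ %g Hz, first_sample=%d%s\n",
              nrow(x$data), ncol(x$data), x$fs, x$first_sample,
              if (is.null(x$trigger_row)) "" else
                sprintf(", trigger_row=%d", x$trigger_row)))
  invisible(x)
}

n_samples <- function(block) ncol(block$data)

#' Split a multichannel recording into stream blocks
#'
#' Utility to turn an offline `channels x samples` matrix into a block
#' sequence, e.g. to replay a recording through the streaming path.
#'
#' @param data numeric matrix `channels x samples`
#' @param fs sampling rate in Hz
#' @param block_size samples per block (last block may be shorter); may also be
#'   an integer vector of block lengths summing to `ncol(data)`
#' @inheritParams stream_block
#' @return list of `stream_block`
#' @export
as_stream_blocks <- function(data, fs, block_size, channel_names = NULL,
                             trigger_row = NULL) {
  ns <- ncol(data)
  if (length(block_size) == 1L) {
    starts <- seq(0L, ns - 1L, by = block_size)
    lens <- pmin(block_size, ns - starts)
  } else {
    if (sum(block_size) != ns) {
      config_error("block lengths must sum to the number of samples")
    }
    starts <- cumsum(c(0L, block_size[-length(block_size)]))
    lens <- block_size
  }
  purrr::map2(starts, lens, function(s, l) {
    stream_block(data[, (s + 1L):(s + l), drop = FALSE], fs = fs,
                 first_sample = s, channel_names = channel_names,
                 trigger_row = trigger_row)
  })
}

concat_blocks <- function(blocks) {
  stopifnot(length(blocks) > 0L)
  first <- blocks[[1L]]$first_sample
  expect <- first
  for (b in blocks) {
    if (b$first_sample != expect) {
      data_error("blocks are not contiguous (gap or overlap in first_sample)")
    }
    expect <- b$first_sample + n_samples(b)
  }
  do.call(cbind, lapply(blocks, function(b) b$data))
}

# fixture stream format -----------------------------------------------------
# A directory holding meta.json plus raw little-endian float32 samples,
# stored sample-major (column-major layout of the channels x samples matrix).

#' Write a fixture stream directory
#'
#' The fixture format is a directory with `meta.json` (fs, channel names,
#' trigger row, dtype, block size, sample count) and `data.bin`, raw
#' little-endian float32 of the `channels x samples` matrix in column-major
#' (sample-major) order.
#'
#' @param dir output directory (created if missing)
#' @param data numeric matrix `channels x samples`
#' @param fs sampling rate in Hz
#' @param channel_names character vector of channel names
#' @param trigger_row optional 1-based trigger row index
#' @param block_size block size the reader should emit
#' @return `dir`, invisibly
#' @export
write_fixture_stream <- function(dir, data, fs, channel_names = NULL,
                                 trigger_row = NULL, block_size = 1000L) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(data)))
  meta <- list(
    format = "connstream-fixture-v1",
    fs = fs,
    n_channels = nrow(data),
    n_samples = ncol(data),
    channel_names = channel_names,
    trigger_row = trigger_row,
    dtype = "float32le",
    block_size = as.integer(block_size)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  invisible(dir)
}

#' Read a fixture stream directory as a list of stream blocks
#'
#' @param dir fixture directory written by [write_fixture_stream()]
#' @param block_size optional override of the block size recorded in the meta
#' @return list of [stream_block()]
#' @export
read_fixture_stream <- function(dir, block_size = NULL) {
  meta_path <- file.path(dir, "meta.json")
  if (!file.exists(meta_path)) config_error("no meta.json in fixture directory")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "connstream-fixture-v1")) {
    data_error("unrecognized fixture format")
  }
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = numeric(), size = 4L,
                 n = meta$n_channels * meta$n_samples, endian = "little")
  if (length(raw) != meta$n_channels * meta$n_samples) {
    data_error("data.bin shorter than declared in meta.json")
  }
  data <- matrix(raw, nrow = meta$n_channels)
  bs <- if (is.null(block_size)) meta$block_size else block_size
  trig <- meta$trigger_row
  if (!is.null(trig) && (length(trig) == 0L || is.na(trig))) trig <- NULL
  as_stream_blocks(data, fs = meta$fs, block_size = bs,
                   channel_names = meta$channel_names, trigger_row = trig)
}

#' Block processing deadline
#'
#' The wall-clock budget an online pipeline has to process one block before
#' the next one arrives: `block_size / fs` seconds.
#'
#' @param block_size block length in samples
#' @param fs sampling rate in Hz
#' @return deadline in milliseconds
#' @export
block_deadline_ms <- function(block_size, fs) 1000 * block_size / fs
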