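#' Detect trigger events in a stream block
#'
#' An event is a rising transition of the trigger channel from a value `<= 0`
#' to a value `> 0`. Transitions across block boundaries are detected through
#' `prev_value`, the trigger value at the last sample of the previous block
#' (0 at stream start, so a positive trigger at absolute sample 0 counts as an
#' event). The event id is the trigger value rounded to the nearest integer.
#'
#' @param block a [stream_block()] with a trigger row
#' @param prev_value trigger value at the last sample of the previous block
#' @return tibble with columns `sample` (absolute 0-based) and `event_id`,
#'   sorted by `sample`
#' @export
detect_events <- function(block, prev_value = 0) {
  if (is.null(block$trigger_row)) {
    config_error("block has no trigger row; cannot detect events")
  }
  trig <- unname(block$data[block$trigger_row, ])
  prev <- c(prev_value, trig[-length(trig)])
  hit <- prev <= 0 & trig > 0
  tibble(sample = block$first_sample + which(hit) - 1L,
         event_id = as.integer(round(trig[hit])))
}

# rolling sample store ------------------------------------------------------
# Mutable buffer over the concatenated stream; keeps a suffix of the stream
# so epochs can be cut as soon as their poststimulus samples have arrived.

#' Create a rolling sample buffer
#'
#' @param keep number of trailing samples to retain after trimming
#'   (default: keep everything; [epoch_stream()] trims adaptively)
#' @return a mutable buffer object of class `sample_buffer`
#' @export
sample_buffer <- function(keep = Inf) {
  env <- new.env(parent = emptyenv())
  env$data <- NULL          # channels x samples
  env$origin <- 0L          # absolute index of column 1
  env$end <- 0L             # absolute index one past the last column
  env$keep <- keep
  env$fs <- NULL
  env$channel_names <- NULL
  class(env) <- "sample_buffer"
  env
}

#' Append a stream block to a buffer
#'
#' @param buf a [sample_buffer()]
#' @param block a [stream_block()]; must be contiguous with what was appended
#'   so far
#' @param trim_before optional absolute sample index before which samples may
#'   be discarded
#' @return the buffer, invisibly
#' @export
buffer_append <- function(buf, block, trim_before = NULL) {
  if (is.null(buf$data)) {
    if (block$first_sample != 0L) {
      data_error("stream must start at absolute sample 0")
    }
    buf$data <- block$data
    buf$fs <- block$fs
    buf$channel_names <- block$channel_names
    buf$end <- n_samples(block)
  } else {
    if (block$first_sample != buf$end) {
      data_error("non-contiguous block appended to buffer")
    }
    buf$data <- cbind(buf$data, block$data)
    buf$end <- buf$end + n_samples(block)
  }
  cut <- buf$origin
  if (!is.null(trim_before)) cut <- max(cut, trim_before)
  if (is.finite(buf$keep)) cut <- max(cut, buf$end - buf$keep)
  if (cut > buf$origin) {
    drop <- cut - buf$origin
    buf$data <- buf$data[, -seq_len(drop), drop = FALSE]
    buf$origin <- as.integer(cut)
  }
  invisible(buf)
}

#' Cut one epoch around an event
#'
#' Returns the half-open window `[event$sample + round(tmin*fs),
#' event$sample + round(tmax*fs))` from the buffered stream. If the window
#' extends beyond the buffered data, an error of class `connstream_not_ready`
#' is signalled — the caller should retry after appending more blocks. If it
#' extends before stream start (or before trimmed history), the error class is
#' `connstream_unavailable`.
#'
#' @param buf a [sample_buffer()]
#' @param event one event: a list/row with `sample` and `event_id`
#' @param tmin,tmax epoch window in seconds relative to the event (`tmin < tmax`)
#' @return an object of class `conn_epoch` with fields `data`
#'   (`channels x samples`), `fs`, `tmin`, `event_id`, `baseline_applied`
#' @export
assemble_epoch <- function(buf, event, tmin, tmax) {
  if (tmin >= tmax) config_error("`tmin` must be < `tmax`")
  fs <- buf$fs
  start <- event$sample + time_to_sample(tmin, fs)
  end <- event$sample + time_to_sample(tmax, fs)
  if (start < 0L || start < buf$origin) {
    abort(sprintf("epoch window [%d, %d) starts before available data", start, end),
          class = c("connstream_unavailable", "connstream_error"))
  }
  if (end > buf$end) {
    abort(sprintf("epoch window [%d, %d) not yet buffered (stream at %d)",
                  start, end, buf$end),
          class = c("connstream_not_ready", "connstream_error"))
  }
  cols <- (start - buf$origin + 1L):(end - buf$origin)
  structure(
    list(data = buf$data[, cols, drop = FALSE],
         fs = fs, tmin = tmin, event_id = event$event_id,
         channel_names = buf$channel_names,
         baseline_applied = FALSE),
    class = "conn_epoch")
}

#' @export
print.conn_epoch <- function(x, ...) {
  cat(sprintf("<conn_epoch> %d ch x %d sp @ %g Hz, tmin=%g s, event_id=%s%s\n",
              nrow(x$data), ncol(x$data), x$fs, x$tmin,
              x$event_id, if (x$baseline_applied) ", baseline-corrected" else ""))
  invisible(x)
}

#' Baseline-correct an epoch
#'
#' Subtracts from each channel its mean over the baseline window
#' `[bmin, bmax)` (seconds relative to the event).
#'
#' @param epoch a `conn_epoch`
#' @param bmin,bmax baseline window in seconds relative to the event
#' @return the corrected epoch with `baseline_applied = TRUE`
#' @export
baseline_correct <- function(epoch, bmin, bmax) {
  fs <- epoch$fs
  i0 <- time_to_sample(bmin, fs) - time_to_sample(epoch$tmin, fs)
  i1 <- time_to_sample(bmax, fs) - time_to_sample(epoch$tmin, fs)
  if (i1 <= i0) config_error("baseline window maps to zero samples")
  if (i0 < 0L || i1 > ncol(epoch$data)) {
    config_error("baseline window lies outside the epoch")
  }
  mns <- rowMeans(epoch$data[, (i0 + 1L):i1, drop = FALSE])
  epoch$data <- epoch$data - mns
  epoch$baseline_applied <- TRUE
  epoch
}

#' Amplitude-threshold artifact rejection
#'
#' An epoch is rejected when the maximum absolute amplitude over the selected
#' channels, outside the exclusion window, exceeds `threshold * factor`.
#' The exclusion window (e.g. covering a stimulus artifact) is removed from
#' the scan before thresholding.
#'
#' @param epoch a `conn_epoch`
#' @param threshold rejection threshold in signal units
#' @param factor scale multiplier; the effective limit is `threshold * factor`
#' @param channel_subset channel names to scan (default: all channels)
#' @param exclusion_window optional `c(t0, t1)` in seconds relative to the
#'   event; samples in `[t0, t1)` are ignored
#' @return `TRUE` if the epoch should be rejected
#' @export
reject_epoch <- function(epoch, threshold, factor = 1,
                         channel_subset = NULL, exclusion_window = NULL) {
  limit <- threshold * factor
  if (!is.finite(limit) || limit <= 0) {
    config_error("`threshold * factor` must be positive")
  }
  if (is.null(channel_subset)) channel_subset <- epoch$channel_names
  if (length(channel_subset) == 0L) config_error("empty channel subset")
  rows <- match(channel_subset, epoch$channel_names)
  if (anyNA(rows)) {
    config_error(sprintf("unknown channels: %s",
                         paste(channel_subset[is.na(rows)], collapse = ", ")))
  }
  x <- epoch$data[rows, , drop = FALSE]
  if (!is.null(exclusion_window)) {
    fs <- epoch$fs
    off <- time_to_sample(epoch$tmin, fs)
    j0 <- time_to_sample(exclusion_window[1L], fs) - off
    j1 <- time_to_sample(exclusion_window[2L], fs) - off
    excl <- seq_len(ncol(x)) - 1L >= j0 & seq_len(ncol(x)) - 1L < j1
    x <- x[, !excl, drop = FALSE]
  }
  if (ncol(x) == 0L) return(FALSE)
  max(abs(x)) > limit
}

#' Epoch a block stream
#'
#' Drives the full evoked front end over a block sequence: trigger detection
#' (with cross-block carry), rolling buffering, epoch assembly, optional
#' baseline correction, and optional artifact rejection. Equivalent to
#' performing the same operations on the concatenated offline recording.
#'
#' @param blocks list of [stream_block()] (contiguous, starting at sample 0)
#' @param tmin,tmax epoch window in seconds relative to each event
#' @param baseline optional `c(bmin, bmax)` for [baseline_correct()]
#' @param reject optional list of arguments for [reject_epoch()]
#'   (`threshold`, `factor`, `channel_subset`, `exclusion_window`)
#' @param event_id optional integer: keep only events with this id
#' @return list of accepted `conn_epoch`s, with attributes `events`
#'   (tibble of all detected events) and `n_rejected`
#' @export
epoch_stream <- function(blocks, tmin, tmax, baseline = NULL, reject = NULL,
                         event_id = NULL) {
  buf <- sample_buffer()
  prev <- 0
  pending <- list()
  out <- list()
  events <- list()
  n_rejected <- 0L
  pre <- max(0L, -time_to_sample(tmin, blocks[[1L]]$fs))

  for (block in blocks) {
    ev <- detect_events(block, prev_value = prev)
    prev <- block$data[block$trigger_row, n_samples(block)]
    if (!is.null(event_id)) ev <- ev[ev$event_id == event_id, ]
    events[[length(events) + 1L]] <- ev
    if (nrow(ev) > 0L) {
      pending <- c(pending, lapply(seq_len(nrow(ev)), function(i) as.list(ev[i, ])))
    }
    # keep history back to the earliest pending epoch start
    trim <- if (length(pending) > 0L) {
      min(vapply(pending, `[[`, integer(1), "sample")) - pre
    } else {
      buf$end + n_samples(block) - pre
    }
    buffer_append(buf, block, trim_before = max(0L, trim))

    still <- list()
    for (p in pending) {
      ep <- tryCatch(assemble_epoch(buf, p, tmin, tmax),
                     connstream_not_ready = function(e) NULL,
                     connstream_unavailable = function(e) NA)
      if (is.null(ep)) { still[[length(still) + 1L]] <- p; next }
      if (!is.list(ep)) next  # unavailable: drop (prestimulus before stream start)
      if (!is.null(baseline)) ep <- baseline_correct(ep, baseline[1L], baseline[2L])
      if (!is.null(reject)) {
        bad <- do.call(reject_epoch, c(list(ep), reject))
        if (bad) { n_rejected <- n_rejected + 1L; next }
      }
      out[[length(out) + 1L]] <- ep
    }
    pending <- still
  }
  attr(out, "events") <- dplyr::bind_rows(events)
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Apply a linear (e.g. inverse) operator to a block or epoch
#'
#' Multiplies every sample column by `op`, mapping e.g. sensor-level data to a
#' source space. Metadata (fs, indices) are preserved; node identities become
#' the operator's rows.
#'
#' @param op numeric matrix `n_out x n_channels`
#' @param x a [stream_block()] or `conn_epoch`
#' @param out_names optional names for the output rows
#' @return an object of the same class as `x` with transformed data
#' @export
apply_linear_operator <- function(op, x, out_names = NULL) {
  op <- as.matrix(op)
  if (ncol(op) != nrow(x$data)) {
    config_error(sprintf("operator has %d columns but data has %d channels",
                         ncol(op), nrow(x$data)))
  }
  x$data <- op %*% x$data
  x$channel_names <- if (is.null(out_names)) paste0("src", seq_len(nrow(op)))
                     else out_names
  if (inherits(x, "stream_block")) x$trigger_row <- NULL
  x
}

#' Read a linear operator from a delimited file
#'
#' Expects a one-line header `# rows=<n_out> cols=<n_channels>` followed by a
#' comma-separated matrix.
#'
#' @param path file path
#' @return numeric matrix
#' @export
read_operator <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec("#\\s*rows=(\\d+)\\s+cols=(\\d+)", header))[[1L]]
  if (length(m) != 3L) data_error("operator file lacks '# rows=<r> cols=<c>' header")
  dims <- as.integer(m[2:3])
  op <- as.matrix(utils::read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(op) <- NULL
  if (!all(dim(op) == dims)) {
    data_error(sprintf("operator is %dx%d but header declares %dx%d",
                       nrow(op), ncol(op), dims[1L], dims[2L]))
  }
  op
}

#' Write a linear operator to a delimited file
#' @param op numeric matrix
#' @param path file path
#' @return `path`, invisibly
#' @export
write_operator <- function(op, path) {
  writeLines(sprintf("# rows=%d cols=%d", nrow(op), ncol(op)), path)
  utils::write.table(op, path, append = TRUE, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
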