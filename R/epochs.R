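#' Epoch container for multichannel EEG
#'
#' Bundles a block of stimulus-locked epochs as a numeric array
#' (`n_epochs x n_channels x n_times`, microvolts) together with per-epoch
#' condition labels, the time axis in ms and the sampling rate.
#'
#' @param data Numeric 3-D array, `n_epochs x n_channels x n_times`.
#' @param labels Character vector of condition labels, one per epoch.
#' @param times Numeric time axis in ms (strictly increasing).
#' @param rate_hz Sampling rate in Hz.
#' @param participant_id Participant identifier.
#' @return An `epoch_set` object.
#' @export
epoch_set <- function(data, labels, times, rate_hz, participant_id = "P01") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array (epochs x channels x times)")
  }
  if (length(labels) != dim(data)[1]) {
    abort("`labels` length must equal the number of epochs")
  }
  if (length(times) != dim(data)[3]) {
    abort("`times` length must equal the number of time samples")
  }
  if (any(diff(times) <= 0)) abort("`times` must be strictly increasing")
  structure(
    list(data = data, labels = as.character(labels), times = as.numeric(times),
         rate_hz = rate_hz, participant_id = participant_id),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %s: %d epochs x %d channels x %d samples @ %g Hz (%g..%g ms)\n",
    x$participant_id, d[1], d[2], d[3], x$rate_hz,
    min(x$times), max(x$times)))
  tab <- table(x$labels)
  cat("  conditions:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn epoch_set Long-format view: one row per epoch, channel, sample.
#' @param x An `epoch_set`.
#' @param ... Unused.
#' @export
tidy.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    epoch = rep(seq_len(d[1]), times = d[2] * d[3]),
    channel = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    time_ms = rep(x$times, each = d[1] * d[2]),
    condition = rep(x$labels, times = d[2] * d[3]),
    amplitude_uv = as.vector(x$data)
  )
}

EPOCH_MAGIC <- "MIDEPO1\n"

#' Read and write the portable epoch container
#'
#' A self-describing binary container: an ASCII magic string, a JSON header
#' (dimensions, labels, time axis, rate, participant, schema version, byte
#' order) and the epoch array as little-endian doubles. Round-trips exactly.
#'
#' @param x An `epoch_set`.
#' @param path File path.
#' @return `read_epochs()` returns an `epoch_set`; `write_epochs()` returns
#'   `path` invisibly.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epoch_set"))
  header <- jsonlite::toJSON(list(
    schema = "middecode-epochs", version = 1L,
    dim = dim(x$data), labels = x$labels, times = x$times,
    rate_hz = x$rate_hz, participant_id = x$participant_id,
    byte_order = "little"
  ), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(EPOCH_MAGIC, con, eos = NULL)
  raw_header <- charToRaw(as.character(header))
  writeBin(length(raw_header), con, size = 4L, endian = "little")
  writeBin(raw_header, con)
  writeBin(as.vector(x$data), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, nchars = nchar(EPOCH_MAGIC), useBytes = TRUE)
  if (!identical(magic, EPOCH_MAGIC)) {
    abort(sprintf("'%s' is not a middecode epoch container (bad magic bytes)",
                  path))
  }
  n_head <- readBin(con, "integer", size = 4L, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n_head)))
  if (!identical(header$schema, "middecode-epochs") || header$version != 1L) {
    abort(sprintf("'%s': unsupported epoch container schema", path))
  }
  n_vals <- prod(header$dim)
  vals <- readBin(con, "double", n = n_vals, size = 8L, endian = "little")
  if (length(vals) != n_vals) {
    abort(sprintf("'%s' is truncated: expected %d values, found %d",
                  path, n_vals, length(vals)))
  }
  epoch_set(array(vals, dim = header$dim), header$labels, header$times,
            header$rate_hz, header$participant_id)
}
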