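#' Multichannel time-series container
#'
#' Bundles an M x T numeric matrix of signals with a sampling rate and
#' channel names. This is the common currency of the simulation, source
#' reconstruction and connectivity functions.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param sampling_rate sampling rate in Hz.
#' @param channels optional character vector of channel names; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @return An object of class `ts_set` with elements `data`,
#'   `sampling_rate`, `channels`.
#' @export
ts_set <- function(data, sampling_rate = 1, channels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) stop("time series contain non-finite values")
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (is.null(channels)) channels <- paste0("ch", seq_len(nrow(data)))
  if (length(channels) != nrow(data))
    stop("length of 'channels' must equal nrow(data)")
  rownames(data) <- channels
  structure(
    list(data = data, sampling_rate = sampling_rate, channels = channels),
    class = "ts_set"
  )
}

#' @export
print.ts_set <- function(x, ...) {
  cat(sprintf("<ts_set> %d channels x %d samples @ %g Hz\n",
              nrow(x$data), ncol(x$data), x$sampling_rate))
  invisible(x)
}

#' @export
dim.ts_set <- function(x) dim(x$data)

#' Number of samples in a time-series set
#' @param x a `ts_set`.
#' @return integer sample count.
#' @export
n_samples <- function(x) ncol(x$data)

#' Number of channels in a time-series set
#' @param x a `ts_set`.
#' @return integer channel count.
#' @export
n_channels <- function(x) nrow(x$data)

#' Write / read a time-series set as plain text
#'
#' The samples go to a TSV (channels in columns) and the metadata
#' (sampling rate, channel names) to a JSON sidecar next to it.
#'
#' @param x a `ts_set`.
#' @param path path of the TSV file; the sidecar is `<path>.json`.
#' @return `write_ts_set` returns `path` invisibly; `read_ts_set` a `ts_set`.
#' @export
write_ts_set <- function(x, path) {
  stopifnot(inherits(x, "ts_set"))
  utils::write.table(t(x$data), path, sep = "\t", row.names = FALSE,
                     col.names = x$channels, quote = FALSE)
  jsonlite::write_json(
    list(sampling_rate_hz = x$sampling_rate, channels = x$channels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ts_set
#' @export
read_ts_set <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  ts_set(t(m), sampling_rate = meta$sampling_rate_hz,
         channels = meta$channels)
}
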