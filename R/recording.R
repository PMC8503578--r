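#' Multichannel recording container
#'
#' A `seizcoh_recording` is the package's basic data object: a channels x
#' samples matrix with labels, a sampling rate, per-channel types and a start
#' offset. Channel types are one of `"scalp"`, `"seeg"`, `"trigger"`,
#' `"refsine"`.
#'
#' @param data numeric matrix, channels x samples.
#' @param labels character vector, one label per row of `data`.
#' @param fs sampling rate in Hz.
#' @param channel_types character vector, one of scalp/seeg/trigger/refsine
#'   per channel.
#' @param start_offset recording start time in seconds (default 0).
#' @return an object of class `seizcoh_recording`.
#' @export
new_recording <- function(data, labels, fs, channel_types, start_offset = 0) {
  if (!is.matrix(data)) data <- matrix(data, nrow = 1L)
  if (length(labels) == 0L) stop("empty channel list")
  if (length(labels) != nrow(data))
    stop(sprintf("%d labels for %d data rows", length(labels), nrow(data)))
  if (anyDuplicated(labels)) stop("duplicate channel labels")
  stopifnot_scalar(fs, "fs")
  if (fs <= 0) stop("fs must be > 0")
  if (length(channel_types) == 1L)
    channel_types <- rep(channel_types, nrow(data))
  if (length(channel_types) != nrow(data))
    stop("channel_types length must match channel count")
  bad <- setdiff(unique(channel_types), c("scalp", "seeg", "trigger", "refsine"))
  if (length(bad)) stop("unknown channel type(s): ", paste(bad, collapse = ", "))
  if (anyNA(data)) stop("recording data contains NA")
  rownames(data) <- labels
  structure(
    list(labels = as.character(labels), fs = fs, data = data,
         channel_types = as.character(channel_types),
         start_offset = start_offset),
    class = "seizcoh_recording")
}

#' @export
print.seizcoh_recording <- function(x, ...) {
  cat(sprintf("<seizcoh_recording> %d channels x %d samples @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  tab <- table(x$channel_types)
  cat("  types:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[.seizcoh_recording` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$labels)
  if (anyNA(i)) stop("unknown channel label")
  new_recording(x$data[i, , drop = FALSE], x$labels[i], x$fs,
                x$channel_types[i], x$start_offset)
}

n_samples <- function(rec) ncol(rec$data)

#' Extract channels of a given type
#' @param rec a `seizcoh_recording`.
#' @param type channel type to keep.
#' @return a `seizcoh_recording` with only the matching channels.
#' @export
channels_of_type <- function(rec, type) {
  idx <- which(rec$channel_types == type)
  if (!length(idx)) stop("no channels of type '", type, "'")
  rec[idx]
}

## single channel as a vector, or NULL when absent
channel_or_null <- function(rec, type) {
  idx <- which(rec$channel_types == type)
  if (!length(idx)) return(NULL)
  rec$data[idx[1L], ]
}
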