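#' Band-pass filter specification
#'
#' Hamming windowed-sinc FIR design. The number of taps follows the Hamming
#' design rule, approximately 3.3 / (transition / fs), forced odd so the
#' filter is exactly linear-phase (type I) and the group delay is an integer.
#'
#' @param band c(low, high) passband edges in Hz (default 5-100).
#' @param transition transition bandwidth in Hz (default 2).
#' @return object of class `seizcoh_filterspec`.
#' @export
filter_spec <- function(band = c(5, 100), transition = 2) {
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must be c(low, high) with 0 < low < high")
  if (transition <= 0) stop("transition must be > 0")
  structure(list(band = as.numeric(band), transition = transition,
                 window = "hamming"), class = "seizcoh_filterspec")
}

filter_taps <- function(spec, fs) {
  n <- ceiling(3.3 * fs / spec$transition)
  if (n %% 2L == 1L) n <- n + 1L          # fir1 order n -> n+1 taps (odd)
  signal::fir1(n, spec$band / (fs / 2), type = "pass",
               window = signal::hamming(n + 1L))
}

## zero-phase FIR: symmetric taps applied by FFT convolution, group delay
## (ntaps-1)/2 compensated exactly
fir_zerophase <- function(x, h) {
  n <- length(x)
  k <- length(h)
  y <- stats::convolve(c(x, numeric(k)), rev(h), type = "open")
  off <- (k - 1L) %/% 2L
  y[(off + 1L):(off + n)]
}

#' Zero-phase band-pass filtering
#'
#' Applies the Hamming windowed-sinc FIR of `spec` to all scalp and SEEG
#' channels (trigger/refsine channels pass through untouched) with exact
#' group-delay compensation, so the output is zero-phase.
#'
#' @param rec a `seizcoh_recording`.
#' @param spec a `seizcoh_filterspec`.
#' @return the filtered recording.
#' @export
bandpass_fir <- function(rec, spec = filter_spec()) {
  stopifnot(inherits(rec, "seizcoh_recording"),
            inherits(spec, "seizcoh_filterspec"))
  if (spec$band[2] >= rec$fs / 2)
    stop("passband upper edge must be below the Nyquist frequency")
  h <- filter_taps(spec, rec$fs)
  out <- rec
  for (i in which(rec$channel_types %in% c("scalp", "seeg")))
    out$data[i, ] <- fir_zerophase(rec$data[i, ], h)
  out
}

#' Bipolar re-referencing of SEEG channels
#'
#' SEEG labels must follow shaft + zero-padded index naming (V01...V18).
#' Consecutive same-shaft contacts are subtracted, labeled "V01-V02"; pairs
#' are never formed across shafts. When `sensors` is supplied the geometric
#' midpoint of each pair is attached as attribute `"midpoints"` for the
#' spatial analysis.
#'
#' @param rec a `seizcoh_recording` containing SEEG channels.
#' @param sensors optional `seizcoh_sensors` with contact coordinates.
#' @return a `seizcoh_recording` of bipolar SEEG channels.
#' @export
bipolar_montage <- function(rec, sensors = NULL) {
  stopifnot(inherits(rec, "seizcoh_recording"))
  idx <- which(rec$channel_types == "seeg")
  if (!length(idx)) stop("no SEEG channels to re-reference")
  labs <- rec$labels[idx]
  m <- regmatches(labs, regexec("^([A-Za-z']+?)([0-9]+)$", labs))
  bad <- labs[vapply(m, length, 0L) != 3L]
  if (length(bad))
    stop("unparseable SEEG label(s): ", paste(bad, collapse = ", "))
  shaft <- vapply(m, `[`, "", 2L)
  num <- as.integer(vapply(m, `[`, "", 3L))
  out_lab <- character(0)
  out_dat <- NULL
  for (sh in unique(shaft)) {
    sel <- which(shaft == sh)
    sel <- sel[order(num[sel])]
    if (length(sel) < 2L) next
    adj <- which(diff(num[sel]) == 1L)
    if (!length(adj)) next
    i1 <- idx[sel[adj]]; i2 <- idx[sel[adj + 1L]]
    out_lab <- c(out_lab, paste0(rec$labels[i1], "-", rec$labels[i2]))
    out_dat <- rbind(out_dat,
                     rec$data[i1, , drop = FALSE] - rec$data[i2, , drop = FALSE])
  }
  if (is.null(out_dat)) stop("no adjacent same-shaft contact pairs found")
  out <- new_recording(out_dat, out_lab, rec$fs, "seeg", rec$start_offset)
  if (!is.null(sensors)) {
    mids <- bipolar_pairs(sensors$seeg)
    mids <- mids[match(out_lab, mids$label), ]
    attr(out, "midpoints") <- mids
  }
  out
}

#' Extract the ictal epoch around the seizure-onset marker
#'
#' @param rec a `seizcoh_recording`.
#' @param so seizure-onset time in s (on the recording's time axis).
#' @param pre s before onset to keep (default 20).
#' @param post s after onset (default 10).
#' @return a `seizcoh_recording` of `round((pre+post)*fs)` samples with the
#'   time axis re-zeroed (onset sits at `+pre` s); the onset sample index is
#'   attached as attribute `"so_sample"`.
#' @export
extract_epoch <- function(rec, so, pre = 20, post = 10) {
  stopifnot(inherits(rec, "seizcoh_recording"))
  if (pre <= 0 || post <= 0) stop("pre and post must be > 0")
  fs <- rec$fs
  first <- round((so - rec$start_offset - pre) * fs) + 1L
  n_out <- round((pre + post) * fs)
  if (first < 1L || first + n_out - 1L > ncol(rec$data))
    stop(sprintf("epoch [%g, %g] s outside the recording", so - pre, so + post))
  out <- new_recording(rec$data[, first:(first + n_out - 1L), drop = FALSE],
                       rec$labels, fs, rec$channel_types, start_offset = 0)
  attr(out, "so_sample") <- as.integer(round(pre * fs)) + 1L
  out
}
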