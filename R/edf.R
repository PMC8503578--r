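## European Data Format (EDF) reader and writer.
##
## EDF stores 16-bit integers per channel in fixed-duration data records,
## with an ASCII header (256 bytes + 256 per channel). Physical calibration
## is linear from (physical min, physical max, digital min, digital max).
## The writer stores the channel type in the transducer field ("type=seeg")
## and the start offset in the recording reserved field, so a seizcoh round
## trip preserves both; foreign files fall back to label heuristics.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s, type = "bytes") > width) s <- substr(s, 1L, width)
  formatC(s, width = -width)
}

edf_num <- function(x, width) {
  s <- formatC(x, width = 1, format = "g", digits = 7)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' @param rec a `seizcoh_recording`. The sample count must fill whole data
#'   records (records of 1 s when `fs` is an integer).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "seizcoh_recording"))
  ns <- nrow(rec$data)
  n <- ncol(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) < 1e-9) {
    rec_dur <- 1
    spr <- as.integer(round(fs))
  } else {
    ## non-integer rate: one record holding everything, duration n/fs
    rec_dur <- n / fs
    spr <- n
    if (nchar(formatC(rec_dur, format = "g", digits = 7)) > 8)
      stop("sampling rate not representable in an EDF record duration field")
  }
  if (n %% spr != 0L)
    stop(sprintf("sample count %d does not fill whole EDF records of %d samples", n, spr))
  n_rec <- n %/% spr

  pmin <- apply(rec$data, 1L, min)
  pmax <- apply(rec$data, 1L, max)
  ## widen degenerate ranges; then round through the 8-char ASCII fields so
  ## the scaling used for digitisation is exactly what a reader will parse
  flat <- pmax - pmin < 1e-12
  pmin[flat] <- pmin[flat] - 1
  pmax[flat] <- pmax[flat] + 1
  pmin_s <- vapply(pmin, edf_num, "", width = 8)
  pmax_s <- vapply(pmax, edf_num, "", width = 8)
  pmin <- as.numeric(pmin_s)
  pmax <- as.numeric(pmax_s)
  if (any(!is.finite(pmin)) || any(!is.finite(pmax)) || any(pmax <= pmin))
    stop("could not encode physical range in EDF header")

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(edf_pad("0", 8))
  wr(edf_pad("X X X X", 80))
  wr(edf_pad(sprintf("Startdate 01-JAN-2000 offset=%.9g", rec$start_offset), 80))
  wr(edf_pad("01.01.00", 8))
  wr(edf_pad("00.00.00", 8))
  wr(edf_pad(256L * (ns + 1L), 8))
  wr(edf_pad("", 44))
  wr(edf_pad(n_rec, 8))
  wr(edf_num(rec_dur, 8))
  wr(edf_pad(ns, 4))
  for (lab in rec$labels) wr(edf_pad(lab, 16))
  for (ty in rec$channel_types) wr(edf_pad(paste0("type=", ty), 80))
  for (i in seq_len(ns)) wr(edf_pad("uV", 8))
  for (s in pmin_s) wr(s)
  for (s in pmax_s) wr(s)
  for (i in seq_len(ns)) wr(edf_pad(-32768L, 8))
  for (i in seq_len(ns)) wr(edf_pad(32767L, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 80))
  for (i in seq_len(ns)) wr(edf_pad(spr, 8))
  for (i in seq_len(ns)) wr(edf_pad("", 32))

  scale <- (pmax - pmin) / 65535
  dig <- round((rec$data - pmin) / scale) - 32768
  dig[dig > 32767] <- 32767
  dig[dig < -32768] <- -32768
  ## records: for each record, channels consecutively
  dim(dig) <- c(ns, spr, n_rec)
  out <- as.integer(aperm(dig, c(2L, 1L, 3L)))
  writeBin(out, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @return a `seizcoh_recording`.
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nbytes) {
    raw <- readBin(con, "raw", nbytes)
    if (length(raw) < nbytes) stop("truncated EDF header in ", path)
    trimws(rawToChar(raw))
  }
  version <- rd(8)
  if (!identical(version, "0")) stop("not an EDF file (version field '", version, "')")
  rd(80)
  rec_info <- rd(80)
  rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("EDF header: invalid channel count")
  if (is.na(header_bytes) || header_bytes != 256L * (ns + 1L))
    stop(sprintf("EDF header: header byte count %s inconsistent with %d channels",
                 header_bytes, ns))
  rdv <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- rdv(16)
  transducer <- rdv(80)
  rdv(8)                                  # physical dimension
  pmin <- as.numeric(rdv(8))
  pmax <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8))
  dmax <- as.numeric(rdv(8))
  rdv(80)                                 # prefilter
  spr <- as.integer(rdv(8))
  rdv(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, spr)))
    stop("EDF header: unparseable numeric fields")
  if (length(unique(spr)) != 1L)
    stop("EDF with per-channel sampling rates is not supported (channels: ",
         paste(labels, collapse = ", "), ")")
  spr <- spr[1L]
  fs <- spr / rec_dur
  n <- spr * n_rec
  dig <- readBin(con, "integer", n_rec * ns * spr, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(dig) < n_rec * ns * spr)
    stop("EDF data shorter than header promises")
  dim(dig) <- c(spr, ns, n_rec)
  dat <- matrix(aperm(dig, c(2L, 1L, 3L)), nrow = ns, ncol = n)
  scale <- (pmax - pmin) / (dmax - dmin)
  dat <- dat * scale + (pmin - dmin * scale)

  types <- sub("^type=", "", transducer)
  known <- types %in% c("scalp", "seeg", "trigger", "refsine")
  types[!known] <- guess_channel_type(labels[!known])
  off <- 0
  m <- regmatches(rec_info, regexec("offset=([-0-9.eE+]+)", rec_info))[[1L]]
  if (length(m) == 2L) off <- as.numeric(m[2L])
  new_recording(dat, labels, fs, types, off)
}

guess_channel_type <- function(labels) {
  vapply(labels, function(l) {
    lu <- toupper(l)
    if (grepl("TRIG|STATUS|MARKER", lu)) "trigger"
    else if (grepl("REF50|SINE", lu)) "refsine"
    else if (grepl("^[A-Z]'?[0-9]{2,}$", lu)) "seeg"
    else "scalp"
  }, "")
}

#' Write a recording (dispatch on file extension)
#' @param rec a `seizcoh_recording`.
#' @param path path ending in `.edf`.
#' @export
write_recording <- function(rec, path) {
  if (!grepl("\\.edf$", path, ignore.case = TRUE))
    stop("write_recording only writes EDF ('.edf') files")
  write_edf(rec, path)
}

#' Read a recording (EDF or BrainVision header)
#' @param path path to an `.edf` or `.vhdr` file.
#' @export
read_recording <- function(path) {
  if (grepl("\\.vhdr$", path, ignore.case = TRUE)) read_brainvision(path)
  else if (grepl("\\.edf$", path, ignore.case = TRUE)) read_edf(path)
  else stop("unsupported recording format: ", path)
}
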