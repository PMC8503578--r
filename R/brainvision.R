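## BrainVision (.vhdr / .vmrk / .eeg) dialect reader, plus a minimal writer
## used to produce test fixtures and exchange data with other tools.
## Supported: binary INT_16 and IEEE_FLOAT_32, MULTIPLEXED or VECTORIZED
## orientation. Marker files are optional and attached as an attribute.

parse_vhdr_ini <- function(lines) {
  section <- ""
  out <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1L]]
    if (length(kv) == 3L) out[[section]][[trimws(kv[2L])]] <- trimws(kv[3L])
  }
  out
}

#' Read a BrainVision recording
#'
#' @param vhdr_path path to the `.vhdr` header; the data file referenced by
#'   the header is resolved relative to it.
#' @return a `seizcoh_recording`; markers (if a `.vmrk` is present) are
#'   attached as attribute `"markers"`.
#' @export
read_brainvision <- function(vhdr_path) {
  if (!file.exists(vhdr_path)) stop("file not found: ", vhdr_path)
  lines <- readLines(vhdr_path, warn = FALSE)
  if (!length(lines) || !grepl("Brain Vision Data Exchange Header File", lines[1L]))
    stop("not a BrainVision header: ", vhdr_path)
  ini <- parse_vhdr_ini(lines[-1L])
  ci <- ini[["Common Infos"]]
  if (is.null(ci)) stop("BrainVision header missing [Common Infos]")
  nchan <- as.integer(ci$NumberOfChannels)
  si_us <- as.numeric(ci$SamplingInterval)
  if (is.na(nchan) || nchan < 1L) stop("BrainVision header: bad NumberOfChannels")
  if (is.na(si_us) || si_us <= 0) stop("BrainVision header: bad SamplingInterval")
  fs <- 1e6 / si_us
  if (!identical(toupper(ci$DataFormat %||% "BINARY"), "BINARY"))
    stop("only BINARY BrainVision data is supported")
  orientation <- toupper(ci$DataOrientation %||% "MULTIPLEXED")
  fmt <- toupper(ini[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")

  chi <- ini[["Channel Infos"]]
  if (is.null(chi) || length(chi) != nchan)
    stop(sprintf("BrainVision header: %d channel entries for NumberOfChannels=%d",
                 length(chi), nchan))
  ord <- order(as.integer(sub("^Ch", "", names(chi))))
  chi <- chi[ord]
  labels <- character(nchan)
  resolution <- rep(1, nchan)
  for (i in seq_len(nchan)) {
    parts <- strsplit(chi[[i]], ",")[[1L]]
    labels[i] <- trimws(parts[1L])
    if (length(parts) >= 3L && nchar(trimws(parts[3L])))
      resolution[i] <- as.numeric(parts[3L])
  }

  data_path <- file.path(dirname(vhdr_path), ci$DataFile)
  if (!file.exists(data_path)) stop("BrainVision data file not found: ", data_path)
  fsize <- file.info(data_path)$size
  bytes <- switch(fmt, INT_16 = 2L, IEEE_FLOAT_32 = 4L,
                  stop("unsupported BinaryFormat: ", fmt))
  if (fsize %% (nchan * bytes) != 0L)
    stop(sprintf(paste0("BrainVision data size %d bytes is not a whole number of ",
                        "%d-channel frames (%s): mismatched sample counts"),
                 fsize, nchan, fmt))
  n <- as.integer(fsize %/% (nchan * bytes))
  con <- file(data_path, "rb")
  on.exit(close(con))
  raw <- if (fmt == "INT_16")
    readBin(con, "integer", n * nchan, size = 2L, signed = TRUE, endian = "little")
  else
    readBin(con, "numeric", n * nchan, size = 4L, endian = "little")
  dat <- if (orientation == "MULTIPLEXED") matrix(raw, nrow = nchan, ncol = n)
  else t(matrix(raw, nrow = n, ncol = nchan))
  dat <- dat * resolution

  rec <- new_recording(dat, labels, fs, guess_channel_type(labels))
  if (!is.null(ci$MarkerFile)) {
    mpath <- file.path(dirname(vhdr_path), ci$MarkerFile)
    if (file.exists(mpath)) {
      mk <- parse_vhdr_ini(readLines(mpath, warn = FALSE)[-1L])[["Marker Infos"]]
      if (!is.null(mk)) {
        mdf <- do.call(rbind, lapply(mk, function(s) {
          p <- trimws(strsplit(s, ",")[[1L]])
          data.frame(type = p[1L], description = p[2L],
                     sample = as.integer(p[3L]), stringsAsFactors = FALSE)
        }))
        attr(rec, "markers") <- mdf
      }
    }
  }
  rec
}

#' Write a BrainVision triplet (header, binary data, markers)
#'
#' Writes IEEE_FLOAT_32 multiplexed data. Mostly useful for tests and for
#' exporting to tools that read the BrainVision dialect.
#'
#' @param rec a `seizcoh_recording`.
#' @param vhdr_path output `.vhdr` path; `.eeg`/`.vmrk` siblings are derived.
#' @param markers optional data.frame with columns type, description, sample.
#' @export
write_brainvision <- function(rec, vhdr_path, markers = NULL) {
  stopifnot(inherits(rec, "seizcoh_recording"))
  base <- sub("\\.vhdr$", "", basename(vhdr_path))
  dir <- dirname(vhdr_path)
  eeg <- paste0(base, ".eeg")
  vmrk <- paste0(base, ".vmrk")
  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", eeg),
    if (!is.null(markers)) paste0("MarkerFile=", vmrk),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", nrow(rec$data)),
    sprintf("SamplingInterval=%.9g", 1e6 / rec$fs),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,uV", seq_along(rec$labels), rec$labels))
  writeLines(hdr, file.path(dir, paste0(base, ".vhdr")))
  con <- file(file.path(dir, eeg), "wb")
  writeBin(as.numeric(rec$data), con, size = 4L, endian = "little")
  close(con)
  if (!is.null(markers)) {
    ml <- c("Brain Vision Data Exchange Marker File, Version 1.0",
            "[Marker Infos]",
            sprintf("Mk%d=%s,%s,%d,1,0", seq_len(nrow(markers)),
                    markers$type, markers$description, markers$sample))
    writeLines(ml, file.path(dir, vmrk))
  }
  invisible(vhdr_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
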