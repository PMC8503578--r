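## Dual-amplifier stream alignment.
##
## The digital trigger channel gives a coarse integer lag (the 50 Hz sine
## alone is ambiguous modulo its period, fs/50 samples); the reference sine
## refines it to sub-sample precision within each trigger epoch. The fine
## estimator takes the integer cross-correlation peak of 2 s sine windows
## and refines the fractional part from the single-bin DFT phase difference
## at the reference frequency, which for a near-pure sine is far more
## accurate than parabolic interpolation of the (cosine-shaped) correlation
## peak; parabolic interpolation remains as fallback. Clock drift is the
## slope of the per-trigger lags over time.

trigger_onsets <- function(trig) {
  above <- trig > 0.5
  which(above & !c(FALSE, above[-length(above)]))
}

## phase of the fref component of x (Hann-windowed single-bin DFT)
tone_phase <- function(x, fs, fref) {
  n <- length(x)
  t <- (seq_len(n) - 1L) / fs
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1L) / (n - 1L))
  z <- sum(w * x * exp(-2i * pi * fref * t))
  Arg(z)
}

xcorr_int_peak <- function(a, b, max_lag) {
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(L) {
    ia <- seq_along(a)
    ib <- ia + L
    ok <- ib >= 1L & ib <= length(b)
    sum(a[ok] * b[ib[ok]])
  }, 0)
  list(lags = lags, cc = cc)
}

#' Align two independently clocked streams
#'
#' @param a,b `seizcoh_recording`s sharing trigger and reference-sine
#'   channels (types `"trigger"` and `"refsine"`).
#' @param window cross-correlation window length in s around each trigger.
#' @return object of class `seizcoh_alignment`: `coarse_lag` (integer
#'   samples), `fine_lag` (fractional samples, evaluated at stream a's first
#'   sample; positive means b's content is delayed), `drift` (ppm),
#'   `residual` (max absolute deviation of per-trigger lags from the linear
#'   fit, samples), `per_trigger` (data.frame), and `coarse_only` flag.
#' @export
align_streams <- function(a, b, window = 2) {
  stopifnot(inherits(a, "seizcoh_recording"), inherits(b, "seizcoh_recording"))
  if (a$fs != b$fs) stop("streams must share a nominal sampling rate")
  fs <- a$fs
  trig_a <- channel_or_null(a, "trigger")
  trig_b <- channel_or_null(b, "trigger")
  if (is.null(trig_a) || is.null(trig_b)) stop("both streams need a trigger channel")
  on_a <- trigger_onsets(trig_a)
  on_b <- trigger_onsets(trig_b)

  ## pair pulses: same underlying event sequence, possibly with pulses
  ## missing at either stream's edges; slide the shorter sequence over the
  ## longer and take the offset minimizing inter-stream spacing mismatch
  k <- min(length(on_a), length(on_b))
  if (k < 2L) stop("need at least 2 matching trigger pulses in both streams")
  best <- NULL
  for (sa in 0:(length(on_a) - k)) for (sb in 0:(length(on_b) - k)) {
    oa <- on_a[sa + seq_len(k)]
    ob <- on_b[sb + seq_len(k)]
    spread <- max(ob - oa) - min(ob - oa)
    if (is.null(best) || spread < best$spread)
      best <- list(oa = oa, ob = ob, spread = spread)
  }
  oa <- best$oa; ob <- best$ob
  ## content delay of b per pulse: b-position minus a-position of the event
  coarse_per <- ob - oa
  coarse_lag <- as.integer(round(stats::median(coarse_per)))

  ref_a <- channel_or_null(a, "refsine")
  ref_b <- channel_or_null(b, "refsine")
  tt <- (oa - 1L) / fs             # trigger times on a's clock
  if (is.null(ref_a) || is.null(ref_b)) {
    fit <- stats::lm(coarse_per ~ tt)
    out <- list(coarse_lag = coarse_lag,
                fine_lag = unname(stats::coef(fit)[1L]),
                drift = unname(stats::coef(fit)[2L]) / fs * 1e6,
                residual = max(abs(stats::residuals(fit))),
                per_trigger = data.frame(time = tt, lag = coarse_per),
                coarse_only = TRUE)
    return(structure(out, class = "seizcoh_alignment"))
  }

  fref <- dominant_freq(ref_a, fs)
  half <- round(window * fs / 2)
  period <- fs / fref
  lag_k <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    ca <- oa[i]; cb <- ob[i]
    ia <- (ca - half):(ca + half)
    if (ia[1L] < 1L || ia[length(ia)] > length(ref_a)) next
    ib <- (cb - half):(cb + half)
    if (ib[1L] < 1L || ib[length(ib)] > length(ref_b)) next
    wa <- ref_a[ia]; wb <- ref_b[ib]
    ## residual shift between the two windows beyond the pulse pairing; the
    ## trigger quantization bounds it to less than one sample, well inside
    ## half a sine period, so the phase difference resolves it unambiguously
    pa <- tone_phase(wa, fs, fref)
    pb <- tone_phase(wb, fs, fref)
    dphi <- Arg(exp(1i * (pa - pb)))         # principal value
    d <- dphi / (2 * pi * fref) * fs
    d <- d - round(d / period) * period      # wrap to +- half period
    if (!is.finite(d)) {                     # degenerate sine: parabolic peak
      pk <- xcorr_int_peak(wa, wb, max_lag = floor(period / 2))
      j <- which.max(pk$cc)
      d <- pk$lags[j]
      if (j > 1L && j < length(pk$cc)) {
        y1 <- pk$cc[j - 1L]; y2 <- pk$cc[j]; y3 <- pk$cc[j + 1L]
        d <- d + 0.5 * (y1 - y3) / (y1 - 2 * y2 + y3)
      }
    }
    ## content delay of b at this trigger
    lag_k[i] <- (cb - ca) + d
  }
  ok <- is.finite(lag_k)
  if (sum(ok) < 2L) stop("too few usable trigger epochs for fine alignment")
  fit <- stats::lm(lag_k[ok] ~ tt[ok])
  fine_lag <- unname(stats::coef(fit)[1L])
  slope <- unname(stats::coef(fit)[2L])       # samples of lag per second
  if (abs(fine_lag - coarse_lag) > period / 2)
    warning("fine lag differs from coarse lag by more than half a sine period")
  structure(list(coarse_lag = coarse_lag, fine_lag = fine_lag,
                 drift = slope / fs * 1e6,
                 residual = max(abs(stats::residuals(fit))),
                 per_trigger = data.frame(time = tt[ok], lag = lag_k[ok]),
                 coarse_only = FALSE),
            class = "seizcoh_alignment")
}

#' @export
print.seizcoh_alignment <- function(x, ...) {
  cat(sprintf("<alignment> coarse %d, fine %.3f samples, drift %.2f ppm, residual %.3f%s\n",
              x$coarse_lag, x$fine_lag, x$drift, x$residual,
              if (isTRUE(x$coarse_only)) " (coarse only)" else ""))
  invisible(x)
}

dominant_freq <- function(x, fs) {
  n <- length(x)
  X <- Mod(stats::fft(x))[seq_len(floor(n / 2))]
  X[1L] <- 0
  (which.max(X) - 1L) * fs / n
}

#' Merge two aligned streams into one synchronized recording
#'
#' Resamples stream b onto stream a's clock using the piecewise-linear lag
#' function estimated between trigger pairs (extrapolated linearly outside),
#' then keeps only the overlapping time span.
#'
#' @param a,b `seizcoh_recording`s.
#' @param alignment result of [align_streams()].
#' @return a `seizcoh_recording` with all channels of `a` followed by those
#'   of `b` (suffixed `_b` on label collisions).
#' @export
merge_streams <- function(a, b, alignment) {
  stopifnot(inherits(alignment, "seizcoh_alignment"))
  fs <- a$fs
  n <- ncol(a$data)
  t_a <- (seq_len(n) - 1L) / fs
  pt <- alignment$per_trigger
  lag_at <- if (nrow(pt) >= 2L) {
    fit <- stats::lm(lag ~ time, data = pt)
    function(t) {
      l <- stats::approx(pt$time, pt$lag, xout = t, rule = 1)$y
      miss <- is.na(l)
      if (any(miss)) l[miss] <- stats::predict(fit, data.frame(time = t[miss]))
      l
    }
  } else function(t) rep(alignment$fine_lag, length(t))
  ## b-sample position (1-based) carrying the content of a's sample at t
  pos_b <- seq_len(n) + lag_at(t_a)
  ok <- pos_b >= 1 & pos_b <= ncol(b$data)
  if (!any(ok)) stop("streams do not overlap after alignment")
  idx <- which(ok)
  ## cubic splines for continuous channels; linear for the rectangular
  ## trigger pulses (spline overshoot at the pulse edges would shift the
  ## threshold crossings)
  bd <- matrix(0, nrow(b$data), length(idx))
  for (r in seq_len(nrow(b$data))) {
    row <- b$data[r, ]
    bd[r, ] <- if (b$channel_types[r] == "trigger")
      stats::approx(seq_along(row), row, xout = pos_b[idx], rule = 2)$y
    else stats::spline(seq_along(row), row, xout = pos_b[idx], method = "fmm")$y
  }
  labs_b <- b$labels
  clash <- labs_b %in% a$labels
  labs_b[clash] <- paste0(labs_b[clash], "_b")
  new_recording(rbind(a$data[, idx, drop = FALSE], bd),
                c(a$labels, labs_b), fs,
                c(a$channel_types, b$channel_types),
                start_offset = a$start_offset + (idx[1L] - 1L) / fs)
}
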