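## Wavelet coherence, surrogate-calibrated significance, and the SNA
## statistic.
##
## Coherence between two Morlet transforms X, Y:
##   C = |S(X Y*)|^2 / ( S(|X|^2) S(|Y|^2) )
## where S is a rectangular smoothing kernel spanning 20 sigma(f) seconds in
## time (10 wavelet widths, width = 2 sigma) per frequency row and 10 voice
## rows in frequency, truncated at the array boundaries. A time-frequency
## point is an edge point when its time-smoothing window overruns the
## record; edge points are excluded from all counts, so the edge band is
## wider at lower frequencies.
##
## Significance: per-frequency thresholds are the (1 - alpha) quantile of
## the pooled non-edge coherence values over n independent two-channel white
## (or 1/f) noise realizations of the same length, rate and parameters. The
## significant normalized area (SNA) of a plane is the fraction of non-edge
## points exceeding the threshold at their frequency. Outlier planes across
## pairs are detected on the Ns distribution via m + k (Q0.75 - Q0.25).

time_smooth_width <- function(freqs, xi, fs) {
  w <- round(20 * xi / (2 * pi * freqs) * fs)
  w <- pmax(w, 1L)
  w + (w %% 2L == 0L)                      # force odd so the window is centered
}

#' Morlet wavelet coherence between two time-frequency maps
#'
#' @param tfx,tfy `seizcoh_tfmap`s on identical frequency/time grids.
#' @param freq_window frequency smoothing extent in voice rows (default 10).
#' @param time_widths optional time smoothing widths (samples per frequency);
#'   defaults to 20 sigma(f) seconds.
#' @return object of class `seizcoh_cohmap`: freqs, times, coherence in
#'   [0,1], edge_mask (TRUE = excluded edge point), fs, params.
#' @export
wavelet_coherence <- function(tfx, tfy, freq_window = 10L, time_widths = NULL) {
  stopifnot(inherits(tfx, "seizcoh_tfmap"), inherits(tfy, "seizcoh_tfmap"))
  if (!isTRUE(all.equal(tfx$freqs, tfy$freqs)) ||
      length(tfx$times) != length(tfy$times) ||
      !isTRUE(all.equal(tfx$times, tfy$times)))
    stop("time-frequency grids do not match")
  X <- tfx$coefficients
  Y <- tfy$coefficients
  nf <- nrow(X); nt <- ncol(X)
  if (is.null(time_widths))
    time_widths <- time_smooth_width(tfx$freqs, tfx$params$xi, tfx$fs)
  sxy <- X * Conj(Y)
  sxx <- Re(X)^2 + Im(X)^2
  syy <- Re(Y)^2 + Im(Y)^2
  sm_xy <- matrix(0i, nf, nt)
  sm_xx <- matrix(0, nf, nt); sm_yy <- matrix(0, nf, nt)
  edge <- matrix(FALSE, nf, nt)
  ii <- seq_len(nt)
  for (i in seq_len(nf)) {
    w <- time_widths[i]
    half_lo <- (w - 1L) %/% 2L
    half_hi <- w - 1L - half_lo
    lo <- pmax(ii - half_lo, 1L)
    hi <- pmin(ii + half_hi, nt)
    den <- hi - lo + 1L
    run <- function(v) {
      cs <- cumsum(c(v[1L] * 0, v))
      (cs[hi + 1L] - cs[lo]) / den
    }
    sm_xy[i, ] <- run(sxy[i, ])
    sm_xx[i, ] <- run(sxx[i, ])
    sm_yy[i, ] <- run(syy[i, ])
    if (half_lo > 0L || half_hi > 0L) {
      edge[i, seq_len(min(half_lo, nt))] <- TRUE
      edge[i, seq.int(max(nt - half_hi + 1L, 1L), nt)] <- TRUE
    }
  }
  ## frequency smoothing: 10 voice rows, centered (offsets -4..+5), truncated
  lo_off <- -(freq_window %/% 2L - 1L) - (freq_window %% 2L)
  hi_off <- freq_window %/% 2L
  sm_xy <- row_window_mean(sm_xy, lo_off, hi_off)
  sm <- row_window_mean(cbind(sm_xx, sm_yy), lo_off, hi_off)
  sm_xx <- sm[, ii, drop = FALSE]
  sm_yy <- sm[, nt + ii, drop = FALSE]
  denom <- sm_xx * sm_yy
  coh <- (Re(sm_xy)^2 + Im(sm_xy)^2) / pmax(denom, .Machine$double.xmin)
  coh[denom <= 0] <- 0
  coh <- pmin(pmax(coh, 0), 1)
  structure(list(freqs = tfx$freqs, times = tfx$times, coherence = coh,
                 edge_mask = edge, fs = tfx$fs, params = tfx$params),
            class = "seizcoh_cohmap")
}

#' Coherence between two signals (convenience wrapper)
#' @param x,y numeric signals of equal length.
#' @param fs sampling rate in Hz.
#' @param params a `seizcoh_wparams`.
#' @export
signal_coherence <- function(x, y, fs, params = wavelet_params()) {
  wavelet_coherence(morlet_tf(x, fs, params), morlet_tf(y, fs, params))
}

#' Calibrate per-frequency significance thresholds from surrogate noise
#'
#' Generates `n` independent two-channel noise realizations of the analysis
#' length, computes their wavelet coherence, and takes per frequency the
#' (1 - alpha) quantile of the pooled non-edge values (linear interpolation
#' of order statistics). Non-edge points are pooled at a fixed stride along
#' time (they are strongly autocorrelated after smoothing; the stride only
#' bounds memory).
#'
#' @param params a `seizcoh_wparams`.
#' @param fs sampling rate in Hz.
#' @param duration analysis epoch length in s (must match the epochs the
#'   thresholds will be applied to).
#' @param alpha significance level (default 0.05).
#' @param n number of surrogate realizations (default 200).
#' @param seed RNG seed.
#' @param noise `"white"` (default) or `"pink"` (1/f) surrogates.
#' @param stride time-pooling stride in samples.
#' @return object of class `seizcoh_threshold`: freqs, threshold, alpha, n,
#'   seed, noise.
#' @export
calibrate_threshold <- function(params, fs, duration, alpha = 0.05, n = 200L,
                                seed = 1, noise = c("white", "pink"),
                                stride = 4L) {
  noise <- match.arg(noise)
  if (n < 50L) warning("fewer than 50 surrogate realizations: unstable quantile")
  if (alpha >= 1) {
    freqs <- wavelet_freqs(params)
    return(structure(list(freqs = freqs, threshold = rep(0, length(freqs)),
                          alpha = alpha, n = n, seed = seed, noise = noise),
                     class = "seizcoh_threshold"))
  }
  ns <- round(duration * fs)
  freqs <- wavelet_freqs(params)
  pooled <- vector("list", length(freqs))
  for (i in seq_along(freqs)) pooled[[i]] <- vector("list", n)
  with_seed(seed, {
    for (r in seq_len(n)) {
      x <- stats::rnorm(ns); y <- stats::rnorm(ns)
      if (noise == "pink") {
        x <- oneoverf_noise_from(x, fs, 1)
        y <- oneoverf_noise_from(y, fs, 1)
      }
      cm <- signal_coherence(x, y, fs, params)
      for (i in seq_along(freqs)) {
        keep <- which(!cm$edge_mask[i, ])
        keep <- keep[seq.int(1L, length(keep), by = stride)]
        pooled[[i]][[r]] <- cm$coherence[i, keep]
      }
    }
  })
  thr <- vapply(pooled, function(v)
    stats::quantile(unlist(v), 1 - alpha, names = FALSE, type = 7), 0)
  structure(list(freqs = freqs, threshold = thr, alpha = alpha, n = n,
                 seed = seed, noise = noise),
            class = "seizcoh_threshold")
}

#' Phase-scrambled surrogate of a signal
#'
#' Randomizes the Fourier phases while keeping the amplitude spectrum: the
#' surrogate has the same power spectrum and autocorrelation as the input
#' but no cross-signal phase relationships. Feeding pairs of scrambled
#' signals through [signal_coherence()] builds a data-driven null for a
#' specific signal pair, a slightly more sensitive (and much costlier)
#' alternative to the default white-noise calibration.
#'
#' @param x numeric signal.
#' @param seed RNG seed.
#' @return numeric vector of the same length.
#' @export
phase_scramble <- function(x, seed = 1) {
  n <- length(x)
  X <- stats::fft(x)
  half <- (n - 1L) %/% 2L
  ph <- with_seed(seed, stats::runif(half, 0, 2 * pi))
  rot <- rep(1 + 0i, n)
  rot[2L:(half + 1L)] <- exp(1i * ph)
  rot[n:(n - half + 1L)] <- Conj(rot[2L:(half + 1L)])
  Re(stats::fft(X * rot, inverse = TRUE)) / n
}

## shape an existing white-noise vector to a 1/f^(exponent/2) spectrum
oneoverf_noise_from <- function(z, fs, exponent) {
  n <- length(z)
  Z <- stats::fft(z)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  H <- ifelse(abs(f) < 0.5, 0, abs(f)^(-exponent / 2))
  x <- Re(stats::fft(Z * H, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Count significant points and the significant normalized area of a plane
#'
#' @param coh a `seizcoh_cohmap`.
#' @param threshold a `seizcoh_threshold` on the same frequency grid.
#' @param component,pair optional identifiers carried into the result.
#' @return list: component, pair, Ns (significant non-edge points), total
#'   (non-edge points), sna = Ns/total.
#' @export
summarize_pair <- function(coh, threshold, component = NA, pair = NA) {
  stopifnot(inherits(coh, "seizcoh_cohmap"),
            inherits(threshold, "seizcoh_threshold"))
  if (!isTRUE(all.equal(coh$freqs, threshold$freqs)))
    stop("threshold frequency grid does not match the coherence map")
  sig <- coh$coherence > threshold$threshold   # thresholds recycle per column
  ok <- !coh$edge_mask
  ns <- sum(sig & ok)
  total <- sum(ok)
  list(component = component, pair = pair, Ns = ns, total = total,
       sna = ns / total)
}

#' Mean exceedance rate of fresh noise against a calibrated threshold
#'
#' Monte-Carlo check of the type-I calibration: generates `n_validate` fresh
#' independent noise pairs and returns the per-frequency mean fraction of
#' non-edge points declared significant (should match alpha).
#'
#' @param threshold a `seizcoh_threshold`.
#' @param params,fs,duration analysis settings (must match the calibration).
#' @param n_validate number of fresh pairs (default 100).
#' @param seed RNG seed (independent of the calibration seed).
#' @return list: per_freq (mean exceedance per frequency), overall (mean
#'   across frequencies), n_validate.
#' @export
validate_threshold <- function(threshold, params, fs, duration,
                               n_validate = 100L, seed = 12345) {
  ns <- round(duration * fs)
  nf <- length(threshold$freqs)
  acc <- matrix(0, nf, n_validate)
  with_seed(seed, {
    for (r in seq_len(n_validate)) {
      cm <- signal_coherence(stats::rnorm(ns), stats::rnorm(ns), fs, params)
      sig <- cm$coherence > threshold$threshold
      ok <- !cm$edge_mask
      acc[, r] <- rowSums(sig & ok) / rowSums(ok)
    }
  })
  per_freq <- rowMeans(acc)
  list(per_freq = per_freq, overall = mean(per_freq), n_validate = n_validate)
}

#' Detect outlier coherence planes across signal pairs
#'
#' The threshold on the Ns distribution is m + k (Q0.75 - Q0.25) with m the
#' median and quartiles by linear interpolation of order statistics; pairs
#' strictly above it are selected.
#'
#' @param summaries list of [summarize_pair()] results, or a numeric vector
#'   of Ns counts (>= 4).
#' @param k multiplier (default 5).
#' @return list: rule (m, q25, q75, k, threshold), selected (indices),
#'   selected_pairs (labels when available).
#' @export
detect_outlier_pairs <- function(summaries, k = 5) {
  ns <- if (is.numeric(summaries)) summaries
  else vapply(summaries, function(s) as.numeric(s$Ns), 0)
  if (length(ns) < 4L) stop("need at least 4 pairs for the outlier rule")
  m <- stats::median(ns)
  q <- stats::quantile(ns, c(0.25, 0.75), names = FALSE, type = 7)
  thr <- m + k * (q[2] - q[1])
  sel <- which(ns > thr)
  labels <- if (!is.numeric(summaries))
    vapply(summaries, function(s) as.character(s$pair), "")[sel]
  else NULL
  list(rule = list(m = m, q25 = q[1], q75 = q[2], k = k, threshold = thr),
       selected = sel, selected_pairs = labels)
}

#' Write a per-pair coherence summary table to TSV
#' @param summaries list of [summarize_pair()] results.
#' @param selection optional [detect_outlier_pairs()] result.
#' @param path output TSV path.
#' @export
write_pair_table <- function(summaries, path, selection = NULL) {
  df <- if (is.data.frame(summaries)) summaries
  else do.call(rbind, lapply(summaries, function(s)
    data.frame(component = s$component, pair = s$pair, Ns = s$Ns,
               total = s$total, SNA = s$sna)))
  df$selected <- FALSE
  if (!is.null(selection)) df$selected[selection$selected] <- TRUE
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write calibrated thresholds to TSV
#' @param threshold a `seizcoh_threshold`.
#' @param path output TSV path (columns freq_hz, threshold).
#' @export
write_threshold_tsv <- function(threshold, path) {
  utils::write.table(
    data.frame(freq_hz = threshold$freqs, threshold = threshold$threshold),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
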