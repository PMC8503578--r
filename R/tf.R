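## Morlet time-frequency transform.
##
## Analytic Morlet wavelet with oscillation parameter xi: temporal SD
## sigma(f) = xi / (2 pi f), so the wavelet "width" is 2 sigma = xi/(pi f).
## Frequencies are log-spaced at 2^(1/voices) from fmin to fmax. The
## transform is the cross-correlation of the signal with the sampled
## analytic wavelet (truncated at 4 sigma), computed by FFT; it equals a
## direct time-domain convolution up to rounding, and is normalized so a
## unit-amplitude sinusoid at an analysis frequency yields |coefficient| = 1.

#' Morlet wavelet parameters
#'
#' @param xi oscillation parameter (default 7; >= 5 for admissibility in
#'   practice).
#' @param fmin,fmax analysis band in Hz (defaults 5 and 100).
#' @param voices_per_octave frequency resolution (default 10).
#' @export
wavelet_params <- function(xi = 7, fmin = 5, fmax = 100, voices_per_octave = 10) {
  if (xi < 5) stop("xi must be >= 5")
  if (fmin <= 0 || fmax <= fmin) stop("need 0 < fmin < fmax")
  structure(list(xi = xi, fmin = fmin, fmax = fmax,
                 voices_per_octave = voices_per_octave),
            class = "seizcoh_wparams")
}

#' Log-spaced analysis frequencies of a parameter set
#' @param params a `seizcoh_wparams`.
#' @return vector of floor(voices * log2(fmax/fmin)) + 1 frequencies in Hz.
#' @export
wavelet_freqs <- function(params) {
  v <- params$voices_per_octave
  n <- floor(v * log2(params$fmax / params$fmin)) + 1L
  params$fmin * 2^((seq_len(n) - 1L) / v)
}

#' Morlet time-frequency transform
#'
#' @param x numeric signal.
#' @param fs sampling rate in Hz.
#' @param params a `seizcoh_wparams`.
#' @return object of class `seizcoh_tfmap`: freqs (Hz), times (s),
#'   coefficients (complex, freqs x times), fs, params.
#' @export
morlet_tf <- function(x, fs, params = wavelet_params()) {
  stopifnot(inherits(params, "seizcoh_wparams"))
  if (params$fmax > fs / 2) stop("fmax must not exceed the Nyquist frequency")
  n <- length(x)
  freqs <- wavelet_freqs(params)
  sig_max <- params$xi / (2 * pi * params$fmin)
  support <- ceiling(4 * sig_max * fs)
  if (n <= 2L * support + 1L)
    stop("signal shorter than the wavelet support at fmin")
  nfft <- stats::nextn(n + 2L * support + 1L, c(2L, 3L))
  X <- stats::fft(c(x - mean(x), numeric(nfft - n)))
  HW <- morlet_kernel_ffts(freqs, fs, params$xi, nfft)
  coef <- matrix(0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    ## cross-correlation of the signal with the analytic wavelet
    y <- stats::fft(X * HW[[i]], inverse = TRUE) / nfft
    coef[i, ] <- y[seq_len(n)]
  }
  structure(list(freqs = freqs, times = (seq_len(n) - 1L) / fs,
                 coefficients = coef, fs = fs, params = params),
            class = "seizcoh_tfmap")
}

## sampled analytic Morlet at frequency f0, truncated at +-4 sigma, scaled
## so a unit-amplitude sinusoid at f0 yields |coefficient| = 1
morlet_kernel <- function(f0, fs, xi) {
  sig_t <- xi / (2 * pi * f0)
  half <- ceiling(4 * sig_t * fs)
  tt <- (-half:half) / fs
  env <- exp(-tt^2 / (2 * sig_t^2))
  exp(2i * pi * f0 * tt) * env * (2 / sum(env))
}

## conjugated kernel FFTs, cached per (nfft, fs, xi, frequency grid): the
## same kernels are reused across every signal of a given epoch length
.kernel_cache <- new.env(parent = emptyenv())

morlet_kernel_ffts <- function(freqs, fs, xi, nfft) {
  key <- paste(nfft, fs, xi, length(freqs), freqs[1L], freqs[length(freqs)],
               sep = "|")
  hit <- .kernel_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- lapply(freqs, function(f0) {
    h <- morlet_kernel(f0, fs, xi)
    half <- (length(h) - 1L) %/% 2L
    ## wavelet wrapped so its center sits at index 1 (circular layout)
    hw <- complex(length.out = nfft)
    hw[seq_len(half + 1L)] <- h[(half + 1L):length(h)]
    hw[(nfft - half + 1L):nfft] <- h[seq_len(half)]
    Conj(stats::fft(hw))
  })
  if (length(ls(.kernel_cache)) > 8L)      # bound the cache
    rm(list = ls(.kernel_cache), envir = .kernel_cache)
  .kernel_cache[[key]] <- out
  out
}

#' Z-score normalization of a time-frequency map (display only)
#'
#' Per frequency row, the baseline mean and SD are computed from the 20%
#' lowest-amplitude points; the whole row is then Z-scored against them.
#' Used to make weak high-frequency activity visible in plots; never feeds
#' the coherence analysis.
#'
#' @param tf a `seizcoh_tfmap`.
#' @param baseline_quantile fraction of lowest-amplitude points forming the
#'   baseline (default 0.2).
#' @return real matrix (freqs x times) of Z values.
#' @export
zscore_tf_display <- function(tf, baseline_quantile = 0.2) {
  stopifnot(inherits(tf, "seizcoh_tfmap"))
  a <- Mod(tf$coefficients)
  out <- a
  floored <- FALSE
  for (i in seq_len(nrow(a))) {
    row <- a[i, ]
    cut <- stats::quantile(row, baseline_quantile, type = 7)
    base <- row[row <= cut]
    m <- mean(base)
    s <- stats::sd(base)
    if (!is.finite(s) || s < .Machine$double.eps) {
      floored <- TRUE
      s <- .Machine$double.eps
    }
    out[i, ] <- (row - m) / s
  }
  if (floored)
    warning("zero-variance baseline in at least one frequency row; SD floored")
  out
}
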