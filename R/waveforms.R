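## Ictal source waveforms.
##
## Each pattern returns a unit-scale moment time course that is (except for
## preictal spikes) silent before the onset marker; the dipole amplitude in
## nA.m is applied multiplicatively. Patterns follow the seizure-onset
## morphologies seen in SEEG: low-voltage fast activity (LVFA, narrowband
## 30-80 Hz), bursts of polyspikes followed by repetitive discharges, a
## ~10 Hz repetitive spike train, and sporadic preictal spikes.

spike_kernel <- function(fs, width = 0.015) {
  tt <- seq(-4 * width, 4 * width, by = 1 / fs)
  (1 - (tt / width)^2) * exp(-tt^2 / (2 * width^2))   # mexican hat, peak 1 at 0
}

place_spikes <- function(n, fs, times, amp, kernel) {
  x <- numeric(n)
  idx <- round(times * fs) + 1L
  keep <- idx >= 1L & idx <= n
  x[idx[keep]] <- amp[keep]
  k <- length(kernel)
  y <- stats::convolve(c(x, numeric(k)), rev(kernel), type = "open")
  off <- (k - 1L) %/% 2L
  y[(off + 1L):(off + n)]
}

## gaussian-band noise centered at f0 (Hz) with bandwidth bw (Hz, SD)
narrowband_noise <- function(n, fs, f0, bw) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  H <- exp(-(abs(f) - f0)^2 / (2 * bw^2))
  Re(stats::fft(Z * H, inverse = TRUE)) / n
}

#' Synthesize an ictal source waveform
#'
#' @param pattern one of `"lvfa"`, `"polyspike_burst"`,
#'   `"repetitive_discharge"`, `"preictal_spikes"`.
#' @param characteristic_frequency Hz (LVFA center frequency, discharge or
#'   spike rate).
#' @param onset_time seizure onset in s; the waveform is ~0 before it except
#'   for the preictal_spikes pattern.
#' @param duration total length in s.
#' @param fs sampling rate in Hz.
#' @param amplitude output scale; post-onset RMS equals `amplitude`.
#' @param seed RNG seed; output is deterministic given the seed.
#' @return numeric vector of `round(duration * fs)` samples.
#' @export
synth_ictal_waveform <- function(pattern, characteristic_frequency, onset_time,
                                 duration, fs, amplitude = 1, seed = 1) {
  pattern <- match.arg(pattern, c("lvfa", "polyspike_burst",
                                  "repetitive_discharge", "preictal_spikes"))
  if (onset_time >= duration) stop("onset_time must be before duration")
  f0 <- characteristic_frequency
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  post <- t >= onset_time
  if (amplitude == 0) return(numeric(n))

  w <- with_seed(seed, switch(
    pattern,
    lvfa = {
      x <- narrowband_noise(n, fs, f0, bw = max(1.5, 0.08 * f0))
      ## low-voltage onset building up over the discharge: linear envelope
      env <- numeric(n)
      env[post] <- (t[post] - onset_time) / max(duration - onset_time, 1)
      x * env
    },
    polyspike_burst = {
      k <- spike_kernel(fs)
      seg <- duration - onset_time
      burst_starts <- seq(onset_time, onset_time + 0.55 * seg, by = 1)
      sp_t <- unlist(lapply(burst_starts, function(b) b + (0:4) / f0))
      rep_t <- seq(onset_time + 0.6 * seg, duration - 1 / fs, by = 0.1)
      times <- c(sp_t, rep_t)
      amp <- 1 + 0.2 * stats::rnorm(length(times))
      place_spikes(n, fs, times, amp, k)
    },
    repetitive_discharge = {
      k <- spike_kernel(fs)
      times <- seq(onset_time, duration - 1 / fs, by = 1 / f0)
      amp <- 1 + 0.1 * stats::rnorm(length(times))
      place_spikes(n, fs, times, amp, k)
    },
    preictal_spikes = {
      k <- spike_kernel(fs)
      n_sp <- max(1L, round(f0 * duration))
      times <- sort(stats::runif(n_sp, 0, duration - 1 / fs))
      amp <- 1 + 0.3 * stats::rnorm(n_sp)
      place_spikes(n, fs, times, amp, k)
    }))

  if (pattern != "preictal_spikes") w[!post] <- 0
  ref <- if (pattern == "preictal_spikes") w else w[post]
  rms <- sqrt(mean(ref^2))
  if (rms > 0) w <- w / rms
  w * amplitude
}
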