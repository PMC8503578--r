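## Simultaneous scalp/SEEG session generator.
##
## Two independently clocked "amplifiers" sample the same underlying (master)
## activity: a dipolar ictal generator plus spatially distributed 1/f
## background sources, sensor noise, and (scalp only) EMG. Both streams carry
## a digital trigger channel and a 50 Hz reference sine for alignment. The
## SEEG stream's content is delayed by `imposed_lag` samples and its clock
## runs at fs*(1 + drift_ppm*1e-6); master signals are generated on an
## extended grid so the delayed stream never reads outside it.

#' Simulation configuration
#'
#' @param fs sampling rate in Hz (both streams nominally; default 512).
#' @param duration recording length in s (>= 30; default 64, leaving a tail
#'   margin after the last 10 s trigger so all pulses fall inside both
#'   streams under realistic lags).
#' @param n_background_sources number of 1/f background dipoles (default
#'   120; the cortical background is high-dimensional).
#' @param background_exponent spectral slope of the background power
#'   spectrum, P(f) ~ 1/f^exponent (default 1).
#' @param background_gamma amplitude of the broadband floor of the
#'   background spectra relative to the power law at 1 Hz (default 0.1;
#'   real EEG spectra flatten in the gamma band).
#' @param background_amplitude background dipole RMS moment in nA.m.
#' @param emg_level EMG RMS in microvolts added to temporal/frontal scalp
#'   channels (default 5; 0 disables).
#' @param sensor_noise white amplifier noise RMS in microvolts (default 5).
#' @param clock_drift_ppm SEEG clock rate error in parts per million.
#' @param trigger_interval s between digital trigger pulses (default 10).
#' @param trigger_width trigger pulse width in s.
#' @param ref_sine_freq reference sine frequency in Hz (default 50).
#' @param ref_sine_amp reference sine amplitude in microvolts.
#' @param imposed_lag content delay of the SEEG stream in samples (may be
#'   fractional).
#' @param seed integer seed; a fixed seed gives bit-identical sessions.
#' @return object of class `seizcoh_simconfig`.
#' @export
simulation_config <- function(fs = 512, duration = 64,
                              n_background_sources = 120,
                              background_exponent = 1,
                              background_gamma = 0.1,
                              background_amplitude = 10.6,
                              emg_level = 5, sensor_noise = 5,
                              clock_drift_ppm = 0,
                              trigger_interval = 10, trigger_width = 0.05,
                              ref_sine_freq = 50, ref_sine_amp = 50,
                              imposed_lag = 0, seed = 1) {
  if (duration < 30) stop("duration must be >= 30 s")
  if (fs <= 0) stop("fs must be > 0")
  structure(list(fs = fs, duration = duration,
                 n_background_sources = n_background_sources,
                 background_exponent = background_exponent,
                 background_gamma = background_gamma,
                 background_amplitude = background_amplitude,
                 emg_level = emg_level, sensor_noise = sensor_noise,
                 clock_drift_ppm = clock_drift_ppm,
                 trigger_interval = trigger_interval,
                 trigger_width = trigger_width,
                 ref_sine_freq = ref_sine_freq, ref_sine_amp = ref_sine_amp,
                 imposed_lag = imposed_lag, seed = as.integer(seed)),
            class = "seizcoh_simconfig")
}

## background-activity noise, unit RMS: 1/f^exponent power law plus a
## broadband floor (real EEG spectra flatten in the gamma band rather than
## falling to zero; without the floor the high-frequency subspace of the
## scalp mixture would be unrealistically low-dimensional), amplitude
## modulated by a slow envelope (background rhythms wax and wane; the
## resulting mild super-Gaussianity is what lets ICA resolve the strong
## background generators into dipolar components, as it does on real EEG)
oneoverf_noise <- function(n, fs, exponent, floor_frac = 0.1, mod_depth = 0.5) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  H <- ifelse(abs(f) < 0.5, 0,
              sqrt(abs(f)^(-exponent) + floor_frac^2))
  x <- Re(stats::fft(Z * H, inverse = TRUE)) / n
  if (mod_depth > 0) {
    e <- stats::rnorm(n)
    E <- stats::fft(e)
    He <- exp(-(abs(f) / 0.3)^2)            # ~0.3 Hz envelope fluctuations
    env <- Re(stats::fft(E * He, inverse = TRUE)) / n
    env <- env / stats::sd(env)
    x <- x * (1 + mod_depth * env)
  }
  x / sqrt(mean(x^2))
}

trigger_wave <- function(t, interval, width, duration) {
  k_max <- floor((duration - 1e-9) / interval)
  on <- rep(FALSE, length(t))
  for (k in 0:k_max) on <- on | (t >= k * interval & t < k * interval + width)
  as.numeric(on)
}

#' Simulate a simultaneous scalp/SEEG session
#'
#' @param config a `seizcoh_simconfig`.
#' @param sensors a `seizcoh_sensors`.
#' @param head a `seizcoh_head`.
#' @param sources a `seizcoh_source` or list of them; the first is taken as
#'   the ictal generator for the ground truth.
#' @param n_soz_contacts how many nearest contacts form the ground-truth SOZ.
#' @return list with elements `scalp` and `seeg` (recordings) and `truth`
#'   (ground truth: source, true scalp mixing column, SOZ contact labels and
#'   bipolar pair, imposed lag and drift).
#' @export
simulate_session <- function(config, sensors, head, sources,
                             n_soz_contacts = 2L) {
  stopifnot(inherits(config, "seizcoh_simconfig"),
            inherits(sensors, "seizcoh_sensors"),
            inherits(head, "seizcoh_head"))
  if (inherits(sources, "seizcoh_source")) sources <- list(sources)
  if (!length(sources)) stop("at least one ictal source is required")
  r <- sqrt(rowSums(sweep(as.matrix(sensors$scalp[, c("x", "y", "z")]),
                          2L, head$center)^2))
  if (any(abs(r - head$radius) > 1e-6))
    stop("incompatible sensor/head geometry: scalp electrodes off the sphere")
  fs <- config$fs
  fmax_src <- max(vapply(sources, `[[`, 0, "characteristic_frequency"))
  if (fs <= 2 * fmax_src)
    stop("fs must exceed twice the maximum source frequency")
  dur <- config$duration
  N <- round(dur * fs)
  delta <- config$clock_drift_ppm * 1e-6
  lag <- config$imposed_lag

  pad0 <- ceiling(max(0, lag) / (1 + min(delta, 0))) + 8L
  pad1 <- ceiling(max(0, -lag)) + ceiling(abs(delta) * N) + 8L
  m_idx <- seq(-pad0, N - 1L + pad1)
  M <- length(m_idx)
  tm <- m_idx / fs                       # master time of each master sample
  t_a <- (seq_len(N) - 1L) / fs          # scalp stream samples master time
  t_b <- ((seq_len(N) - 1L) - lag) / (fs * (1 + delta))  # seeg stream

  ne <- nrow(sensors$scalp)
  nc <- nrow(sensors$seeg)
  scalp <- matrix(0, ne, N)
  seeg <- matrix(0, nc, N)

  add_source <- function(pos, mom, wave) {
    add_gains(forward_scalp(pos, sensors, head, moment = mom),
              forward_seeg(pos, sensors, head$conductivity, moment = mom),
              wave)
  }

  add_gains <- function(ga, gs, wave) {
    wa <- wave[pad0 + seq_len(N)]
    wb <- stats::spline(tm, wave, xout = t_b, method = "fmm")$y
    scalp <<- scalp + outer(as.numeric(ga), wa)
    seeg <<- seeg + outer(as.numeric(gs), wb)
  }

  ## ictal source(s), possibly extended patches sharing one waveform
  for (i in seq_along(sources)) {
    s <- sources[[i]]
    wave <- synth_ictal_waveform(s$pattern, s$characteristic_frequency,
                                 s$onset_time + pad0 / fs, M / fs, fs,
                                 amplitude = 1, seed = config$seed + 1000L + i)
    pd <- patch_dipoles(s, head)
    ga <- 0; gs <- 0
    for (j in seq_len(nrow(pd$positions))) {
      mom <- pd$orientations[j, ] * s$amplitude * pd$weights[j]
      ga <- ga + forward_scalp(pd$positions[j, ], sensors, head, moment = mom)
      gs <- gs + forward_seeg(pd$positions[j, ], sensors, head$conductivity,
                              moment = mom)
    }
    add_gains(ga, gs, wave)
  }

  ## distributed 1/f background sources
  nb <- config$n_background_sources
  if (nb > 0) {
    bg <- with_seed(config$seed + 2000L, {
      pos <- matrix(NA_real_, nb, 3L)
      k <- 0L
      while (k < nb) {
        p <- stats::runif(3, -1, 1)
        if (vnorm(p) <= 0.9) { k <- k + 1L; pos[k, ] <- p * head$radius }
      }
      ori <- matrix(stats::rnorm(3L * nb), nb, 3L)
      ori <- ori / sqrt(rowSums(ori^2))
      list(pos = sweep(pos, 2L, head$center, `+`), ori = ori)
    })
    for (i in seq_len(nb)) {
      wave <- with_seed(config$seed + 3000L + i,
                        oneoverf_noise(M, fs, config$background_exponent,
                                       config$background_gamma)) *
        config$background_amplitude
      add_source(bg$pos[i, ], bg$ori[i, ], wave)
    }
  }

  ## amplifier noise (independent per stream) and EMG (scalp only)
  if (config$sensor_noise > 0) {
    scalp <- scalp + with_seed(config$seed + 4001L,
                               matrix(stats::rnorm(ne * N), ne, N)) * config$sensor_noise
    seeg <- seeg + with_seed(config$seed + 4002L,
                             matrix(stats::rnorm(nc * N), nc, N)) * config$sensor_noise
  }
  if (config$emg_level > 0) {
    emg_ch <- which(sensors$scalp$label %in% EMG_PRONE)
    if (length(emg_ch)) {
      emg <- with_seed(config$seed + 5000L, {
        t(vapply(emg_ch, function(i) narrowband_noise(N, fs, 60, 20), numeric(N)))
      })
      emg <- emg / sqrt(rowMeans(emg^2)) * config$emg_level
      scalp[emg_ch, ] <- scalp[emg_ch, ] + emg
    }
  }

  ## synchronization channels, analytic in master time
  tw <- config$trigger_width
  ti <- config$trigger_interval
  fref <- config$ref_sine_freq
  trig_a <- trigger_wave(t_a, ti, tw, dur)
  trig_b <- trigger_wave(t_b, ti, tw, dur)
  ref_a <- config$ref_sine_amp * sin(2 * pi * fref * t_a)
  ref_b <- config$ref_sine_amp * sin(2 * pi * fref * t_b)

  rec_a <- new_recording(rbind(scalp, trig_a, ref_a),
                         c(sensors$scalp$label, "TRIG", "REF50"), fs,
                         c(rep("scalp", ne), "trigger", "refsine"))
  rec_b <- new_recording(rbind(seeg, trig_b, ref_b),
                         c(sensors$seeg$label, "TRIG", "REF50"), fs,
                         c(rep("seeg", nc), "trigger", "refsine"))

  src <- sources[[1L]]
  dists <- sqrt(rowSums(sweep(as.matrix(sensors$seeg[, c("x", "y", "z")]),
                              2L, src$position)^2))
  soz_labels <- sensors$seeg$label[order(dists)[seq_len(min(n_soz_contacts, nc))]]
  mids <- bipolar_pairs(sensors$seeg)
  pd <- sqrt(rowSums(sweep(as.matrix(mids[, c("x", "y", "z")]), 2L, src$position)^2))
  truth <- structure(
    list(source = src, mixing_column = source_topography(src, sensors, head),
         soz_labels = soz_labels, soz_pair = mids$label[which.min(pd)],
         imposed_lag = lag, clock_drift_ppm = config$clock_drift_ppm,
         onset_time = src$onset_time),
    class = "seizcoh_truth")
  list(scalp = rec_a, seeg = rec_b, truth = truth)
}

## bipolar pair labels and midpoints for a SEEG coordinate table
bipolar_pairs <- function(seeg) {
  out <- NULL
  for (sh in unique(seeg$shaft)) {
    d <- seeg[seeg$shaft == sh, ]
    d <- d[order(d$index), ]
    if (nrow(d) < 2L) next
    keep <- which(diff(d$index) == 1L)
    if (!length(keep)) next
    out <- rbind(out, data.frame(
      label = paste0(d$label[keep], "-", d$label[keep + 1L]),
      x = (d$x[keep] + d$x[keep + 1L]) / 2,
      y = (d$y[keep] + d$y[keep + 1L]) / 2,
      z = (d$z[keep] + d$z[keep + 1L]) / 2, stringsAsFactors = FALSE))
  }
  out
}

#' Write a simulated session to disk
#'
#' One EDF per stream, a sensor-coordinate TSV and a JSON ground-truth
#' sidecar.
#'
#' @param session result of [simulate_session()].
#' @param dir output directory (created if needed).
#' @param sensors the `seizcoh_sensors` used for the simulation.
#' @param stem file name stem.
#' @return named character vector of the written paths.
#' @export
write_session <- function(session, dir, sensors, stem = "session") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_scalp <- file.path(dir, paste0(stem, "_scalp.edf"))
  p_seeg <- file.path(dir, paste0(stem, "_seeg.edf"))
  p_tsv <- file.path(dir, paste0(stem, "_sensors.tsv"))
  p_json <- file.path(dir, paste0(stem, "_truth.json"))
  write_edf(session$scalp, p_scalp)
  write_edf(session$seeg, p_seeg)
  write_sensors_tsv(sensors, p_tsv)
  tr <- session$truth
  jsonlite::write_json(list(
    source = list(position = tr$source$position,
                  orientation = tr$source$orientation,
                  pattern = tr$source$pattern,
                  characteristic_frequency = tr$source$characteristic_frequency,
                  onset_time = tr$source$onset_time,
                  amplitude = tr$source$amplitude),
    mixing_column = as.list(tr$mixing_column),
    soz_labels = tr$soz_labels, soz_pair = tr$soz_pair,
    imposed_lag = tr$imposed_lag, clock_drift_ppm = tr$clock_drift_ppm),
    p_json, auto_unbox = TRUE, digits = NA)
  c(scalp = p_scalp, seeg = p_seeg, sensors = p_tsv, truth = p_json)
}

#' Demo session: one dipolar ictal generator at a controllable depth
#'
#' Builds the standard synthetic study condition: a 21-electrode 10-20 scalp
#' cap, an 18-contact SEEG shaft running along the source axis plus an
#' 8-contact shaft elsewhere, and a radial LVFA generator at the requested
#' eccentricity.
#'
#' @param eccentricity source depth as a fraction of the head radius.
#' @param seed session seed.
#' @param pattern,characteristic_frequency ictal waveform parameters.
#' @param amplitude ictal dipole moment in nA.m.
#' @param onset_time seizure onset in s.
#' @param fs,duration sampling rate and length (desk-scale defaults).
#' @param ... further arguments to [simulation_config()].
#' @return list(session, sensors, head, config).
#' @export
make_demo_session <- function(eccentricity = 0.85, seed = 1, pattern = "lvfa",
                              characteristic_frequency = 60, amplitude = 65,
                              patch_extent = 30, onset_time = 40, fs = 256,
                              duration = 64, ...) {
  head <- head_model()
  u <- c(1, 1, 0.5); u <- u / vnorm(u)
  ## one shaft along the source axis (covers every probed depth) plus six
  ## exploring other regions, as in a clinical implantation where most
  ## electrodes end up far from the seizure-onset zone. The axial shaft is
  ## placed so the generator projects midway between two adjacent contacts
  ## at every eccentricity: the local source-to-contact geometry is then
  ## constant across depths instead of oscillating with the 3.5 mm grid.
  pitch <- 3.5
  m <- round((eccentricity * head$radius - 38) / pitch - 0.5)
  tip_dist <- eccentricity * head$radius - (m + 0.5) * pitch
  dirs <- list(T = c(-1, 1, 0.2), F = c(0.2, -1, 0.6), P = c(-0.6, -0.5, -1),
               A = c(1, -1, 0.3), B = c(-1, -0.2, 0.8), C = c(0.3, 1, -0.8))
  shafts <- rbind(
    seeg_shaft("V", tip = tip_dist * u, direction = u, n_contacts = 14L),
    do.call(rbind, lapply(names(dirs), function(nm) {
      d <- dirs[[nm]] / vnorm(dirs[[nm]])
      seeg_shaft(nm, tip = 40 * d, direction = d, n_contacts = 8L)
    })))
  sensors <- sensor_array(scalp_sensors_1020(head), shafts, head = head)
  perp <- c(1, -1, 0) / vnorm(c(1, -1, 0))   # off-axis offset, keeps the
  pos <- eccentricity * head$radius * u + 3 * perp  # source off the contacts
  src <- source_spec(pos, u, pattern, characteristic_frequency, onset_time,
                     amplitude, patch_extent = patch_extent)
  config <- simulation_config(fs = fs, duration = duration, seed = seed, ...)
  list(session = simulate_session(config, sensors, head, src),
       sensors = sensors, head = head, config = config)
}
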