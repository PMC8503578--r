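# Shared small fixtures, built in code.

test_head <- function() head_model()

test_sensors <- function(head = test_head()) {
  u <- c(1, 1, 0.5); u <- u / sqrt(sum(u^2))
  v <- c(-1, 1, 0.2); v <- v / sqrt(sum(v^2))
  sensor_array(scalp_sensors_1020(head),
               rbind(seeg_shaft("V", 30 * u, u, 18L),
                     seeg_shaft("T", 45 * v, v, 8L)),
               head = head)
}

# small fast session for IO/alignment tests (fewer background sources)
quick_session <- function(seed = 1, fs = 256, duration = 64, ...,
                          eccentricity = 0.85) {
  make_demo_session(eccentricity = eccentricity, seed = seed, fs = fs,
                    duration = duration, n_background_sources = 5, ...)
}

# a tiny recording for format round trips
toy_recording <- function(nch = 4, n = 1024, fs = 512, seed = 7) {
  with_seed_t(seed, {
    dat <- matrix(stats::rnorm(nch * n, sd = 40), nch, n)
    new_recording(dat, paste0("CH", seq_len(nch)), fs, "scalp")
  })
}

with_seed_t <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
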