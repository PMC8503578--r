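# Alignment recovery is exercised against sessions with known imposed lag
# and clock drift. Sessions here carry few background sources (alignment
# only uses the trigger and reference-sine channels).

align_case <- function(lag, drift, seed = 5) {
  demo <- quick_session(seed = seed, fs = 512, imposed_lag = lag,
                        clock_drift_ppm = drift)
  align_streams(demo$session$scalp, demo$session$seeg)
}

test_that("integer, fractional and zero lags are recovered to 0.05 samples", {
  a <- align_case(1234, 0)
  expect_lt(abs(a$fine_lag - 1234), 0.05)
  expect_equal(a$coarse_lag, 1234L, tolerance = 1)
  b <- align_case(1234.25, 0)
  expect_lt(abs(b$fine_lag - 1234.25), 0.05)
  z <- align_case(0, 0)
  expect_lt(abs(z$fine_lag), 0.05)
  expect_identical(z$coarse_lag, 0L)
})

test_that("lag plus drift are recovered jointly and the fit is tight", {
  a <- align_case(1234.25, 100)
  expect_lt(abs(a$fine_lag - 1234.25), 0.05)
  expect_lt(abs(a$drift - 100), 5)
  expect_lt(a$residual, 1)
  expect_lt(abs(a$fine_lag - a$coarse_lag), 512 / 50 / 2)
})

test_that("alignment is inverse-consistent", {
  demo <- quick_session(seed = 9, fs = 512, imposed_lag = 87.6)
  ab <- align_streams(demo$session$scalp, demo$session$seeg)
  ba <- align_streams(demo$session$seeg, demo$session$scalp)
  expect_lt(abs(ab$fine_lag + ba$fine_lag), 0.1)
})

test_that("merge restores trigger coincidence and sine alignment", {
  demo <- quick_session(seed = 4, fs = 512, imposed_lag = 1234.25,
                        clock_drift_ppm = 100)
  al <- align_streams(demo$session$scalp, demo$session$seeg)
  mg <- merge_streams(demo$session$scalp, demo$session$seeg, al)
  expect_equal(sort(unique(mg$channel_types)),
               c("refsine", "scalp", "seeg", "trigger"))
  onsets <- function(x) which(x > 0.5 & c(FALSE, x[-length(x)] <= 0.5))
  ta <- onsets(mg$data[mg$labels == "TRIG", ])
  tb <- onsets(mg$data[mg$labels == "TRIG_b", ])
  ## match pulses by nearest neighbor (a boundary pulse can be half-visible
  ## in one stream only)
  match_d <- vapply(ta, function(t) min(abs(tb - t)), 0)
  matched <- match_d[match_d < 2560]
  expect_gte(length(matched), 5)
  expect_true(all(matched <= 1))
  ## refsine channels cross-correlate with peak at lag 0
  ra <- mg$data[mg$labels == "REF50", ]
  rb <- mg$data[mg$labels == "REF50_b", ]
  lags <- -5:5
  cc <- vapply(lags, function(L) {
    i <- seq_along(ra); j <- i + L; ok <- j >= 1 & j <= length(rb)
    sum(ra[ok] * rb[j[ok]])
  }, 0)
  expect_identical(lags[which.max(cc)], 0L)
})

test_that("merging identical streams at zero lag doubles the channels", {
  demo <- quick_session(seed = 6)
  a <- demo$session$scalp
  al <- align_streams(a, a)
  expect_lt(abs(al$fine_lag), 1e-9)
  mg <- merge_streams(a, a, al)
  expect_equal(nrow(mg$data), 2L * nrow(a$data))
  half <- seq_len(nrow(a$data))
  expect_lt(max(abs(mg$data[half, ] - mg$data[-half, ])), 1e-6)
})

test_that("alignment degrades gracefully without a reference sine", {
  demo <- quick_session(seed = 8, fs = 512, imposed_lag = 100)
  a <- demo$session$scalp
  b <- demo$session$seeg
  drop_ref <- function(r) r[r$channel_types != "refsine"]
  al <- align_streams(drop_ref(a), drop_ref(b))
  expect_true(al$coarse_only)
  expect_lt(abs(al$fine_lag - 100), 1.5)   # trigger quantization only
})

test_that("fewer than two matching triggers is an error", {
  demo <- quick_session(seed = 8)
  a <- demo$session$scalp
  short <- new_recording(a$data[, 1:2000, drop = FALSE], a$labels, a$fs,
                         a$channel_types)
  expect_error(align_streams(short, short), "at least 2 matching trigger")
})
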