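make_rec <- function(dat, labels, fs = 256, types = "seeg") {
  new_recording(dat, labels, fs, types)
}

test_that("band-pass keeps the passband and rejects the stopband, zero phase", {
  fs <- 256
  t <- (0:(20 * fs - 1)) / fs
  s50 <- sin(2 * pi * 50 * t)
  s1 <- sin(2 * pi * 1 * t)
  rec <- make_rec(rbind(s50, s1), c("a", "b"), fs, "scalp")
  out <- bandpass_fir(rec)
  mid <- (5 * fs):(15 * fs)
  ## 50 Hz passes at unit gain with no phase shift
  expect_equal(sd(out$data[1, mid]) / sd(s50[mid]), 1, tolerance = 0.01)
  expect_gt(cor(out$data[1, mid], s50[mid]), 0.9999)
  ## 1 Hz attenuated by more than 20 dB
  expect_lt(sd(out$data[2, mid]) / sd(s1[mid]), 10^(-20 / 20))
  ## all-zero input stays zero
  z <- bandpass_fir(make_rec(matrix(0, 1, 20 * fs), "z", fs, "scalp"))
  expect_equal(max(abs(z$data)), 0)
})

test_that("filtering is linear and rejects bands beyond Nyquist", {
  fs <- 256
  set.seed(2)
  x <- rnorm(10 * fs); y <- rnorm(10 * fs)
  f <- function(v) bandpass_fir(make_rec(matrix(v, 1), "a", fs, "scalp"))$data[1, ]
  expect_rel_equal(f(x + y), f(x) + f(y), 1e-10)
  expect_error(bandpass_fir(make_rec(matrix(x, 1), "a", fs, "scalp"),
                            filter_spec(band = c(5, 130))), "Nyquist")
})

test_that("aux channels pass through the filter untouched", {
  fs <- 256
  trig <- rep(c(1, 0), each = 5 * fs)
  rec <- new_recording(rbind(rnorm(10 * fs), trig), c("a", "TRIG"), fs,
                       c("scalp", "trigger"))
  out <- bandpass_fir(rec)
  expect_identical(out$data[2, ], trig)
})

test_that("bipolar montage pairs consecutive same-shaft contacts only", {
  dat <- matrix(seq_len(5 * 4), 5, 4)
  rec <- make_rec(dat, c("V01", "V02", "V03", "T01", "T02"))
  out <- bipolar_montage(rec)
  expect_identical(out$labels, c("V01-V02", "V02-V03", "T01-T02"))
  expect_equal(out$data[1, ], dat[1, ] - dat[2, ])
  ## identical contacts difference to zero
  rec2 <- make_rec(rbind(dat[1, ], dat[1, ]), c("V01", "V02"))
  expect_equal(max(abs(bipolar_montage(rec2)$data)), 0)
  ## no cross-shaft pairs ever
  expect_false(any(grepl("V.*-T|T.*-V", out$labels)))
})

test_that("bipolar montage annihilates a common reference and keeps midpoints", {
  head <- test_head()
  sensors <- test_sensors(head)
  n <- 100
  set.seed(3)
  base <- matrix(rnorm(nrow(sensors$seeg) * n), ncol = n)
  common <- matrix(rep(rnorm(n), each = nrow(base)), ncol = n)
  r1 <- make_rec(base, sensors$seeg$label)
  r2 <- make_rec(base + common, sensors$seeg$label)
  b1 <- bipolar_montage(r1, sensors)
  b2 <- bipolar_montage(r2, sensors)
  expect_rel_equal(b2$data, b1$data, 1e-12)
  mids <- attr(b1, "midpoints")
  expect_identical(mids$label, b1$labels)
  v12 <- sensors$seeg[sensors$seeg$label %in% c("V01", "V02"), c("x", "y", "z")]
  expect_equal(as.numeric(mids[1, c("x", "y", "z")]),
               unname(colMeans(v12)), tolerance = 1e-12)
})

test_that("bipolar montage reports unparseable labels", {
  rec <- make_rec(matrix(0, 2, 10), c("V01", "weird-label"))
  expect_error(bipolar_montage(rec), "weird-label")
})

test_that("epoch extraction slices exactly and re-zeroes time", {
  fs <- 256
  n <- 200 * fs
  dat <- matrix(seq_len(2 * n), 2, n)
  rec <- new_recording(dat, c("a", "b"), fs, "scalp")
  ep <- extract_epoch(rec, so = 100)
  expect_identical(ncol(ep$data), as.integer(30 * fs))
  first <- (100 - 20) * fs + 1
  expect_equal(ep$data, dat[, first:(first + 30 * fs - 1)],
               ignore_attr = TRUE)
  expect_identical(ep$start_offset, 0)
  expect_identical(attr(ep, "so_sample"), as.integer(20 * fs + 1))
  expect_error(extract_epoch(rec, so = 5), "outside")
  expect_error(extract_epoch(rec, so = 100, pre = -1), "pre and post")
})
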