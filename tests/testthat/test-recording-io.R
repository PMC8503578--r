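test_that("recording construction validates its invariants", {
  expect_error(new_recording(matrix(0, 2, 10), character(0), 256, "scalp"),
               "empty channel list")
  expect_error(new_recording(matrix(0, 2, 10), c("a", "b", "c"), 256, "scalp"),
               "3 labels for 2")
  expect_error(new_recording(matrix(0, 2, 10), c("a", "a"), 256, "scalp"),
               "duplicate")
  expect_error(new_recording(matrix(0, 2, 10), c("a", "b"), -1, "scalp"),
               "fs")
  expect_error(new_recording(matrix(NA_real_, 2, 10), c("a", "b"), 256, "scalp"),
               "NA")
  expect_error(new_recording(matrix(0, 2, 10), c("a", "b"), 256, "bogus"),
               "unknown channel type")
})

test_that("EDF round trip preserves labels, rate, types, and data to the
           quantization step", {
  rec <- toy_recording()
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_identical(back$labels, rec$labels)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$channel_types, rec$channel_types)
  step <- (apply(rec$data, 1, max) - apply(rec$data, 1, min)) / 65535
  expect_true(all(abs(back$data - rec$data) <= step + 1e-12))
})

test_that("EDF read rejects malformed headers", {
  path <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw(paste(rep("x", 300), collapse = "")), path)
  expect_error(read_edf(path), "not an EDF file")
  ## header byte count inconsistent with the channel count
  rec <- toy_recording(nch = 2, n = 512)
  write_edf(rec, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  raw[185:192] <- charToRaw(sprintf("%-8d", 9999))
  writeBin(raw, path)
  expect_error(read_edf(path), "inconsistent")
})

test_that("a simulated session writes EDF + TSV + JSON and reads back", {
  demo <- quick_session(seed = 2)
  dir <- withr::local_tempdir()
  paths <- write_session(demo$session, dir, demo$sensors, stem = "s1")
  expect_true(all(file.exists(paths)))
  sc <- read_recording(paths["scalp"])
  expect_identical(sc$labels, demo$session$scalp$labels)
  expect_identical(sc$channel_types, demo$session$scalp$channel_types)
  sens <- read_sensors_tsv(paths["sensors"])
  expect_equal(sens$seeg$label, demo$sensors$seeg$label)
  truth <- jsonlite::read_json(paths["truth"])
  expect_identical(truth$soz_pair, demo$session$truth$soz_pair)
})

test_that("BrainVision triplet round trips and detects frame mismatches", {
  rec <- toy_recording(nch = 3, n = 700, fs = 250)
  dir <- withr::local_tempdir()
  vhdr <- file.path(dir, "t.vhdr")
  write_brainvision(rec, vhdr,
                    markers = data.frame(type = "Stimulus", description = "SO",
                                         sample = 100L))
  back <- read_brainvision(vhdr)
  expect_identical(back$labels, rec$labels)
  expect_equal(back$fs, rec$fs)
  expect_lt(max(abs(back$data - rec$data)), 1e-4)  # float32 rounding
  expect_identical(attr(back, "markers")$sample, 100L)
  ## truncate the data file so frames do not divide evenly
  sz <- file.info(file.path(dir, "t.eeg"))$size
  con <- file(file.path(dir, "t.eeg"), "r+b")
  truncate_at <- sz - 6   # not a multiple of 3 channels x 4 bytes
  seek(con, 0); raw <- readBin(con, "raw", truncate_at); close(con)
  writeBin(raw, file.path(dir, "t.eeg"))
  expect_error(read_brainvision(vhdr), "mismatched sample counts")
})

test_that("BrainVision header errors carry context", {
  dir <- withr::local_tempdir()
  writeLines("not a header", file.path(dir, "bad.vhdr"))
  expect_error(read_brainvision(file.path(dir, "bad.vhdr")), "not a BrainVision")
  expect_error(read_recording(file.path(dir, "x.foo")), "unsupported")
})
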