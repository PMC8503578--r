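test_that("sessions are bit-identical under a fixed seed", {
  a <- quick_session(seed = 3)
  b <- quick_session(seed = 3)
  expect_identical(a$session$scalp$data, b$session$scalp$data)
  expect_identical(a$session$seeg$data, b$session$seeg$data)
  expect_identical(a$session$truth$soz_labels, b$session$truth$soz_labels)
  c_ <- quick_session(seed = 4)
  expect_false(identical(a$session$scalp$data, c_$session$scalp$data))
})

test_that("zero EMG level adds no variance to scalp channels", {
  a <- quick_session(seed = 5, emg_level = 0)
  b <- quick_session(seed = 5, emg_level = 8)
  emg_ch <- which(a$session$scalp$labels %in%
                    c("T7", "T8", "F7", "F8", "P7", "P8", "Fp1", "Fp2"))
  other <- setdiff(which(a$session$scalp$channel_types == "scalp"), emg_ch)
  expect_false(identical(a$session$scalp$data[emg_ch, ],
                         b$session$scalp$data[emg_ch, ]))
  expect_identical(a$session$scalp$data[other, ], b$session$scalp$data[other, ])
})

test_that("both streams carry the full trigger train and a reference sine", {
  demo <- quick_session(seed = 2, fs = 256, imposed_lag = 300.5,
                        clock_drift_ppm = 50)
  count <- function(rec) {   # rising edges, counting a pulse active at start
    x <- rec$data[rec$labels == "TRIG", ]
    sum(x > 0.5 & !c(FALSE, x[-length(x)] > 0.5))
  }
  expected <- floor(demo$config$duration / demo$config$trigger_interval) + 1
  expect_identical(count(demo$session$scalp), as.integer(expected))
  expect_identical(count(demo$session$seeg), as.integer(expected))
  for (rec in demo$session[c("scalp", "seeg")]) {
    ref <- rec$data[rec$channel_types == "refsine", ]
    sp <- Mod(stats::fft(ref))[seq_len(length(ref) / 2)]
    f <- (which.max(sp[-1])) * rec$fs / length(ref)
    expect_lt(abs(f - 50), 0.1)
  }
})

test_that("ground truth is consistent with the forward model and sensors", {
  demo <- quick_session(seed = 6)
  tr <- demo$session$truth
  expect_true(all(tr$soz_labels %in% demo$sensors$seeg$label))
  expect_equal(as.numeric(tr$mixing_column),
               as.numeric(source_topography(tr$source, demo$sensors,
                                            demo$head)),
               tolerance = 1e-12)
  ## SOZ contacts are the nearest to the source
  d <- sqrt(rowSums(sweep(as.matrix(demo$sensors$seeg[, c("x", "y", "z")]),
                          2, tr$source$position)^2))
  expect_setequal(tr$soz_labels,
                  demo$sensors$seeg$label[order(d)[1:2]])
})

test_that("shallow sources leave a stronger ictal footprint on scalp than
           deep ones", {
  ## forward-model evaluation through the ground-truth mixing columns
  shallow <- quick_session(seed = 7, eccentricity = 0.85)
  deep <- quick_session(seed = 7, eccentricity = 0.45)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(shallow$session$truth$mixing_column) /
              rms(deep$session$truth$mixing_column), 1)
})

test_that("configuration and geometry preconditions are enforced", {
  expect_error(simulation_config(duration = 10), ">= 30")
  head <- test_head()
  sensors <- test_sensors(head)
  src <- source_spec(c(0, 0, 40), c(0, 0, 1), "lvfa", 60, 40)
  cfg <- simulation_config(fs = 100, duration = 30)
  expect_error(simulate_session(cfg, sensors, head, src), "twice the maximum")
  bad_scalp <- sensors
  bad_scalp$scalp$x[1] <- bad_scalp$scalp$x[1] + 5
  expect_error(simulate_session(simulation_config(fs = 256), bad_scalp, head,
                                src), "incompatible sensor/head")
})

test_that("sensor arrays validate counts, pitch and collinearity", {
  head <- test_head()
  sc <- scalp_sensors_1020(head)
  shaft <- seeg_shaft("V", c(30, 0, 0), c(1, 0, 0), 10)
  expect_error(sensor_array(sc[1:5, ], shaft, head = head), "20-37")
  expect_silent(sensor_array(sc[1:5, ], shaft, strict = FALSE))
  bent <- shaft
  bent$y[5] <- 4
  expect_error(sensor_array(sc, bent, head = head), "pitch|collinear")
  expect_error(sensor_array(sc, rbind(shaft, shaft), head = head), "duplicate")
})
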