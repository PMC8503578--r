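test_that("scalp forward matches the independent Legendre-series oracle", {
  head <- test_head()
  sc <- scalp_sensors_1020(head)
  set.seed(42)
  for (i in 1:6) {
    pos <- stats::rnorm(3)
    pos <- pos / sqrt(sum(pos^2)) * stats::runif(1, 2, 85)
    mom <- stats::rnorm(3) * 60
    got <- forward_scalp(pos, sc, head, moment = mom)
    want <- series_forward_oracle(pos, mom, sc, head)
    expect_rel_equal(got, want, 1e-10)
  }
})

test_that("scalp forward symmetry for a dipole at the center", {
  head <- test_head()
  sc <- scalp_sensors_1020(head)
  ## dipole at center: V proportional to moment . electrode direction,
  ## so electrodes on the equatorial plane of the moment get exactly 0
  v <- forward_scalp(c(0, 0, 0), sc, head, moment = c(10, 0, 0))
  midline <- sc$label %in% c("Fz", "Cz", "Pz", "Oz", "Fpz")
  expect_true(all(abs(v[midline]) < 1e-9))
  ## and electrodes at equal angle from the axis agree (z-moment case)
  vz <- forward_scalp(c(0, 0, 0), sc, head, moment = c(0, 0, 10))
  expect_equal(unname(vz[sc$label == "Fp1"]), unname(vz[sc$label == "O2"]),
               tolerance = 1e-12)
  expect_equal(unname(vz[sc$label == "F3"]), unname(vz[sc$label == "P4"]),
               tolerance = 1e-12)
})

test_that("forward maps are linear and superpose", {
  head <- test_head()
  sc <- scalp_sensors_1020(head)
  pos <- c(20, 10, 30)
  m1 <- c(10, 0, 5); m2 <- c(-3, 8, 1)
  expect_equal(forward_scalp(pos, sc, head, moment = 2 * m1),
               2 * forward_scalp(pos, sc, head, moment = m1), tolerance = 1e-12)
  s12 <- forward_scalp(pos, sc, head, moment = m1 + m2)
  s1 <- forward_scalp(pos, sc, head, moment = m1)
  s2 <- forward_scalp(pos, sc, head, moment = m2)
  expect_rel_equal(s12, s1 + s2, 1e-10)
  ## superposition across positions
  pos2 <- c(-15, 25, 5)
  both <- forward_scalp(pos, sc, head, moment = m1) +
    forward_scalp(pos2, sc, head, moment = m2)
  expect_equal(sum(abs(both - (s1 + forward_scalp(pos2, sc, head, moment = m2)))),
               0, tolerance = 1e-12)
})

test_that("shallower sources produce stronger scalp fields, monotonically", {
  head <- test_head()
  sc <- scalp_sensors_1020(head)
  u <- c(1, 1, 0.5); u <- u / sqrt(sum(u^2))
  eccs <- c(0.2, 0.4, 0.55, 0.7, 0.85)
  rms <- vapply(eccs, function(e) {
    v <- forward_scalp(e * head$radius * u, sc, head, moment = 100 * u)
    sqrt(mean(v^2))
  }, 0)
  expect_true(all(diff(rms) > 0))
  ## spec example: 0.8R vs 0.4R RMS ratio > 1
  expect_gt(rms[5] / rms[2], 1)
})

test_that("average reference and domain errors hold for the scalp forward", {
  head <- test_head()
  sc <- scalp_sensors_1020(head)
  v <- forward_scalp(c(30, -10, 20), sc, head, moment = c(5, 5, 5))
  expect_equal(sum(v), 0, tolerance = 1e-9)
  expect_error(forward_scalp(c(0, 0, 95), sc, head, moment = c(1, 0, 0)),
               "outside")
})

test_that("SEEG forward follows the infinite-medium dipole formula", {
  co <- data.frame(label = c("a", "b", "c"),
                   x = c(0, 0, 10), y = c(0, 0, 0), z = c(10, 20, 0))
  v <- forward_seeg(c(0, 0, 0), co, conductivity = 0.33, moment = c(0, 0, 10))
  ## p.d/(4 pi sigma d^3): 1e-10 / (4 pi 0.33 1e-6) volts = 24.114 uV
  expect_equal(unname(v["a"]), 1e-10 / (4 * pi * 0.33 * 1e-6) * 1e6,
               tolerance = 1e-6)
  ## inverse square along the moment axis
  expect_equal(unname(v["a"] / v["b"]), 4, tolerance = 1e-12)
  ## perpendicular plane through the source: zero
  expect_equal(unname(v["c"]), 0, tolerance = 1e-12)
  expect_error(forward_seeg(c(0, 0, 10), co, moment = c(1, 0, 0)), "coincides")
})

test_that("gain matrix agrees with the forward map", {
  head <- test_head()
  sc <- scalp_sensors_1020(head)
  set.seed(1)
  pos <- c(12, -30, 25); mom <- stats::rnorm(3) * 30
  expect_equal(as.numeric(gain_scalp(pos, sc, head) %*% mom),
               unname(forward_scalp(pos, sc, head, moment = mom)),
               tolerance = 1e-10)
})

test_that("source_spec validates pattern bands and geometry", {
  expect_error(source_spec(c(0, 0, 40), c(1, 0, 0), "lvfa", 10, 5), "band")
  expect_error(source_spec(c(0, 0, 40), c(0, 0, 0), "lvfa", 60, 5), "nonzero")
  s <- source_spec(c(0, 0, 40), c(2, 0, 0), "lvfa", 60, 5)
  expect_equal(s$orientation, c(1, 0, 0))
})

test_that("patch sources smooth the topography and deepen the fitted dipole", {
  head <- test_head()
  sc <- scalp_sensors_1020(head)
  u <- c(1, 1, 0.5); u <- u / sqrt(sum(u^2))
  pos <- 0.85 * head$radius * u
  point <- source_spec(pos, u, "lvfa", 60, 5, 100, patch_extent = 0)
  patch <- source_spec(pos, u, "lvfa", 60, 5, 100, patch_extent = 30)
  tp <- source_topography(point, sc, head)
  tq <- source_topography(patch, sc, head)
  expect_lt(screen_outlier_topography(tq)$max_z,
            screen_outlier_topography(tp)$max_z)
  fit <- fit_ecd(tq, sc, head, seed = 1)
  ## extended patch fits as a deeper equivalent dipole
  expect_lte(fit$eccentricity, 0.85 + 1e-6)
  expect_gt(fit$gof, 90)
})
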