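test_that("midpoints and distances follow the geometry", {
  expect_equal(pair_midpoint(c(0, 0, 0), c(2, 0, 0)), c(1, 0, 0))
  expect_equal(pair_midpoint(c(1, 2, 3), c(1, 2, 3)), c(1, 2, 3))
  expect_equal(pair_midpoint(c(5, -1, 2), c(-3, 4, 0)),
               pair_midpoint(c(-3, 4, 0), c(5, -1, 2)))
  pairs <- data.frame(label = c("a", "b"), x = c(3, 0), y = c(4, 0), z = c(0, 0))
  prof <- distance_profile(c(0, 0, 0), pairs)
  expect_equal(prof$distance_mm, c(5, 0))
  pairs$x[2] <- NA
  expect_warning(p2 <- distance_profile(c(0, 0, 0), pairs), "skipped")
  expect_identical(p2$pair, "a")
})

test_that("SOZ center and localization error are plain geometry", {
  coords <- data.frame(label = c("V01", "V02", "V03"),
                       x = c(0, 2, 4), y = 0, z = 0)
  soz <- soz_definition(c("V01", "V02", "V03"), coords)
  expect_equal(soz$center, c(2, 0, 0))
  expect_equal(soz_error(c(2, 0, 0), soz), 0)
  expect_equal(soz_error(c(2, 3, 0), soz), 3)
  expect_error(soz_definition("V09", coords), "missing")
  expect_error(soz_definition(character(0), coords), "at least one")
})

test_that("distances are invariant under a rigid transform", {
  set.seed(6)
  pts <- matrix(rnorm(30), 10, 3)
  dip <- c(1, 2, 3)
  ## random rotation (QR of a random matrix) plus translation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  tr <- c(10, -5, 2)
  pairs1 <- data.frame(label = letters[1:10], x = pts[, 1], y = pts[, 2],
                       z = pts[, 3])
  pts2 <- t(R %*% t(pts)) + matrix(tr, 10, 3, byrow = TRUE)
  pairs2 <- data.frame(label = letters[1:10], x = pts2[, 1], y = pts2[, 2],
                       z = pts2[, 3])
  d1 <- distance_profile(dip, pairs1)$distance_mm
  d2 <- distance_profile(as.numeric(R %*% dip + tr), pairs2)$distance_mm
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("coherence-distance correlations behave on exact and shuffled data", {
  exact <- coherence_distance_correlation(c(1, 0.5, 0), c(0, 0.5, 1))
  expect_equal(exact$pearson_r, -1, tolerance = 1e-12)
  expect_equal(exact$spearman_rho, -1, tolerance = 1e-12)
  set.seed(31)
  ## independent shuffles: near-zero correlation, roughly uniform p-values
  ps <- replicate(200, {
    coh <- runif(20)
    coherence_distance_correlation(coh, sample(runif(20)))$pearson_p
  })
  expect_gt(min(ps), 0)
  expect_lt(abs(mean(ps) - 0.5), 0.1)
  expect_gt(mean(ps < 0.05), 0.01)
  expect_lt(mean(ps < 0.05), 0.12)
  ## degenerate input flagged
  expect_warning(d <- coherence_distance_correlation(rep(1, 5), 1:5),
                 "zero variance")
  expect_true(d$degenerate)
})

test_that("LOWESS smoothing is exact on lines, flat on constants, monotone on
           noisy monotone data", {
  x <- seq(0, 10, length.out = 50)
  const <- lowess_smooth(x, rep(3, 50), span = 0.7)
  expect_lt(max(abs(const$fitted - 3)), 1e-9)
  line <- lowess_smooth(x, 2 * x - 1, span = 0.7)
  expect_lt(max(abs(line$fitted - (2 * line$x - 1))), 1e-9)
  set.seed(12)
  y <- 1 / (1 + exp(-(x - 5))) + rnorm(50, 0, 0.03)
  sm <- lowess_smooth(x, y, span = 0.7)
  expect_true(all(diff(sm$fitted) > -1e-6))
  expect_error(lowess_smooth(x, y, span = 1.5), "span")
  expect_error(lowess_smooth(1:3, 1:3), "at least 5")
})
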