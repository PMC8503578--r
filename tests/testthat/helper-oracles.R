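# Independent oracles used across the suite. These deliberately avoid the
# package's code paths: the forward oracle is a truncated Legendre series
# with recurrences (the package uses the generating-function closed form);
# the coherence oracle is a direct time-domain convolution with explicit
# loop smoothing (the package uses FFTs and cumulative sums).

# surface potential of a dipole in a homogeneous sphere, Legendre series
series_forward_oracle <- function(pos, moment, el, head, nterms = 400) {
  E <- as.matrix(el[, c("x", "y", "z")])
  R <- head$radius * 1e-3
  r0 <- (pos - head$center) * 1e-3
  p <- moment * 1e-9
  b <- sqrt(sum(r0^2))
  f <- b / R
  u <- if (b > 1e-12) r0 / b else p / sqrt(sum(p^2))
  pr <- sum(p * u)
  ptv <- p - pr * u
  ptm <- sqrt(sum(ptv^2))
  Ec <- sweep(E, 2, head$center) * 1e-3
  eh <- Ec / sqrt(rowSums(Ec^2))
  x <- pmin(pmax(as.numeric(eh %*% u), -1), 1)
  s <- sqrt(pmax(1 - x^2, 0))
  cosb <- numeric(length(x))
  if (ptm > 0) {
    th <- ptv / ptm
    ep <- eh - outer(x, u)
    en <- sqrt(rowSums(ep^2))
    ok <- en > 1e-12
    cosb[ok] <- (ep[ok, , drop = FALSE] %*% th) / en[ok]
  }
  V <- numeric(length(x))
  for (j in seq_along(x)) {
    xx <- x[j]
    P <- numeric(nterms); P1 <- numeric(nterms)
    P[1] <- xx; P[2] <- (3 * xx^2 - 1) / 2
    P1[1] <- s[j]; P1[2] <- 3 * s[j] * xx
    for (n in 2:(nterms - 1)) {
      P[n + 1] <- ((2 * n + 1) * xx * P[n] - n * P[n - 1]) / (n + 1)
      P1[n + 1] <- ((2 * n + 1) * xx * P1[n] - (n + 1) * P1[n - 1]) / n
    }
    n <- seq_len(nterms)
    V[j] <- sum((2 * n + 1) / n * f^(n - 1) * (n * pr * P + ptm * cosb[j] * P1))
  }
  V <- V / (4 * pi * head$conductivity * R^2) * 1e6
  V - mean(V)
}

# direct time-domain Morlet transform (same sampled kernel definition)
naive_morlet_tf <- function(x, fs, wp) {
  freqs <- wavelet_freqs(wp)
  n <- length(x)
  xc <- x - mean(x)
  co <- matrix(0i, length(freqs), n)
  for (i in seq_along(freqs)) {
    f0 <- freqs[i]
    sig <- wp$xi / (2 * pi * f0)
    half <- ceiling(4 * sig * fs)
    tt <- (-half:half) / fs
    env <- exp(-tt^2 / (2 * sig^2))
    h <- exp(2i * pi * f0 * tt) * env * (2 / sum(env))
    for (t in seq_len(n)) {
      kk <- (t - half):(t + half)
      ok <- which(kk >= 1 & kk <= n)
      co[i, t] <- sum(xc[kk[ok]] * Conj(h[ok]))
    }
  }
  co
}

# naive coherence: explicit double-loop rectangular smoothing
naive_coherence <- function(x, y, fs, wp) {
  cx <- naive_morlet_tf(x, fs, wp)
  cy <- naive_morlet_tf(y, fs, wp)
  freqs <- wavelet_freqs(wp)
  nf <- nrow(cx); nt <- ncol(cx)
  sxy <- cx * Conj(cy)
  sxx <- Mod(cx)^2
  syy <- Mod(cy)^2
  tsm <- function(m, w) {
    half_lo <- (w - 1) %/% 2; half_hi <- w - 1 - half_lo
    out <- m
    for (i in seq_len(nf)) for (t in seq_len(nt)) {
      lo <- max(1, t - half_lo); hi <- min(nt, t + half_hi)
      out[i, t] <- mean(m[i, lo:hi])
    }
    out
  }
  widths <- round(20 * wp$xi / (2 * pi * freqs) * fs)
  widths <- pmax(widths, 1); widths <- widths + (widths %% 2 == 0)
  sm1 <- function(m) {
    out <- m
    for (i in seq_len(nf)) {
      w <- widths[i]
      half_lo <- (w - 1) %/% 2; half_hi <- w - 1 - half_lo
      for (t in seq_len(nt)) {
        lo <- max(1, t - half_lo); hi <- min(nt, t + half_hi)
        out[i, t] <- mean(m[i, lo:hi])
      }
    }
    out
  }
  fsm <- function(m) {
    out <- m
    for (i in seq_len(nf)) {
      lo <- max(1, i - 4); hi <- min(nf, i + 5)
      out[i, ] <- colMeans(m[lo:hi, , drop = FALSE])
    }
    out
  }
  a <- fsm(sm1(Re(sxy))); b <- fsm(sm1(Im(sxy)))
  xx <- fsm(sm1(sxx)); yy <- fsm(sm1(syy))
  (a^2 + b^2) / (xx * yy)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)) / max(abs(expected)), tol)
}

# three super-Gaussian sources used by the ICA recovery checks
super_gaussian_sources <- function(n, seed) {
  with_seed_t(seed, rbind(
    sign(rnorm(n)) * rnorm(n)^2,
    rt(n, df = 3),
    sin(2 * pi * 7 * seq_len(n) / 256) * rt(n, df = 4)))
}
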