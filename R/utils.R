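#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's RNG
#' state afterwards, so deterministic internals never clobber user seeds.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Moore-Penrose pseudo-inverse via SVD
#' @param x numeric matrix.
#' @param tol relative singular-value tolerance.
#' @keywords internal
pinv <- function(x, tol = 1e-12) {
  s <- svd(x)
  keep <- s$d > tol * max(s$d)
  if (!any(keep)) return(matrix(0, ncol(x), nrow(x)))
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Centered moving average with boundary truncation
#'
#' Running mean over a centered window of `width` samples; near the array
#' ends the window is truncated to the available samples (the denominator
#' shrinks accordingly). O(n) via cumulative sums.
#'
#' @param x numeric vector.
#' @param width window length in samples (>= 1).
#' @keywords internal
moving_average <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  half_lo <- (width - 1L) %/% 2L
  half_hi <- width - 1L - half_lo
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## row-wise moving average over the frequency axis of a matrix (freq x time),
## window given as offsets lo..hi relative to each row, truncated at edges
row_window_mean <- function(m, lo_off, hi_off) {
  nf <- nrow(m)
  cs <- matrix(if (is.complex(m)) 0i else 0, nf + 1L, ncol(m))
  for (i in seq_len(nf)) cs[i + 1L, ] <- cs[i, ] + m[i, ]
  i <- seq_len(nf)
  lo <- pmax(i + lo_off, 1L)
  hi <- pmin(i + hi_off, nf)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

vnorm <- function(v) sqrt(sum(v^2))

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name))
}
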