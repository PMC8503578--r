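## Extended-infomax ICA.
##
## Natural-gradient infomax with the extended sub/super-Gaussian switch:
##   W <- W + lr * (I - K tanh(u) u' - u u') W,   u = W x_white,
## K = diag(+1) for super-Gaussian, diag(-1) for sub-Gaussian components,
## signs re-estimated from the stability criterion
##   sign( E[sech^2 u] E[u^2] - E[u tanh u] ).
## Data are PCA-whitened first; rank deficiency reduces the dimension with a
## warning. Learning-rate annealing follows the angle between successive
## weight updates; the whole procedure is deterministic under the seed
## (which drives the per-iteration sample permutations).

#' Extended-infomax independent component analysis
#'
#' @param x a `seizcoh_recording` or channels x samples matrix.
#' @param n_components number of components; default the numeric rank of the
#'   data (at most the channel count).
#' @param seed RNG seed for the block permutations.
#' @param max_iter maximum passes over the data.
#' @param tol stop when the weight change per iteration falls below this.
#' @param verbose print progress.
#' @return object of class `seizcoh_ica`: `unmixing` (components x
#'   channels), `mixing` (channels x components, its columns are the
#'   topographies), `activations` (components x samples, unit variance),
#'   `signs`, `iterations`, `converged`.
#' @export
run_infomax <- function(x, n_components = NULL, seed = 1, max_iter = 512L,
                        tol = 1e-6, verbose = FALSE) {
  dat <- if (inherits(x, "seizcoh_recording"))
    x$data[x$channel_types %in% c("scalp", "seeg"), , drop = FALSE]
  else as.matrix(x)
  nch <- nrow(dat)
  n <- ncol(dat)
  if (n < nch) stop("need more samples than channels")
  ctr <- rowMeans(dat)
  xc <- dat - ctr

  ## PCA whitening, with rank reduction if needed
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-9
  rank <- sum(keep)
  k <- if (is.null(n_components)) rank else min(n_components, rank)
  if (k < nch && is.null(n_components))
    warning(sprintf("rank-deficient data: reducing to %d dimensions", k))
  E <- eg$vectors[, seq_len(k), drop = FALSE]
  d <- eg$values[seq_len(k)]
  wh <- t(E) / sqrt(d)                     # k x nch whitening
  dewh <- E * rep(sqrt(d), each = nch)     # nch x k  (E %*% diag(sqrt(d)))
  xw <- wh %*% xc

  W <- diag(k)
  signs <- rep(1, k)                       # +1 super-Gaussian to start
  block <- as.integer(ceiling(min(5 * log(n), 0.3 * n)))
  lrate <- 0.00065 / log(max(k, 2))
  I_k <- diag(k)
  old_dW <- NULL
  wchange <- Inf
  it <- 0L

  with_seed(seed, {
    for (it_ in seq_len(max_iter)) {
      it <- it_
      W_old <- W
      perm <- sample.int(n)
      nblk <- n %/% block
      for (bi in seq_len(nblk)) {
        ii <- perm[((bi - 1L) * block + 1L):(bi * block)]
        u <- W %*% xw[, ii, drop = FALSE]
        y <- tanh(u)
        grad <- I_k * block - (signs * y) %*% t(u) - u %*% t(u)
        W <- W + lrate * grad %*% W
        if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
          W <- diag(k); lrate <- lrate * 0.5
          if (verbose) message("blowup, restarting with lrate ", lrate)
          break
        }
      }
      ## sub/super-Gaussian switch on a fixed subsample
      u <- W %*% xw[, seq.int(1L, n, by = max(1L, n %/% 3000L)), drop = FALSE]
      signs <- sign(rowMeans(1 / cosh(u)^2) * rowMeans(u^2) -
                      rowMeans(u * tanh(u)))
      signs[signs == 0] <- 1
      dW <- W - W_old
      wchange <- sum(dW^2)
      if (!is.null(old_dW)) {
        denom <- sqrt(sum(dW^2) * sum(old_dW^2))
        if (denom > 0) {
          ang <- sum(dW * old_dW) / denom
          if (ang < cos(60 * pi / 180)) lrate <- lrate * 0.98
        }
      }
      old_dW <- dW
      if (verbose && it_ %% 50L == 0L)
        message(sprintf("iter %d wchange %.2e lrate %.2e", it_, wchange, lrate))
      if (wchange < tol) break
    }
  })

  unmix <- W %*% wh                        # k x nch
  mix <- dewh %*% solve(W)                 # nch x k
  act <- unmix %*% xc
  sds <- apply(act, 1L, stats::sd)
  sds[sds == 0] <- 1
  unmix <- unmix / sds
  act <- act / sds
  mix <- mix * rep(sds, each = nch)
  rownames(mix) <- rownames(dat)
  structure(list(unmixing = unmix, mixing = mix, activations = act,
                 center = ctr, signs = signs, iterations = it,
                 converged = wchange < tol),
            class = "seizcoh_ica")
}

#' @export
print.seizcoh_ica <- function(x, ...) {
  cat(sprintf("<seizcoh_ica> %d components x %d channels (%d iterations%s)\n",
              nrow(x$unmixing), ncol(x$unmixing), x$iterations,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Screen a component topography for outlier electrodes
#'
#' Leave-one-out Z-score: for each electrode, the absolute deviation of its
#' topography value from the mean of the remaining electrodes, in units of
#' their standard deviation. A component dominated by a single electrode
#' (typically an artifact) is flagged. The statistic is scale-invariant.
#'
#' @param topography numeric vector over electrodes (>= 3).
#' @param threshold flag when max Z exceeds this (default 10).
#' @return list(flag, max_z).
#' @export
screen_outlier_topography <- function(topography, threshold = 10) {
  v <- as.numeric(topography)
  ne <- length(v)
  if (ne < 3L) stop("need at least 3 electrodes")
  z <- vapply(seq_len(ne), function(i) {
    rest <- v[-i]
    s <- stats::sd(rest)
    dev <- abs(v[i] - mean(rest))
    if (s == 0) { if (dev > 0) Inf else 0 } else dev / s
  }, 0)
  mz <- max(z)
  list(flag = mz > threshold, max_z = mz)
}

#' Screen all components of a decomposition
#'
#' Combines the outlier-electrode rule with the dipole fits: a component is
#' retained when it is not an outlier and its equivalent-dipole goodness of
#' fit exceeds `gof_threshold` (a dipolar topography).
#'
#' @param ica a `seizcoh_ica`.
#' @param sensors,head geometry for the dipole fits.
#' @param z_threshold outlier-electrode Z threshold (default 10).
#' @param gof_threshold dipolarity threshold in percent (default 90).
#' @param n_restarts,seed dipole-fit settings.
#' @return data.frame with component, outlier_flag, max_z, gof, retained,
#'   plus the fit list as attribute `"fits"`.
#' @export
screen_components <- function(ica, sensors, head, z_threshold = 10,
                              gof_threshold = 90, n_restarts = 5L, seed = 1) {
  k <- ncol(ica$mixing)
  res <- data.frame(component = seq_len(k), outlier_flag = FALSE,
                    max_z = NA_real_, gof = NA_real_, retained = FALSE)
  fits <- vector("list", k)
  for (i in seq_len(k)) {
    sc <- screen_outlier_topography(ica$mixing[, i], z_threshold)
    res$outlier_flag[i] <- sc$flag
    res$max_z[i] <- sc$max_z
    if (!sc$flag) {
      fits[[i]] <- fit_ecd(ica$mixing[, i], sensors, head,
                           n_restarts = n_restarts, seed = seed + i)
      res$gof[i] <- fits[[i]]$gof
    }
  }
  res$retained <- !res$outlier_flag & !is.na(res$gof) & res$gof > gof_threshold
  attr(res, "fits") <- fits
  res
}

#' Rank candidate ictal components
#'
#' Flagged components are excluded; the rest are ordered by goodness of fit
#' (descending), ties broken by component variance (descending). In the
#' clinical workflow the final choice among these candidates is an expert
#' step; analyses here select among them by coherence with the SEEG.
#'
#' @param ica a `seizcoh_ica`.
#' @param screens data.frame from [screen_components()].
#' @return integer vector of component ids, best first (may be empty).
#' @export
rank_candidates <- function(ica, screens) {
  ok <- which(screens$retained)
  if (!length(ok)) {
    warning("no components retained")
    return(integer(0))
  }
  varc <- colSums(ica$mixing[, ok, drop = FALSE]^2)   # unit-variance activations
  ok[order(-screens$gof[ok], -varc)]
}
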