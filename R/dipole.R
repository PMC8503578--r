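#' Fit an equivalent current dipole to a scalp topography
#'
#' Single dipole in the spherical head model. The position is found by
#' multi-start nonlinear least squares (BFGS on a smooth unconstrained
#' parameterization that maps R^3 into the sphere of eccentricity 0.95,
#' avoiding the surface singularity); at every candidate position the moment
#' is the closed-form linear least-squares solution against the three
#' unit-moment gain columns. Goodness of fit is
#' GOF = 100 * (1 - residual variance / topography variance).
#'
#' @param topography numeric vector over the scalp electrodes
#'   (average-referenced; it is re-referenced defensively).
#' @param sensors a `seizcoh_sensors` or scalp coordinate data.frame.
#' @param head a `seizcoh_head`.
#' @param n_restarts number of random starting positions (default 5), drawn
#'   uniformly in the sphere of eccentricity 0.8.
#' @param seed RNG seed for the starts.
#' @param max_ecc eccentricity bound for the fitted position.
#' @return object of class `seizcoh_dipole`: position (mm), moment (nA.m),
#'   gof (percent), converged, eccentricity.
#' @export
fit_ecd <- function(topography, sensors, head, n_restarts = 5L, seed = 1,
                    max_ecc = 0.95) {
  stopifnot(inherits(head, "seizcoh_head"))
  el <- if (inherits(sensors, "seizcoh_sensors")) sensors$scalp else sensors
  v <- as.numeric(topography)
  if (length(v) != nrow(el)) stop("topography length must match electrode count")
  if (length(v) < 6L) stop("need at least 6 electrodes for a dipole fit")
  v <- v - mean(v)
  tot <- sum(v^2)
  if (tot == 0) stop("all-zero topography")
  Rmax <- max_ecc * head$radius

  elm <- as.matrix(el[, c("x", "y", "z")])
  rownames(elm) <- el$label
  gain <- function(pos) gain_scalp(pos, elm, head)
  ## residual sum of squares with closed-form moment at position pos
  rss_at <- function(pos) {
    G <- gain(pos)
    fit <- stats::lm.fit(G, v)
    sum(fit$residuals^2)
  }
  ## smooth bijection R^3 -> open ball of radius Rmax (centered on the head)
  to_pos <- function(w) {
    r <- vnorm(w)
    head$center + if (r == 0) w else w * (Rmax * r / sqrt(1 + r^2)) / r
  }
  obj <- function(w) rss_at(to_pos(w))
  from_ecc <- function(p) p / sqrt(max(1 - sum(p^2), 1e-6))  # ecc vec -> w

  ## coarse scan (Fibonacci-sphere directions x eccentricity shells) picks
  ## refinement starts, plus random restarts for robustness
  ndir <- 40L
  gold <- pi * (3 - sqrt(5))
  kk <- seq_len(ndir)
  zdir <- 1 - (2 * kk - 1) / ndir
  rdir <- sqrt(pmax(1 - zdir^2, 0))
  dirs <- cbind(rdir * cos(gold * kk), rdir * sin(gold * kk), zdir)
  grid <- rbind(dirs * 0.3, dirs * 0.55, dirs * 0.8)
  grid_rss <- apply(grid, 1L, function(p) rss_at(head$center + p * head$radius))
  grid_starts <- grid[order(grid_rss)[seq_len(3L)], , drop = FALSE]

  rand_starts <- with_seed(seed, {
    s <- matrix(NA_real_, n_restarts, 3L)
    k <- 0L
    while (k < n_restarts) {
      p <- stats::runif(3L, -1, 1)
      if (vnorm(p) <= 0.8) { k <- k + 1L; s[k, ] <- p }
    }
    s
  })
  starts <- rbind(grid_starts, rand_starts)
  best <- NULL
  converged <- FALSE
  for (i in seq_len(nrow(starts))) {   # quick pass over every start ...
    w0 <- from_ecc(starts[i, ])        # (start eccentricity = |row|)
    opt <- tryCatch(
      stats::optim(w0, obj, method = "BFGS",
                   control = list(maxit = 40, reltol = 1e-7)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("dipole fit failed from every start")
  polish <- tryCatch(                  # ... then polish the winner
    stats::optim(best$par, obj, method = "BFGS",
                 control = list(maxit = 400, reltol = 1e-13)),
    error = function(e) NULL)
  if (!is.null(polish) && polish$value <= best$value) best <- polish
  converged <- !is.null(polish) && polish$convergence == 0
  pos <- to_pos(best$par)
  G <- gain(pos)
  mom <- stats::lm.fit(G, v)$coefficients
  resid <- v - G %*% mom
  gof <- 100 * (1 - sum(resid^2) / tot)
  structure(list(position = as.numeric(pos), moment = as.numeric(mom),
                 gof = max(0, min(100, gof)), converged = converged,
                 eccentricity = vnorm(pos - head$center) / head$radius),
            class = "seizcoh_dipole")
}

#' @export
print.seizcoh_dipole <- function(x, ...) {
  cat(sprintf("<dipole> (%.1f, %.1f, %.1f) mm, |q| %.1f nA.m, GOF %.2f%%%s\n",
              x$position[1], x$position[2], x$position[3], vnorm(x$moment),
              x$gof, if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Write dipole fits to a JSON file
#' @param fits list of `seizcoh_dipole` (NULL entries skipped).
#' @param path output path.
#' @export
write_dipoles_json <- function(fits, path) {
  recs <- list()
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (is.null(f)) next
    recs[[length(recs) + 1L]] <- list(
      component = i, x_mm = f$position[1], y_mm = f$position[2],
      z_mm = f$position[3], qx = f$moment[1], qy = f$moment[2],
      qz = f$moment[3], gof = f$gof)
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
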