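## Forward models.
##
## Scalp: closed-form surface potential of a current dipole inside a
## homogeneous conducting sphere with insulating exterior. Writing the
## classical Legendre expansion
##   V = 1/(4 pi sigma R^2) * sum_n (2n+1)/n f^(n-1)
##         [ n p_r P_n(cos g) + p_t P_n^1(cos g) cos b ],   f = b/R,
## the radial and tangential series both have generating-function closed
## forms, used here (the truncated series itself serves as an independent
## oracle in the tests):
##   sum (2n+1) f^(n-1) P_n(x)      = ((1-f^2)/D^(3/2) - 1)/f,  D = 1-2fx+f^2
##   sum (2n+1)/n f^(n-1) P_n^1(x)  = 2 s / D^(3/2)
##                                    + s (1+sqrt(D))/(sqrt(D)(1-fx+sqrt(D)))
## with s = sqrt(1-x^2).
##
## SEEG: infinite homogeneous medium dipole potential V = p.d/(4 pi sigma d^3)
## (depth contacts are far from the skull boundary at these distances).

#' Ictal source specification
#'
#' @param position 3-vector, dipole position in mm.
#' @param orientation 3-vector, dipole orientation (normalized internally).
#' @param pattern one of `"lvfa"`, `"polyspike_burst"`,
#'   `"repetitive_discharge"`, `"preictal_spikes"`.
#' @param characteristic_frequency Hz; must be inside the pattern's plausible
#'   band (low-voltage fast activity 30-80 Hz, repetitive discharges 5-15 Hz,
#'   polyspike bursts 5-100 Hz, preictal spikes 0.1-5 Hz).
#' @param onset_time seizure onset in s from recording start.
#' @param amplitude total dipole moment scale in nA.m (RMS of the post-onset
#'   moment time course, summed over the patch).
#' @param patch_extent geodesic radius in mm of the synchronously active
#'   cortical patch the generator stands for; 0 (default) is a point dipole.
#'   A patch is modeled as a cluster of parallel dipoles on the spherical
#'   cap through the source position, sharing one waveform and splitting the
#'   total moment.
#' @return object of class `seizcoh_source`.
#' @export
source_spec <- function(position, orientation, pattern,
                        characteristic_frequency, onset_time, amplitude = 65,
                        patch_extent = 0) {
  pattern <- match.arg(pattern, c("lvfa", "polyspike_burst",
                                  "repetitive_discharge", "preictal_spikes"))
  if (length(position) != 3L || length(orientation) != 3L)
    stop("position and orientation must be 3-vectors")
  if (vnorm(orientation) == 0) stop("orientation must be nonzero")
  band <- switch(pattern,
                 lvfa = c(30, 80),
                 polyspike_burst = c(5, 100),
                 repetitive_discharge = c(5, 15),
                 preictal_spikes = c(0.1, 5))
  if (characteristic_frequency < band[1] || characteristic_frequency > band[2])
    stop(sprintf("characteristic_frequency %g Hz outside the %s band [%g, %g]",
                 characteristic_frequency, pattern, band[1], band[2]))
  if (patch_extent < 0) stop("patch_extent must be >= 0")
  structure(list(position = as.numeric(position),
                 orientation = as.numeric(orientation) / vnorm(orientation),
                 pattern = pattern,
                 characteristic_frequency = characteristic_frequency,
                 onset_time = onset_time, amplitude = amplitude,
                 patch_extent = patch_extent),
            class = "seizcoh_source")
}

#' Dipole cluster representing a cortical patch
#'
#' Deterministic layout: the center plus two rings (6 and 12 points at half
#' and full geodesic radius) on the spherical cap through the source
#' position. Each cluster dipole is oriented like the source but tilted with
#' the local cap normal (for a radial source this is the surface-normal
#' orientation of a curved cortical sheet, which is what produces the
#' classic "extended patches fit as deeper dipoles" bias). Weights split the
#' total moment evenly.
#'
#' @param source a `seizcoh_source`.
#' @param head a `seizcoh_head` (the cap lives on the sphere through the
#'   source at its eccentricity).
#' @return list(positions = k x 3 mm, orientations = k x 3 unit rows,
#'   weights = k-vector summing to 1).
#' @export
patch_dipoles <- function(source, head) {
  pos <- source$position
  ext <- source$patch_extent %||% 0
  if (ext <= 0)
    return(list(positions = matrix(pos, 1L, 3L),
                orientations = matrix(source$orientation, 1L, 3L),
                weights = 1))
  c0 <- head$center
  v <- pos - c0
  b <- vnorm(v)
  if (b < 1e-9) stop("patch source cannot sit at the head center")
  u <- v / b
  a <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  t1 <- a - sum(a * u) * u; t1 <- t1 / vnorm(t1)
  t2 <- c(u[2] * t1[3] - u[3] * t1[2], u[3] * t1[1] - u[1] * t1[3],
          u[1] * t1[2] - u[2] * t1[1])
  ring <- function(r_geo, npts) {
    alpha <- r_geo / b                    # geodesic angle on the cap
    phi <- 2 * pi * (seq_len(npts) - 1L) / npts
    t(vapply(phi, function(p)
      cos(alpha) * u + sin(alpha) * (cos(p) * t1 + sin(p) * t2), numeric(3)))
  }
  D <- rbind(matrix(u, 1L, 3L), ring(ext / 2, 6L), ring(ext, 12L))
  P <- sweep(D * b, 2L, c0, `+`)
  ## rotate the source orientation with the local normal: R_j maps u -> d_j
  O <- t(apply(D, 1L, function(d) rotate_with(source$orientation, u, d)))
  list(positions = P, orientations = O,
       weights = rep(1 / nrow(P), nrow(P)))
}

## rotate vector x by the minimal rotation taking unit vector a to unit b
rotate_with <- function(x, a, b) {
  cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  cosang <- sum(a * b)
  if (cosang > 1 - 1e-12) return(x)
  if (cosang < -1 + 1e-12) return(-x)     # antipodal: flip
  ## Rodrigues with k = cr / |cr|, sin = |cr|
  s2 <- sum(cr^2)
  x * cosang + c(cr[2] * x[3] - cr[3] * x[2], cr[3] * x[1] - cr[1] * x[3],
                 cr[1] * x[2] - cr[2] * x[1]) +
    cr * (sum(cr * x) * (1 - cosang) / s2)
}

#' Summed scalp topography of a (possibly patch) source
#' @param source a `seizcoh_source`.
#' @param sensors,head geometry.
#' @return average-referenced potentials in microvolts for the total moment.
#' @export
source_topography <- function(source, sensors, head) {
  pd <- patch_dipoles(source, head)
  v <- 0
  for (j in seq_len(nrow(pd$positions)))
    v <- v + forward_scalp(pd$positions[j, ], sensors, head,
                           moment = pd$orientations[j, ] * source$amplitude *
                             pd$weights[j])
  v
}

#' Scalp potentials of a dipole in the spherical head model
#'
#' @param source a `seizcoh_source`, or a 3-vector position in mm (then
#'   `moment` must be given).
#' @param sensors a `seizcoh_sensors` or a scalp coordinate data.frame
#'   (label, x, y, z in mm on the sphere).
#' @param head a `seizcoh_head`.
#' @param moment dipole moment 3-vector in nA.m; defaults to
#'   `orientation * amplitude` of the source.
#' @return named vector of average-referenced potentials in microvolts.
#' @export
forward_scalp <- function(source, sensors, head, moment = NULL) {
  stopifnot(inherits(head, "seizcoh_head"))
  if (inherits(source, "seizcoh_source")) {
    pos <- source$position
    if (is.null(moment)) moment <- source$orientation * source$amplitude
  } else {
    pos <- as.numeric(source)
    if (is.null(moment)) stop("moment required when source is a bare position")
  }
  el <- if (inherits(sensors, "seizcoh_sensors")) sensors$scalp else sensors
  E <- as.matrix(el[, c("x", "y", "z")])
  v <- dipole_potential_sphere(pos, moment, E, head)
  names(v) <- el$label
  v - mean(v)
}

#' Scalp gain matrix of a dipole position
#'
#' Potentials are linear in the moment: `forward_scalp(pos, ..., moment = p)`
#' equals `gain_scalp(pos, ...) %*% p`. The three unit-moment columns share
#' all geometry terms, which makes the dipole fit's inner loop cheap.
#'
#' @param pos 3-vector position in mm.
#' @param sensors a `seizcoh_sensors` or scalp coordinate data.frame.
#' @param head a `seizcoh_head`.
#' @return electrodes x 3 matrix in microvolts per nA.m, average-referenced.
#' @export
gain_scalp <- function(pos, sensors, head) {
  E <- if (is.matrix(sensors)) sensors else {
    el <- if (inherits(sensors, "seizcoh_sensors")) sensors$scalp else sensors
    m <- as.matrix(el[, c("x", "y", "z")])
    rownames(m) <- el$label
    m
  }
  R <- head$radius * 1e-3
  r0 <- (as.numeric(pos) - head$center) * 1e-3
  b <- vnorm(r0)
  if (b >= R) stop("source outside the head sphere")
  f <- b / R
  if (f > 0.999) stop("source too close to the sphere surface (eccentricity > 0.999)")
  Ec <- sweep(E, 2L, head$center) * 1e-3
  ehat <- Ec / sqrt(rowSums(Ec^2))
  u <- if (b > 1e-12) r0 / b else c(0, 0, 1)
  x <- pmin(pmax(as.numeric(ehat %*% u), -1), 1)
  D <- 1 - 2 * f * x + f^2
  sqD <- sqrt(D)
  rad <- if (f < 1e-9) 3 * x + 7.5 * f * (x^2 - 1/3) else ((1 - f^2) / D^1.5 - 1) / f
  tang <- 2 / D^1.5 + (1 + sqD) / (sqD * (1 - f * x + sqD))
  ## for unit moment e_k: p_r = u[k], tangential part t_k = e_k - u[k] u;
  ## p_t cos(beta) * sin(gamma) = t_k . eperp_hat * |eperp| = e_k.ehat - x u[k]
  ## (tang above already has the sin(gamma) factor divided out)
  scale <- 1e6 * 1e-9 / (4 * pi * head$conductivity * R^2)
  G <- matrix(0, nrow(E), 3L)
  for (k in 1:3) {
    tk <- as.numeric(ehat[, k] - x * u[k])   # = e_k.ehat - (e_k.u)(ehat.u)
    G[, k] <- scale * (u[k] * rad + tk * tang)
  }
  Gm <- G - matrix(colMeans(G), nrow(G), 3L, byrow = TRUE)
  rownames(Gm) <- rownames(E)
  Gm
}

## core closed form; positions mm, moment nA.m, output microvolts,
## potentials at electrode rows of E (assumed on the sphere)
dipole_potential_sphere <- function(pos, moment, E, head) {
  R <- head$radius * 1e-3
  r0 <- (pos - head$center) * 1e-3
  p <- moment * 1e-9
  b <- vnorm(r0)
  if (b >= R) stop("source outside the head sphere")
  f <- b / R
  if (f > 0.999) stop("source too close to the sphere surface (eccentricity > 0.999)")
  Ec <- sweep(E, 2L, head$center) * 1e-3
  ehat <- Ec / sqrt(rowSums(Ec^2))
  if (b > 1e-12) {
    u <- r0 / b
  } else {
    u <- if (vnorm(p) > 0) p / vnorm(p) else c(0, 0, 1)
  }
  pr <- sum(p * u)
  pt_vec <- p - pr * u
  ptm <- vnorm(pt_vec)
  x <- as.numeric(ehat %*% u)
  x <- pmin(pmax(x, -1), 1)
  D <- 1 - 2 * f * x + f^2
  sqD <- sqrt(D)
  s <- sqrt(pmax(1 - x^2, 0))
  rad <- if (f < 1e-9) 3 * x + 7.5 * f * (x^2 - 1/3) else ((1 - f^2) / D^1.5 - 1) / f
  tang <- 2 * s / D^1.5 + s * (1 + sqD) / (sqD * (1 - f * x + sqD))
  cosb <- numeric(length(x))
  if (ptm > 0) {
    that <- pt_vec / ptm
    eperp <- ehat - outer(x, u)
    en <- sqrt(rowSums(eperp^2))
    ok <- en > 1e-12
    cosb[ok] <- (eperp[ok, , drop = FALSE] %*% that) / en[ok]
  }
  V <- (pr * rad + ptm * cosb * tang) / (4 * pi * head$conductivity * R^2)
  V * 1e6
}

#' SEEG contact potentials of a dipole (infinite homogeneous medium)
#'
#' @param source a `seizcoh_source` or 3-vector position in mm.
#' @param sensors a `seizcoh_sensors` or SEEG coordinate data.frame.
#' @param conductivity S/m (default 0.33).
#' @param moment dipole moment 3-vector in nA.m.
#' @return named vector of potentials in microvolts.
#' @export
forward_seeg <- function(source, sensors, conductivity = 0.33, moment = NULL) {
  if (inherits(source, "seizcoh_source")) {
    pos <- source$position
    if (is.null(moment)) moment <- source$orientation * source$amplitude
  } else {
    pos <- as.numeric(source)
    if (is.null(moment)) stop("moment required when source is a bare position")
  }
  co <- if (inherits(sensors, "seizcoh_sensors")) sensors$seeg else sensors
  C <- as.matrix(co[, c("x", "y", "z")])
  d <- sweep(C, 2L, pos) * 1e-3
  dist3 <- rowSums(d^2)^1.5
  if (any(dist3 < 1e-18)) stop("SEEG contact coincides with the source position")
  p <- moment * 1e-9
  v <- (d %*% p) / (4 * pi * conductivity * dist3)
  v <- as.numeric(v) * 1e6
  names(v) <- co$label
  v
}
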