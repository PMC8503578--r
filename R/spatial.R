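## Spatial statistics in the common (mm) coordinate frame: dipole-to-pair
## distance profiles, seizure-onset-zone geometric center and localization
## error, coherence-distance correlations, and LOWESS display smoothing.
## Distances to bipolar SEEG pairs are measured to the pair midpoint.

#' Midpoint of a contact pair
#' @param contact_a,contact_b 3-vectors in mm.
#' @return componentwise mean, a 3-vector.
#' @export
pair_midpoint <- function(contact_a, contact_b) {
  (as.numeric(contact_a) + as.numeric(contact_b)) / 2
}

#' Euclidean distances from a dipole to SEEG pair midpoints
#'
#' @param dipole a `seizcoh_dipole` or 3-vector position in mm.
#' @param pairs data.frame with label, x, y, z (midpoints, e.g. the
#'   `"midpoints"` attribute of [bipolar_montage()]); rows with missing
#'   coordinates are skipped with a warning.
#' @return data.frame with pair and distance_mm.
#' @export
distance_profile <- function(dipole, pairs) {
  pos <- if (inherits(dipole, "seizcoh_dipole")) dipole$position
  else as.numeric(dipole)
  xyz <- as.matrix(pairs[, c("x", "y", "z")])
  ok <- stats::complete.cases(xyz)
  if (!all(ok)) warning(sum(!ok), " pair(s) without coordinates skipped")
  d <- sqrt(rowSums(sweep(xyz[ok, , drop = FALSE], 2L, pos)^2))
  data.frame(pair = pairs$label[ok], distance_mm = d, stringsAsFactors = FALSE)
}

#' Seizure-onset-zone definition
#'
#' @param labels SOZ contact labels.
#' @param coords data.frame with label, x, y, z for (at least) those contacts.
#' @return list(labels, center) with the geometric center as the unweighted
#'   mean of the member contact coordinates.
#' @export
soz_definition <- function(labels, coords) {
  if (!length(labels)) stop("SOZ needs at least one contact")
  idx <- match(labels, coords$label)
  if (anyNA(idx)) stop("SOZ contact(s) missing from coordinates: ",
                       paste(labels[is.na(idx)], collapse = ", "))
  ctr <- colMeans(as.matrix(coords[idx, c("x", "y", "z")]))
  list(labels = labels, center = as.numeric(ctr))
}

#' Dipole-to-SOZ localization error
#' @param dipole a `seizcoh_dipole` or 3-vector in mm.
#' @param soz a [soz_definition()] result.
#' @return Euclidean distance in mm.
#' @export
soz_error <- function(dipole, soz) {
  pos <- if (inherits(dipole, "seizcoh_dipole")) dipole$position
  else as.numeric(dipole)
  vnorm(pos - soz$center)
}

#' Correlation between coherence and distance across pairs
#'
#' @param coherence numeric vector (e.g. per-pair SNA).
#' @param distance numeric vector of the same length (mm).
#' @return list: pearson_r, pearson_p, spearman_rho, spearman_p, n,
#'   degenerate (TRUE when either variable has zero variance).
#' @export
coherence_distance_correlation <- function(coherence, distance) {
  if (length(coherence) != length(distance)) stop("length mismatch")
  if (length(coherence) < 3L) stop("need at least 3 pairs")
  if (stats::sd(coherence) == 0 || stats::sd(distance) == 0) {
    warning("zero variance: correlation undefined")
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                n = length(coherence), degenerate = TRUE))
  }
  pe <- stats::cor.test(coherence, distance, method = "pearson")
  sp <- stats::cor.test(coherence, distance, method = "spearman", exact = FALSE)
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(coherence), degenerate = FALSE)
}

#' LOWESS smoothing for display
#'
#' Tricube-weighted local linear fit (Cleveland's LOWESS) evaluated at the
#' sample x positions. Display layer only; no statistic is derived from it.
#'
#' @param x,y numeric vectors (>= 5 points).
#' @param span smoothing fraction in (0, 1].
#' @param iter robustness iterations (default 3, as in classical LOWESS).
#' @return data.frame(x, fitted), sorted by x.
#' @export
lowess_smooth <- function(x, y, span = 0.7, iter = 3L) {
  if (length(x) < 5L) stop("need at least 5 points")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  fit <- stats::lowess(x, y, f = span, iter = iter)
  data.frame(x = fit$x, fitted = fit$y)
}
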