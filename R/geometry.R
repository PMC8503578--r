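#' Spherical head model
#'
#' Homogeneous conducting sphere used both as the forward model for the
#' synthetic generator and as the head model for equivalent-current-dipole
#' fitting. Coordinates are in mm; conductivity in S/m.
#'
#' @param radius scalp sphere radius in mm (default 92.5, an adult head).
#' @param center 3-vector, sphere center in mm.
#' @param conductivity homogeneous tissue conductivity in S/m (default 0.33).
#' @return object of class `seizcoh_head`.
#' @export
head_model <- function(radius = 92.5, center = c(0, 0, 0), conductivity = 0.33) {
  stopifnot_scalar(radius, "radius")
  stopifnot_scalar(conductivity, "conductivity")
  if (radius <= 0) stop("radius must be > 0")
  if (conductivity <= 0) stop("conductivity must be > 0")
  if (length(center) != 3L) stop("center must be a 3-vector")
  structure(list(radius = radius, center = as.numeric(center),
                 conductivity = conductivity),
            class = "seizcoh_head")
}

## idealized 10-20 positions as (inclination from vertex, azimuth) in degrees;
## azimuth measured counterclockwise from +x (right ear), +y anterior
POS_1020 <- local({
  p <- rbind(
    Cz  = c(0,    0),
    Fz  = c(36,  90), C3 = c(36, 180), Pz = c(36, 270), C4 = c(36, 0),
    F3  = c(48, 129), F4 = c(48,  51), P3 = c(48, 231), P4 = c(48, 309),
    Fpz = c(72,  90), Fp1 = c(72, 108), Fp2 = c(72, 72),
    F7  = c(72, 144), F8 = c(72,  36),
    T7  = c(72, 180), T8 = c(72,   0),
    P7  = c(72, 216), P8 = c(72, 324),
    O1  = c(72, 252), O2 = c(72, 288), Oz = c(72, 270))
  colnames(p) <- c("incl", "az")
  p
})

## scalp channels conventionally carrying muscle (EMG) contamination
EMG_PRONE <- c("Fp1", "Fp2", "F7", "F8", "T7", "T8", "P7", "P8")

#' Scalp electrode layout: spherical 10-20 projection
#'
#' Projects an idealized 21-electrode 10-20 set onto the head sphere.
#' Electrodes can be dropped to emulate positions blocked by SEEG anchors.
#'
#' @param head a `seizcoh_head`.
#' @param drop labels to omit.
#' @return data.frame with columns label, x, y, z (mm).
#' @export
scalp_sensors_1020 <- function(head, drop = character()) {
  stopifnot(inherits(head, "seizcoh_head"))
  keep <- setdiff(rownames(POS_1020), drop)
  ang <- POS_1020[keep, , drop = FALSE] * pi / 180
  R <- head$radius
  data.frame(label = keep,
             x = head$center[1] + R * sin(ang[, 1]) * cos(ang[, 2]),
             y = head$center[2] + R * sin(ang[, 1]) * sin(ang[, 2]),
             z = head$center[3] + R * cos(ang[, 1]),
             stringsAsFactors = FALSE)
}

#' Construct a depth-electrode shaft
#'
#' Contacts are collinear, numbered from the tip (deepest contact first),
#' labeled `<shaft><01..n>`.
#'
#' @param label shaft letter(s).
#' @param tip 3-vector, deepest contact position in mm.
#' @param direction 3-vector pointing from tip outwards (toward entry).
#' @param n_contacts number of contacts (2-18 on clinical electrodes).
#' @param pitch center-to-center contact spacing in mm (default 3.5).
#' @return data.frame with columns label, shaft, index, x, y, z.
#' @export
seeg_shaft <- function(label, tip, direction, n_contacts, pitch = 3.5) {
  if (length(tip) != 3L || length(direction) != 3L)
    stop("tip and direction must be 3-vectors")
  if (n_contacts < 2L) stop("a shaft needs at least 2 contacts")
  u <- direction / vnorm(direction)
  idx <- seq_len(n_contacts)
  pos <- t(vapply(idx, function(i) tip + (i - 1) * pitch * u, numeric(3)))
  data.frame(label = sprintf("%s%02d", label, idx), shaft = label, index = idx,
             x = pos[, 1], y = pos[, 2], z = pos[, 3], stringsAsFactors = FALSE)
}

#' Assemble a sensor array
#'
#' Validates the joint scalp + SEEG geometry: unique labels, collinear
#' equispaced shaft contacts, scalp electrodes on the head sphere, and the
#' clinically plausible sensor counts (20-37 scalp electrodes, 2-258 SEEG
#' contacts) unless `strict = FALSE`.
#'
#' @param scalp data.frame from [scalp_sensors_1020()] (label, x, y, z).
#' @param seeg data.frame rbind of [seeg_shaft()] outputs.
#' @param head optional `seizcoh_head` for the on-sphere check.
#' @param pitch nominal contact pitch in mm.
#' @param strict enforce the sensor-count ranges.
#' @return object of class `seizcoh_sensors` (list with scalp and seeg).
#' @export
sensor_array <- function(scalp, seeg, head = NULL, pitch = 3.5, strict = TRUE) {
  labs <- c(scalp$label, seeg$label)
  if (anyDuplicated(labs)) stop("duplicate sensor labels")
  if (strict) {
    if (nrow(scalp) < 20L || nrow(scalp) > 37L)
      stop("expected 20-37 scalp electrodes (got ", nrow(scalp),
           "); use strict = FALSE to override")
    if (nrow(seeg) < 2L || nrow(seeg) > 258L)
      stop("expected 2-258 SEEG contacts (got ", nrow(seeg), ")")
  }
  if (!is.null(head)) {
    r <- sqrt((scalp$x - head$center[1])^2 + (scalp$y - head$center[2])^2 +
                (scalp$z - head$center[3])^2)
    if (any(abs(r - head$radius) > 1e-6))
      stop("scalp electrodes must lie on the head sphere")
  }
  for (sh in unique(seeg$shaft)) {
    p <- as.matrix(seeg[seeg$shaft == sh, c("x", "y", "z")])
    if (nrow(p) < 2L) next
    d <- diff(p)
    step <- sqrt(rowSums(d^2))
    if (!is.na(pitch) && any(abs(step - pitch) > 1e-6))
      stop("shaft ", sh, ": contacts not at the configured pitch")
    u <- d / step
    if (nrow(u) > 1L && any(abs(u %*% u[1L, ] - 1) > 1e-9))
      stop("shaft ", sh, ": contacts not collinear")
  }
  structure(list(scalp = scalp, seeg = seeg, pitch = pitch),
            class = "seizcoh_sensors")
}

#' Write sensor coordinates to TSV
#' @param sensors a `seizcoh_sensors`.
#' @param path output TSV path (columns label, x_mm, y_mm, z_mm, type).
#' @export
write_sensors_tsv <- function(sensors, path) {
  df <- rbind(
    data.frame(label = sensors$scalp$label, x_mm = sensors$scalp$x,
               y_mm = sensors$scalp$y, z_mm = sensors$scalp$z, type = "scalp"),
    data.frame(label = sensors$seeg$label, x_mm = sensors$seeg$x,
               y_mm = sensors$seeg$y, z_mm = sensors$seeg$z, type = "seeg"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sensor coordinates from TSV
#' @param path TSV with columns label, x_mm, y_mm, z_mm, type.
#' @return a `seizcoh_sensors` (strict checks off).
#' @export
read_sensors_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm", "type")
  if (!all(need %in% names(df))) stop("sensor TSV must have columns ",
                                      paste(need, collapse = ", "))
  mk <- function(d) data.frame(label = d$label, x = d$x_mm, y = d$y_mm,
                               z = d$z_mm, stringsAsFactors = FALSE)
  sc <- mk(df[df$type == "scalp", ])
  se <- mk(df[df$type == "seeg", ])
  se$shaft <- sub("[0-9]+$", "", se$label)
  se$index <- as.integer(sub("^.*?([0-9]+)$", "\\1", se$label))
  sensor_array(sc, se, strict = FALSE, pitch = NA_real_)
}
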