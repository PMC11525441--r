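#' Per-frame kinematic feature series
#'
#' Lightweight container for one nonnegative scalar per frame: the substrate
#' of all per-sequence summary statistics. Every feature in this package is a
#' Euclidean norm, a distance, an angle in `[0, pi]`, a ratio, an area or a
#' volume, so values are nonnegative by construction (`NA` marks frames where
#' a feature is undefined, e.g. the quantity of motion on an empty silhouette
#' frame).
#'
#' @param values numeric vector, one value per frame.
#' @param name feature identifier, e.g. `"speed"`.
#' @param keypoint keypoint label or `"ALL"` for full-body features.
#' @param units unit string, e.g. `"m/s"` or `"dimensionless"`.
#' @param framerate sampling rate in Hz of the source series.
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, name, keypoint = "ALL",
                           units = "dimensionless", framerate = NA_real_) {
  values <- as.numeric(values)
  if (any(values < -1e-12, na.rm = TRUE))
    stop(sprintf("feature %s produced negative values", dQuote(name)))
  values[values < 0] <- 0
  structure(list(values = values, name = name, keypoint = keypoint,
                 units = units, framerate = framerate),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  cat(sprintf("<feature_series> %s [%s] keypoint=%s, %d frames\n",
              x$name, x$units, x$keypoint, length(x$values)))
  invisible(x)
}

.row_norms <- function(m) sqrt(rowSums(m * m))

# Pick a per-keypoint derivative channel: file-provided if present and
# preferred, otherwise finite differences of the base channel.
.derivative_channel <- function(series, keypoint, file_channel, base, order,
                                prefer_file_channels, unwrap = FALSE) {
  i <- .kp_index(series, keypoint)
  if (prefer_file_channels && !is.null(series[[file_channel]]))
    return(series[[file_channel]][, i, , drop = TRUE])
  x <- series[[base]][, i, , drop = TRUE]
  if (unwrap) x <- .unwrap_angles(x)
  finite_difference(x, order, series$framerate)
}

#' Speed of a keypoint
#'
#' Euclidean norm of the keypoint velocity, `v_j(t) = ||d p_j / dt||_2`, in
#' m/s. Uses the file-provided velocity channel when the source carried one,
#' otherwise first-order finite differences of position.
#'
#' @param series a [keypoint_series].
#' @param keypoint keypoint label.
#' @param prefer_file_channels use source derivative channels when present
#'   (default TRUE).
#' @return A [feature_series] in m/s.
#' @export
kin_speed <- function(series, keypoint, prefer_file_channels = TRUE) {
  v <- .derivative_channel(series, keypoint, "velocity", "positions", 1,
                           prefer_file_channels)
  feature_series(.row_norms(v), "speed", keypoint, "m/s", series$framerate)
}

#' Acceleration magnitude of a keypoint
#'
#' `a_j(t) = ||d^2 p_j / dt^2||_2` in m/s^2; second finite difference of
#' position unless the source carried an acceleration channel.
#'
#' @inheritParams kin_speed
#' @return A [feature_series] in m/s^2.
#' @export
kin_acceleration <- function(series, keypoint, prefer_file_channels = TRUE) {
  a <- .derivative_channel(series, keypoint, "acceleration", "positions", 2,
                           prefer_file_channels)
  feature_series(.row_norms(a), "acceleration", keypoint, "m/s^2",
                 series$framerate)
}

#' Angular speed of a keypoint
#'
#' Euclidean norm of the time derivative of the segment's Euler orientation
#' vector, in rad/s. A body rotating one full circle per second has angular
#' speed `2 * pi` rad/s. Orientation channels are unwrapped per axis (jumps
#' larger than pi folded) before differentiation, so a continuous rotation
#' crossing the +/- pi seam does not produce a spurious spike.
#'
#' @inheritParams kin_speed
#' @return A [feature_series] in rad/s.
#' @export
kin_angular_speed <- function(series, keypoint, prefer_file_channels = TRUE) {
  w <- .derivative_channel(series, keypoint, "angular_velocity",
                           "orientations", 1, prefer_file_channels,
                           unwrap = TRUE)
  feature_series(.row_norms(w), "angular_speed", keypoint, "rad/s",
                 series$framerate)
}

#' Angular acceleration of a keypoint
#'
#' Norm of the second time derivative of the Euler orientation vector, in
#' rad/s^2 (orientations unwrapped before differentiation).
#'
#' @inheritParams kin_speed
#' @return A [feature_series] in rad/s^2.
#' @export
kin_angular_acceleration <- function(series, keypoint,
                                     prefer_file_channels = TRUE) {
  w <- .derivative_channel(series, keypoint, "angular_acceleration",
                           "orientations", 2, prefer_file_channels,
                           unwrap = TRUE)
  feature_series(.row_norms(w), "angular_acceleration", keypoint, "rad/s^2",
                 series$framerate)
}

#' Limb contraction
#'
#' Mean Euclidean distance between the head and the four extremity endpoints
#' (right hand, left hand, right toe, left toe), in meters. Contracted poses
#' give short distances, expanded poses long ones; the feature is full-body
#' (keypoint `"ALL"`).
#'
#' @param series a [keypoint_series] containing the head and extremity
#'   keypoints.
#' @return A [feature_series] in m.
#' @export
limb_contraction <- function(series) {
  head <- .kp_positions(series, "Head")
  d <- sapply(.extremity_labels(), function(lab) {
    .row_norms(head - .kp_positions(series, lab))
  })
  feature_series(rowMeans(d), "limb_contraction", "ALL", "m",
                 series$framerate)
}

#' Distance of a keypoint to the center of mass
#'
#' `m_j(t) = ||p_j(t) - mu(t)||_2` in meters, where `mu(t)` is the per-frame
#' center of mass carried by the series.
#'
#' @inheritParams kin_speed
#' @return A [feature_series] in m.
#' @export
com_distance <- function(series, keypoint) {
  p <- .kp_positions(series, keypoint)
  feature_series(.row_norms(p - series$com), "com_distance", keypoint, "m",
                 series$framerate)
}

# Euclidean diameter of a point set: exact (chunked pairwise) up to
# `exact_max` points, bounding-box diagonal beyond that.
.trajectory_extent <- function(p, exact_max = 10000L) {
  p <- as.matrix(p)
  n <- nrow(p)
  if (n > exact_max) {
    r <- apply(p, 2, range)
    return(sqrt(sum((r[2, ] - r[1, ])^2)))
  }
  dmax <- 0
  chunk <- 512L
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    block <- p[i0:i1, , drop = FALSE]
    g2 <- rowSums(p * p)
    b2 <- rowSums(block * block)
    d2 <- outer(b2, g2, "+") - 2 * block %*% t(p)
    dmax <- max(dmax, max(d2))
  }
  sqrt(max(dmax, 0))
}

#' Dimensionless jerk (integral)
#'
#' Duration- and amplitude-normalized integral of squared jerk, a
#' smoothness measure: `lambda = (T^5 / Dp^2) * integral ||d^3 p/dt^3||^2 dt`
#' where `T` is the trajectory duration in seconds and `Dp` the movement
#' extent (the Euclidean diameter of the trajectory point set). Lower values
#' indicate smoother movement; the quantity is invariant to uniform spatial
#' scaling and, for smooth trajectories, stable under resampling.
#'
#' @param series a [keypoint_series].
#' @param trajectory `"com"` (default; the feature is full-body) or a
#'   keypoint label.
#' @return A single nonnegative dimensionless number.
#' @export
dimensionless_jerk <- function(series, trajectory = "com") {
  p <- if (identical(trajectory, "com")) series$com
       else .kp_positions(series, trajectory)
  n <- nrow(p)
  if (n < 4L) stop("dimensionless jerk needs at least 4 frames")
  jerk <- finite_difference(p, 3, series$framerate)
  j2 <- rowSums(jerk * jerk)
  dur <- (n - 1) / series$framerate
  dp <- .trajectory_extent(p)
  integral <- .trapz(seq(0, dur, length.out = n), j2)
  if (dp == 0) {
    if (integral == 0) return(0)
    stop("dimensionless jerk undefined: zero movement extent with nonzero jerk")
  }
  dur^5 / dp^2 * integral
}

# angle between consecutive unit vectors; errors on zero-length segments
.unit_rows <- function(m, what) {
  nrm <- .row_norms(m)
  if (any(nrm < 1e-12))
    stop(sprintf("zero-length %s segment (coincident keypoints)", what))
  m / nrm
}

#' Head tilt with respect to the back
#'
#' Angle `alpha(t)` between the unit vector from the T8 vertebra to the neck
#' and the unit vector from the neck to the head, in radians in `[0, pi]`;
#' zero when the head continues the line of the upper back.
#'
#' @param series a [keypoint_series] containing T8, Neck and Head.
#' @return A [feature_series] in rad.
#' @export
head_angle_back <- function(series) {
  a <- .kp_positions(series, "T8")
  b <- .kp_positions(series, "Neck")
  cc <- .kp_positions(series, "Head")
  uab <- .unit_rows(b - a, "T8-neck")
  ubc <- .unit_rows(cc - b, "neck-head")
  cosang <- pmin(1, pmax(-1, rowSums(uab * ubc)))
  feature_series(acos(cosang), "head_angle_back", "ALL", "rad",
                 series$framerate)
}

#' Head tilt with respect to the vertical
#'
#' Angle `beta(t)` between the neck-to-head unit vector and the global
#' up-axis `(0, 0, 1)`, in radians; zero for an upright head.
#'
#' @inheritParams head_angle_back
#' @return A [feature_series] in rad.
#' @export
head_angle_vertical <- function(series) {
  b <- .kp_positions(series, "Neck")
  cc <- .kp_positions(series, "Head")
  ubc <- .unit_rows(cc - b, "neck-head")
  cosang <- pmin(1, pmax(-1, ubc[, 3]))
  feature_series(acos(cosang), "head_angle_vertical", "ALL", "rad",
                 series$framerate)
}
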