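#' Per-keypoint motion-capture time series
#'
#' The central container of the package: positions (m), orientations
#' (Euler angles, rad), the body's center of mass (m) and foot contacts,
#' sampled at a fixed framerate. The world frame follows the inertial
#' motion-capture convention: x points to magnetic north, y to the west,
#' and z up; time for frame k (1-based storage) is `t = (k - 1) / framerate`
#' seconds.
#'
#' Positions and orientations are stored as 3-dimensional arrays
#' `[frame, keypoint, axis]`; the center of mass as a `[frame, 3]` matrix;
#' foot contacts as a `[frame, 4]` logical matrix (left heel, left toe,
#' right heel, right toe). Optional derivative channels (`velocity`,
#' `acceleration`, `angular_velocity`, `angular_acceleration`), when carried
#' by a source file, have the same shape as `positions` and take precedence
#' over recomputation in the feature extractors unless
#' `prefer_file_channels = FALSE` is requested there.
#'
#' @param positions numeric array `[frames, keypoints, 3]`, meters.
#' @param orientations numeric array `[frames, keypoints, 3]`, Euler angles in
#'   radians, Z (flexion/extension), X (abduction/adduction),
#'   Y (internal/external) convention. Defaults to all-zero.
#' @param com numeric matrix `[frames, 3]`, center of mass in meters. Defaults
#'   to the unweighted keypoint mean.
#' @param framerate sampling rate in Hz, > 0.
#' @param keypoint_labels character vector naming the keypoint dimension; the
#'   full-body configuration must use the 23 canonical labels in order (see
#'   [mocap_keypoint_labels()]).
#' @param foot_contacts logical matrix `[frames, 4]` or NULL.
#' @param velocity,acceleration,angular_velocity,angular_acceleration optional
#'   derivative channels with the shape of `positions`, or NULL.
#'
#' @return An object of class `keypoint_series`.
#' @export
keypoint_series <- function(positions, orientations = NULL, com = NULL,
                            framerate = 240,
                            keypoint_labels = mocap_keypoint_labels(),
                            foot_contacts = NULL,
                            velocity = NULL, acceleration = NULL,
                            angular_velocity = NULL,
                            angular_acceleration = NULL) {
  if (length(dim(positions)) != 3L || dim(positions)[3] != 3L)
    stop("`positions` must be a [frames, keypoints, 3] array")
  n <- dim(positions)[1]
  k <- dim(positions)[2]
  if (length(keypoint_labels) != k)
    stop("length(keypoint_labels) must match dim(positions)[2]")
  if (!is.numeric(framerate) || length(framerate) != 1L || framerate <= 0)
    stop("`framerate` must be a single positive number")
  if (is.null(orientations))
    orientations <- array(0, dim(positions))
  if (!all(dim(orientations) == dim(positions)))
    stop("frame-count mismatch: `orientations` must have the shape of `positions`")
  if (is.null(com))
    com <- apply(positions, c(1, 3), mean)
  com <- as.matrix(com)
  if (nrow(com) != n || ncol(com) != 3L)
    stop("frame-count mismatch: `com` must be a [frames, 3] matrix")
  if (is.null(foot_contacts))
    foot_contacts <- matrix(TRUE, n, 4)
  foot_contacts <- as.matrix(foot_contacts)
  if (nrow(foot_contacts) != n || ncol(foot_contacts) != 4L)
    stop("frame-count mismatch: `foot_contacts` must be [frames, 4]")
  for (nm in c("velocity", "acceleration", "angular_velocity",
               "angular_acceleration")) {
    ch <- get(nm)
    if (!is.null(ch) && !all(dim(ch) == dim(positions)))
      stop(sprintf("frame-count mismatch: `%s` must have the shape of `positions`", nm))
  }
  dimnames(positions) <- list(NULL, keypoint_labels, c("x", "y", "z"))
  dimnames(orientations) <- list(NULL, keypoint_labels, c("x", "y", "z"))
  structure(
    list(keypoint_labels = keypoint_labels,
         positions = positions, orientations = orientations,
         com = com, foot_contacts = foot_contacts,
         framerate = framerate, frame_count = n,
         velocity = velocity, acceleration = acceleration,
         angular_velocity = angular_velocity,
         angular_acceleration = angular_acceleration),
    class = "keypoint_series")
}

#' @export
print.keypoint_series <- function(x, ...) {
  cat(sprintf("<keypoint_series> %d keypoints x %d frames @ %g Hz (%.2f s)\n",
              length(x$keypoint_labels), x$frame_count, x$framerate,
              (x$frame_count - 1) / x$framerate))
  aux <- c("velocity", "acceleration", "angular_velocity",
           "angular_acceleration")
  have <- aux[!vapply(x[aux], is.null, logical(1))]
  if (length(have))
    cat("  auxiliary channels:", paste(have, collapse = ", "), "\n")
  invisible(x)
}

# index of a keypoint label, with a helpful error
.kp_index <- function(series, keypoint) {
  i <- match(keypoint, series$keypoint_labels)
  if (is.na(i))
    stop(sprintf("unknown keypoint %s; valid labels are: %s",
                 dQuote(keypoint),
                 paste(series$keypoint_labels, collapse = ", ")))
  i
}

# positions of one keypoint as an [frames, 3] matrix
.kp_positions <- function(series, keypoint) {
  series$positions[, .kp_index(series, keypoint), , drop = TRUE]
}
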