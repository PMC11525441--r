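#' Resample a keypoint series to another framerate
#'
#' Linear interpolation of positions, center of mass and derivative
#' channels on the common time grid; orientations are unwrapped per axis
#' before interpolation so the Euler seam does not contaminate in-between
#' frames; foot contacts use nearest-frame selection. The first and last
#' frame values are preserved. Upsampling beyond the source framerate is
#' refused unless `force = TRUE` (the data carries no information between
#' source frames).
#'
#' @param series a [keypoint_series].
#' @param target_hz new framerate in Hz, > 0.
#' @param force allow target_hz > source framerate.
#' @return A [keypoint_series] at `target_hz`.
#' @export
resample_series <- function(series, target_hz, force = FALSE) {
  stopifnot(inherits(series, "keypoint_series"), target_hz > 0)
  if (target_hz > series$framerate && !force)
    stop("refusing to upsample beyond the source framerate (use force = TRUE)")
  if (target_hz == series$framerate) return(series)
  n <- series$frame_count
  dur <- (n - 1) / series$framerate
  t_src <- seq(0, dur, length.out = n)
  # a uniform grid spanning exactly [0, dur]; when dur is not a multiple of
  # 1/target_hz the effective rate is nudged to the nearest value that is,
  # so the first and last captured poses are always preserved
  n_out <- max(2L, as.integer(round(dur * target_hz)) + 1L)
  t_out <- seq(0, dur, length.out = n_out)
  target_hz <- (n_out - 1L) / dur
  interp_mat <- function(m) apply(m, 2, function(col)
    stats::approx(t_src, col, xout = t_out)$y)
  interp_arr <- function(arr, unwrap = FALSE) {
    out <- array(NA_real_, c(length(t_out), dim(arr)[2], 3))
    for (j in seq_len(dim(arr)[2])) {
      x <- arr[, j, , drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, ncol = 3)
      if (unwrap) x <- .unwrap_angles(x)
      out[, j, ] <- interp_mat(x)
    }
    out
  }
  nearest <- pmin(n, pmax(1L, round(t_out * series$framerate) + 1L))
  aux <- lapply(c(velocity = "velocity", acceleration = "acceleration",
                  angular_velocity = "angular_velocity",
                  angular_acceleration = "angular_acceleration"),
                function(ch) if (is.null(series[[ch]])) NULL
                             else interp_arr(series[[ch]]))
  keypoint_series(
    positions = interp_arr(series$positions),
    orientations = interp_arr(series$orientations, unwrap = TRUE),
    com = interp_mat(series$com), framerate = target_hz,
    keypoint_labels = series$keypoint_labels,
    foot_contacts = series$foot_contacts[nearest, , drop = FALSE],
    velocity = aux$velocity, acceleration = aux$acceleration,
    angular_velocity = aux$angular_velocity,
    angular_acceleration = aux$angular_acceleration)
}
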