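#' Virtual pinhole camera
#'
#' Stand-in for the render-engine camera used to produce the
#' camera-relative landmark coordinates: a pinhole model with a position,
#' a look-at target, a horizontal field of view and an image aspect ratio.
#' Depth is measured along the optical axis (the render-engine depth-pass
#' convention), not as Euclidean distance to the camera center.
#'
#' @param position camera center, 3-vector in meters.
#' @param target point the camera looks at, 3-vector in meters.
#' @param fov horizontal field of view in radians, in (0, pi).
#' @param aspect image aspect ratio width/height, > 0 (default 16/9).
#' @param up approximate up direction (default world z-up).
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(position = c(4, 0, 1.2), target = c(0, 0, 1.2),
                         fov = 50 * pi / 180, aspect = 16 / 9,
                         up = c(0, 0, 1)) {
  stopifnot(length(position) == 3, length(target) == 3,
            fov > 0, fov < pi, aspect > 0)
  fwd <- target - position
  if (sqrt(sum(fwd^2)) < 1e-12) stop("camera target coincides with position")
  fwd <- fwd / sqrt(sum(fwd^2))
  right <- .cross3(fwd, up)
  if (sqrt(sum(right^2)) < 1e-12)
    stop("camera forward direction is parallel to `up`")
  right <- right / sqrt(sum(right^2))
  upv <- .cross3(right, fwd)
  structure(list(position = as.numeric(position), forward = fwd,
                 right = right, up = upv, fov = fov, aspect = aspect),
            class = "camera_model")
}

#' Camera-relative landmark coordinate series
#'
#' Per-frame, per-landmark screen coordinates: `x` runs 0 (leftmost pixel)
#' to 1 (rightmost), `y` runs 0 (bottom) to 1 (top) of the rendered frame,
#' and `depth` is the distance along the optical axis in meters (non-positive
#' depth flags a landmark behind the camera; such landmarks are kept, not
#' dropped).
#'
#' @param x,y,depth numeric matrices `[frames, landmarks]`.
#' @param landmark_names character vector naming the landmark columns.
#' @param framerate sampling rate in Hz (the conventional rendering rate is
#'   60).
#' @return An object of class `campos_series`.
#' @export
campos_series <- function(x, y, depth, landmark_names, framerate = 60) {
  x <- as.matrix(x); y <- as.matrix(y); depth <- as.matrix(depth)
  if (!all(dim(x) == dim(y)) || !all(dim(x) == dim(depth)))
    stop("x, y and depth must have identical dimensions")
  if (ncol(x) != length(landmark_names))
    stop("landmark_names must match the number of landmark columns")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("campos x/y must be finite")
  stopifnot(framerate > 0)
  structure(list(x = x, y = y, depth = depth,
                 landmark_names = landmark_names, framerate = framerate),
            class = "campos_series")
}

#' @export
print.campos_series <- function(x, ...) {
  cat(sprintf("<campos_series> %d landmarks x %d frames @ %g Hz\n",
              ncol(x$x), nrow(x$x), x$framerate))
  invisible(x)
}

#' Project a keypoint series through a camera
#'
#' Pinhole projection of every keypoint into screen-ratio coordinates, with
#' temporal resampling to `out_hz` by nearest-frame selection (preserving
#' exactly captured poses; the timing error is at most half a source frame).
#'
#' @param series a [keypoint_series].
#' @param camera a [camera_model].
#' @param out_hz output framerate, must not exceed the source framerate.
#' @return A [campos_series].
#' @export
project_campos <- function(series, camera, out_hz = 60) {
  stopifnot(inherits(series, "keypoint_series"),
            inherits(camera, "camera_model"))
  if (out_hz > series$framerate)
    stop("out_hz exceeds the source framerate; resample the source first")
  n <- series$frame_count
  dur <- (n - 1) / series$framerate
  t_out <- seq(0, dur, by = 1 / out_hz)
  pick <- pmin(n, pmax(1L, round(t_out * series$framerate) + 1L))
  k <- length(series$keypoint_labels)
  xm <- matrix(NA_real_, length(pick), k)
  ym <- xm; dm <- xm
  tanh2 <- tan(camera$fov / 2)
  tanv2 <- tanh2 / camera$aspect
  for (j in seq_len(k)) {
    p <- series$positions[pick, j, , drop = TRUE]
    if (is.null(dim(p))) p <- matrix(p, ncol = 3)
    rel <- sweep(p, 2, camera$position)
    dz <- rel %*% camera$forward
    dx <- rel %*% camera$right
    dy <- rel %*% camera$up
    xm[, j] <- 0.5 + dx / (dz * tanh2) / 2
    ym[, j] <- 0.5 + dy / (dz * tanv2) / 2
    dm[, j] <- dz
  }
  bad <- !is.finite(xm) | !is.finite(ym)
  xm[bad] <- 0.5; ym[bad] <- 0.5
  campos_series(xm, ym, dm, series$keypoint_labels, out_hz)
}

#' Write a campos series to JSON
#'
#' Top-level object `{framerate, landmark_names, frames}` where `frames` is
#' a list of per-frame lists of `[x, y, depth]` triplets.
#'
#' @param campos a [campos_series].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_campos <- function(campos, path) {
  frames <- lapply(seq_len(nrow(campos$x)), function(t) {
    lapply(seq_len(ncol(campos$x)), function(j) {
      c(campos$x[t, j], campos$y[t, j], campos$depth[t, j])
    })
  })
  obj <- list(framerate = campos$framerate,
              landmark_names = campos$landmark_names,
              frames = frames)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a campos series from JSON
#'
#' @param path file written by [write_campos()].
#' @return A [campos_series].
#' @export
read_campos <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fr <- obj$frames
  if (is.list(fr)) {
    fr <- aperm(simplify2array(fr), c(3, 1, 2))  # -> frames x landmarks x 3
  }
  if (!(is.array(fr) && length(dim(fr)) == 3L && dim(fr)[3] == 3L))
    stop("unrecognised campos frame layout")
  arr <- fr
  campos_series(arr[, , 1, drop = TRUE], arr[, , 2, drop = TRUE],
                arr[, , 3, drop = TRUE],
                obj$landmark_names, obj$framerate)
}
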