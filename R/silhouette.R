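#' Silhouette clip: a stack of Boolean foreground masks
#'
#' Frames are logical matrices (rows = image rows, top row first; columns =
#' image columns, left first) with TRUE marking the figure's foreground. All
#' frames share one shape; the nominal full-resolution clip is 1080 x 1920
#' at 25 fps, but any shape is accepted.
#'
#' @param frames list of logical matrices of identical shape.
#' @param fps frames per second, > 0 (default 25).
#' @return An object of class `silhouette_clip`.
#' @export
silhouette_clip <- function(frames, fps = 25) {
  stopifnot(is.list(frames), length(frames) >= 1L, fps > 0)
  dims <- dim(frames[[1]])
  for (f in frames) {
    if (!is.logical(f)) stop("silhouette frames must be logical matrices")
    if (!identical(dim(f), dims)) stop("silhouette frames differ in shape")
  }
  structure(list(frames = frames, fps = fps, height = dims[1],
                 width = dims[2]), class = "silhouette_clip")
}

#' @export
print.silhouette_clip <- function(x, ...) {
  cat(sprintf("<silhouette_clip> %d frames of %dx%d @ %g fps\n",
              length(x$frames), x$height, x$width, x$fps))
  invisible(x)
}

#' Silhouette motion masks
#'
#' For each frame `t`, the motion mask is active exactly where some of the
#' previous `delta` frames were foreground and the current frame is not:
#' `Q_delta(t) = (union of f(t-1) ... f(t-delta)) AND NOT f(t)`. It encodes
#' the recently vacated area: all zeros if nothing moves, more active pixels
#' as movement increases. Warm-up frames `t <= delta` use the available
#' history (the first frame has none and yields an empty mask).
#'
#' @param clip a [silhouette_clip].
#' @param delta history span in frames, `>= 1` and shorter than the clip.
#' @return List of logical matrices, one per frame.
#' @export
motion_mask <- function(clip, delta = 5L) {
  stopifnot(inherits(clip, "silhouette_clip"))
  n <- length(clip$frames)
  if (delta < 1L) stop("delta must be >= 1")
  if (delta >= n)
    stop(sprintf("delta (%d) must be smaller than the clip length (%d)",
                 delta, n))
  lapply(seq_len(n), function(t) {
    lo <- max(1L, t - delta)
    if (lo > t - 1L) return(clip$frames[[t]] & FALSE)
    hist <- Reduce(`|`, clip$frames[lo:(t - 1L)])
    hist & !clip$frames[[t]]
  })
}

#' Quantity of motion
#'
#' Per-frame ratio between the number of active pixels in the silhouette
#' motion mask and the number of currently active silhouette pixels:
#' `q(t) = |Q_delta(t)| / |f(t)|`. A full-body movement-activity measure,
#' dimensionless and invariant to uniform spatial rescaling of the masks.
#' Frames with an empty silhouette have no defined ratio: they are returned
#' as `NA` with a warning and excluded from aggregation.
#'
#' @inheritParams motion_mask
#' @return A [feature_series] (keypoint `"ALL"`, dimensionless) whose
#'   conventional aggregations are average, MAD and integral.
#' @export
qom <- function(clip, delta = 5L) {
  masks <- motion_mask(clip, delta)
  active <- vapply(clip$frames, sum, numeric(1))
  moved <- vapply(masks, sum, numeric(1))
  q <- ifelse(active > 0, moved / active, NA_real_)
  if (anyNA(q))
    warning(sprintf("%d empty silhouette frame(s): QoM undefined there",
                    sum(is.na(q))))
  feature_series(q, "qom", "ALL", "dimensionless", clip$fps)
}

#' Foreground statistics of a silhouette clip
#'
#' Per-frame foreground ratio (active pixels / total pixels) and normalized
#' bounding extents of the active area, plus per-clip aggregates. Extents
#' are screen ratios: horizontally 0 = left edge, 1 = right edge; vertically
#' 0 = bottom edge, 1 = top edge (matching the camera-relative coordinate
#' convention). A fully active frame spans (0, 1) on both axes. Empty frames
#' have undefined extents (`NA`) and are flagged.
#'
#' @param clip a [silhouette_clip].
#' @return A list with `per_frame` (data.frame: frame, ratio, x_min, x_max,
#'   y_min, y_max, empty) and `aggregate` (mean ratio and global extents).
#' @export
foreground_stats <- function(clip) {
  stopifnot(inherits(clip, "silhouette_clip"))
  h <- clip$height; w <- clip$width
  per <- lapply(seq_along(clip$frames), function(t) {
    f <- clip$frames[[t]]
    npix <- sum(f)
    if (npix == 0L)
      return(data.frame(frame = t, ratio = 0, x_min = NA_real_,
                        x_max = NA_real_, y_min = NA_real_,
                        y_max = NA_real_, empty = TRUE))
    cols <- range(which(colSums(f) > 0))
    rows <- range(which(rowSums(f) > 0))
    data.frame(frame = t, ratio = npix / (h * w),
               x_min = (cols[1] - 1) / w, x_max = cols[2] / w,
               y_min = (h - rows[2]) / h, y_max = (h - rows[1] + 1) / h,
               empty = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_frame = per,
       aggregate = list(mean_ratio = mean(per$ratio),
                        x_min = suppressWarnings(min(per$x_min, na.rm = TRUE)),
                        x_max = suppressWarnings(max(per$x_max, na.rm = TRUE)),
                        y_min = suppressWarnings(min(per$y_min, na.rm = TRUE)),
                        y_max = suppressWarnings(max(per$y_max, na.rm = TRUE)),
                        n_empty = sum(per$empty)))
}

#' Threshold grayscale frames into Boolean masks
#'
#' Utility for white-on-black silhouette footage: any pixel with luminance
#' above `threshold` (default 0) becomes foreground.
#'
#' @param frames list of numeric matrices (luminance).
#' @param fps frames per second.
#' @param threshold luminance threshold.
#' @return A [silhouette_clip].
#' @export
threshold_silhouette <- function(frames, fps = 25, threshold = 0) {
  silhouette_clip(lapply(frames, function(f) f > threshold), fps = fps)
}

#' Write silhouette frames as plain-text PBM images
#'
#' One P1 (plain portable-bitmap) file per frame, `frame_0001.pbm` etc.:
#' a text-only Boolean image format writable and readable without external
#' codecs.
#'
#' @param clip a [silhouette_clip].
#' @param out_dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_pbm_frames <- function(clip, out_dir) {
  stopifnot(inherits(clip, "silhouette_clip"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(clip$frames))
  for (t in seq_along(clip$frames)) {
    f <- clip$frames[[t]]
    paths[t] <- file.path(out_dir, sprintf("frame_%04d.pbm", t))
    rows <- apply(f * 1L, 1, paste, collapse = " ")
    writeLines(c("P1", sprintf("%d %d", ncol(f), nrow(f)), rows), paths[t])
  }
  writeLines(sprintf("%.12g", clip$fps), file.path(out_dir, "fps.txt"))
  invisible(paths)
}

#' Read silhouette frames from plain-text PBM images
#'
#' @param dir directory written by [write_pbm_frames()].
#' @param fps frames per second; defaults to the `fps.txt` sidecar if
#'   present, else 25.
#' @return A [silhouette_clip].
#' @export
read_pbm_frames <- function(dir, fps = NULL) {
  files <- sort(list.files(dir, pattern = "\\.pbm$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no .pbm frames under %s", dir))
  if (is.null(fps)) {
    side <- file.path(dir, "fps.txt")
    fps <- if (file.exists(side)) as.numeric(readLines(side)[1]) else 25
  }
  frames <- lapply(files, function(p) {
    lines <- readLines(p)
    lines <- lines[!grepl("^#", lines)]
    if (lines[1] != "P1") stop(sprintf("%s is not a plain PBM (P1) file", p))
    dims <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
    vals <- as.integer(unlist(strsplit(trimws(lines[-(1:2)]), "\\s+")))
    matrix(vals == 1L, dims[2], dims[1], byrow = TRUE)
  })
  silhouette_clip(frames, fps = fps)
}
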