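# Tabular CSV export/import of a keypoint series: one file per quantity,
# comma-separated with '.' decimal, header row naming keypoint and axis
# ("Pelvis_x", ...), one data row per frame. Derivative channels absent from
# the source are computed by finite differences so the file set is always
# complete.

.csv_quantities <- c("position", "orientation", "velocity",
                     "angular_velocity", "acceleration",
                     "angular_acceleration", "center_of_mass",
                     "foot_contacts")

.wide_frame <- function(arr, labels) {
  k <- length(labels)
  out <- matrix(NA_real_, dim(arr)[1], 3 * k)
  cols <- character(3 * k)
  for (j in seq_len(k)) for (ax in 1:3) {
    out[, (j - 1) * 3 + ax] <- arr[, j, ax]
    cols[(j - 1) * 3 + ax] <- paste0(gsub(" ", "_", labels[j]),
                                     "_", c("x", "y", "z")[ax])
  }
  colnames(out) <- cols
  as.data.frame(out)
}

#' Write a keypoint series as a set of CSV files
#'
#' Emits eight files into `out_dir`: position, orientation, velocity,
#' angular_velocity, acceleration, angular_acceleration, center_of_mass and
#' foot_contacts. Derivative channels carried by the source are written as
#' is; missing ones are computed by [finite_difference()] (orientations
#' unwrapped first). A `framerate.txt` sidecar records the sampling rate.
#'
#' @param series a [keypoint_series].
#' @param out_dir output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_series_csv <- function(series, out_dir) {
  stopifnot(inherits(series, "keypoint_series"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop(sprintf("cannot create %s", out_dir))
  lab <- series$keypoint_labels
  fr <- series$framerate
  deriv <- function(ch, base, order, unwrap = FALSE) {
    if (!is.null(series[[ch]])) return(series[[ch]])
    arr <- series[[base]]
    out <- array(NA_real_, dim(arr))
    for (j in seq_along(lab)) {
      x <- arr[, j, , drop = TRUE]
      if (is.null(dim(x))) x <- matrix(x, ncol = 3)
      if (unwrap) x <- .unwrap_angles(x)
      out[, j, ] <- finite_difference(x, order, fr)
    }
    out
  }
  tables <- list(
    position = .wide_frame(series$positions, lab),
    orientation = .wide_frame(series$orientations, lab),
    velocity = .wide_frame(deriv("velocity", "positions", 1), lab),
    angular_velocity = .wide_frame(
      deriv("angular_velocity", "orientations", 1, unwrap = TRUE), lab),
    acceleration = .wide_frame(deriv("acceleration", "positions", 2), lab),
    angular_acceleration = .wide_frame(
      deriv("angular_acceleration", "orientations", 2, unwrap = TRUE), lab),
    center_of_mass = stats::setNames(as.data.frame(series$com),
                                     c("com_x", "com_y", "com_z")),
    foot_contacts = stats::setNames(
      as.data.frame(series$foot_contacts * 1L),
      c("left_heel", "left_toe", "right_heel", "right_toe")))
  paths <- file.path(out_dir, paste0(.csv_quantities, ".csv"))
  for (i in seq_along(tables))
    utils::write.csv(format(tables[[i]], digits = 15, trim = TRUE,
                            scientific = FALSE),
                     paths[i], row.names = FALSE, quote = FALSE)
  writeLines(sprintf("%.12g", fr), file.path(out_dir, "framerate.txt"))
  invisible(paths)
}

#' Read a keypoint series from a CSV directory
#'
#' Inverse of [write_series_csv()]: reconstructs the series (including the
#' derivative channels as auxiliary channels) from the file set.
#'
#' @param dir directory written by [write_series_csv()].
#' @return A [keypoint_series].
#' @export
read_series_csv <- function(dir) {
  need <- file.path(dir, paste0(.csv_quantities, ".csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop(sprintf("missing CSV files: %s", paste(missing, collapse = ", ")))
  fr <- as.numeric(readLines(file.path(dir, "framerate.txt"))[1])
  rd <- function(q) utils::read.csv(file.path(dir, paste0(q, ".csv")))
  to_arr <- function(df) {
    cols <- colnames(df)
    labels <- unique(sub("_[xyz]$", "", cols))
    arr <- array(NA_real_, c(nrow(df), length(labels), 3))
    for (j in seq_along(labels)) for (ax in 1:3)
      arr[, j, ax] <- df[[paste0(labels[j], "_", c("x", "y", "z")[ax])]]
    list(arr = arr, labels = gsub("_", " ", labels))
  }
  pos <- to_arr(rd("position"))
  ori <- to_arr(rd("orientation"))
  keypoint_series(
    positions = pos$arr, orientations = ori$arr,
    com = as.matrix(rd("center_of_mass")), framerate = fr,
    keypoint_labels = pos$labels,
    foot_contacts = as.matrix(rd("foot_contacts")) != 0,
    velocity = to_arr(rd("velocity"))$arr,
    acceleration = to_arr(rd("acceleration"))$arr,
    angular_velocity = to_arr(rd("angular_velocity"))$arr,
    angular_acceleration = to_arr(rd("angular_acceleration"))$arr)
}
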