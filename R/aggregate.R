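#' Summarise a feature series into a scalar statistic
#'
#' The three time aggregations used throughout the package, plus the time
#' integral used by the quantity of motion:
#' * `average`: mean over frames;
#' * `mad`: median absolute deviation, `median(|median(K) - K(t)|)` with no
#'   consistency constant;
#' * `max`: maximum over frames;
#' * `integral`: trapezoidal integral over time in seconds (requires the
#'   feature's framerate).
#'
#' `NA` frames (e.g. undefined quantity of motion on empty silhouette
#' frames) are excluded.
#'
#' @param feature a [feature_series] or plain numeric vector.
#' @param statistic one of `"average"`, `"mad"`, `"max"`, `"integral"`.
#' @param framerate required when `feature` is a bare vector and
#'   `statistic = "integral"`.
#' @return A single number.
#' @export
#' @examples
#' aggregate_feature(c(1, 2, 3, 4, 5), "mad")  # 1
aggregate_feature <- function(feature,
                              statistic = c("average", "mad", "max",
                                            "integral"),
                              framerate = NULL) {
  statistic <- match.arg(statistic)
  if (inherits(feature, "feature_series")) {
    framerate <- feature$framerate
    values <- feature$values
  } else {
    values <- as.numeric(feature)
  }
  values <- values[!is.na(values)]
  if (!length(values)) stop("cannot aggregate an empty feature series")
  switch(statistic,
    average = mean(values),
    mad = .mad_plain(values),
    max = max(values),
    integral = {
      if (is.null(framerate) || is.na(framerate))
        stop("integral aggregation needs a framerate")
      .trapz(seq(0, by = 1 / framerate, length.out = length(values)), values)
    })
}

# one summary-table row
.summary_row <- function(sequence, emotion, feature, statistic, keypoint,
                         value, units) {
  data.frame(sequence = sequence, emotion = emotion, feature = feature,
             statistic = statistic, keypoint = keypoint, value = value,
             units = units, stringsAsFactors = FALSE)
}

#' Extract all kinematic summary statistics for one sequence
#'
#' Runs the full feature inventory on one recording and returns the
#' long-format summary table. With all three modalities present the table
#' contains exactly 32 distinct (feature, statistic) kinds:
#' average/MAD/max for speed, acceleration, angular speed and angular
#' acceleration (12); average/MAD for limb contraction, center-of-mass
#' distance and the two head angles (8); average/MAD/integral for the
#' quantity of motion (3); the dimensionless jerk (1); and
#' average/MAD/global/union for the 3D and 2D convex hulls (8).
#'
#' Per-joint kinds (speed, acceleration, angular speed, angular
#' acceleration, center-of-mass distance) carry one row per keypoint plus an
#' `ALL` row holding the cross-keypoint mean of the per-keypoint statistics;
#' full-body kinds carry a single `ALL` row. If `campos` or `clip` is
#' missing, the dependent kinds (2D hull; quantity of motion) are omitted
#' with a warning and everything else is still computed.
#'
#' @param series a [keypoint_series].
#' @param campos a [campos_series] for the same sequence, or NULL.
#' @param clip a [silhouette_clip] for the same sequence, or NULL.
#' @param sequence,emotion identifiers copied into every row.
#' @param delta history span in frames for the silhouette motion mask.
#' @param voxel voxel resolution (m) for the 3D hull union.
#' @param jerk_trajectory `"com"` or a keypoint label.
#' @param prefer_file_channels use source derivative channels when present.
#' @return A data.frame with columns sequence, emotion, feature, statistic,
#'   keypoint, value, units.
#' @export
extract_features <- function(series, campos = NULL, clip = NULL,
                             sequence = "seq", emotion = "unspecified",
                             delta = 5L, voxel = 0.01,
                             jerk_trajectory = "com",
                             prefer_file_channels = TRUE) {
  stopifnot(inherits(series, "keypoint_series"))
  rows <- list()
  add <- function(feature, statistic, keypoint, value, units)
    rows[[length(rows) + 1L]] <<- .summary_row(sequence, emotion, feature,
                                               statistic, keypoint, value,
                                               units)
  per_joint <- list(
    speed = function(kp) kin_speed(series, kp, prefer_file_channels),
    acceleration = function(kp) kin_acceleration(series, kp,
                                                 prefer_file_channels),
    angular_speed = function(kp) kin_angular_speed(series, kp,
                                                   prefer_file_channels),
    angular_acceleration = function(kp)
      kin_angular_acceleration(series, kp, prefer_file_channels),
    com_distance = function(kp) com_distance(series, kp))
  stats_for <- list(speed = c("average", "mad", "max"),
                    acceleration = c("average", "mad", "max"),
                    angular_speed = c("average", "mad", "max"),
                    angular_acceleration = c("average", "mad", "max"),
                    com_distance = c("average", "mad"))
  for (feat in names(per_joint)) {
    fs_list <- lapply(series$keypoint_labels, per_joint[[feat]])
    units <- fs_list[[1]]$units
    for (st in stats_for[[feat]]) {
      vals <- vapply(fs_list, aggregate_feature, numeric(1), statistic = st)
      for (i in seq_along(fs_list))
        add(feat, st, series$keypoint_labels[i], vals[i], units)
      add(feat, st, "ALL", mean(vals), units)
    }
  }
  for (fs in list(limb_contraction(series), head_angle_back(series),
                  head_angle_vertical(series))) {
    for (st in c("average", "mad"))
      add(fs$name, st, "ALL", aggregate_feature(fs, st), fs$units)
  }
  add("dimensionless_jerk", "value", "ALL",
      dimensionless_jerk(series, jerk_trajectory), "dimensionless")
  h3 <- convex_hull_3d(series, "per-frame")
  for (st in c("average", "mad"))
    add("convex_hull_3d", st, "ALL", aggregate_feature(h3, st), "m^3")
  add("convex_hull_3d", "global", "ALL",
      convex_hull_3d(series, "global"), "m^3")
  add("convex_hull_3d", "union", "ALL",
      convex_hull_3d(series, "union", voxel = voxel), "m^3")
  if (is.null(campos)) {
    warning("no campos input: 2D convex hull statistics omitted")
  } else {
    h2 <- convex_hull_2d(campos, "per-frame")
    for (st in c("average", "mad"))
      add("convex_hull_2d", st, "ALL", aggregate_feature(h2, st),
          "screen-ratio^2")
    add("convex_hull_2d", "global", "ALL",
        convex_hull_2d(campos, "global"), "screen-ratio^2")
    add("convex_hull_2d", "union", "ALL",
        convex_hull_2d(campos, "union"), "screen-ratio^2")
  }
  if (is.null(clip)) {
    warning("no silhouette input: quantity-of-motion statistics omitted")
  } else {
    q <- qom(clip, delta = delta)
    for (st in c("average", "mad", "integral"))
      add("qom", st, "ALL", aggregate_feature(q, st), "dimensionless")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Count distinct (feature, statistic) kinds in a summary table
#'
#' Convenience check of the statistic inventory: a full extraction yields 32.
#'
#' @param summary a data.frame from [extract_features()].
#' @return Integer.
#' @export
count_statistic_kinds <- function(summary) {
  nrow(unique(summary[, c("feature", "statistic")]))
}
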