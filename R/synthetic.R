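# Synthetic emotion-modulated choreography.
#
# The generator emulates the pilot-dataset design this package is built to
# analyse: short arm-dominant dance phrases on a fixed 23-keypoint skeleton,
# repeated with different emotional intentions. Emotion enters through five
# interpretable dials encoding the directions the movement-emotion
# literature agrees on: overall tempo (anger/joy fast, sadness/fear slow),
# limb expansion (joy expanded, fear/sadness contracted), movement jitter
# (inverse smoothness; anger/fear shaky), a downward head-tilt bias
# (sadness), and a pause fraction (movement activity). Poses are built by
# forward kinematics on fixed bone vectors, so bone lengths are preserved
# exactly; the arm phase advances as a time-warp of a periodic keyframe
# curve, which makes the mean extracted speed proportional to the speed
# scale regardless of the pause pattern.

#' Default emotion profiles
#'
#' One row per emotion with the generator's five dials: `speed`
#' (tempo multiplier), `expansion` (limb-extension multiplier), `jitter`
#' (positional noise amplitude at the hands, meters), `head_tilt`
#' (downward head pitch bias, radians) and `pause` (fraction of the phrase
#' spent in holds, 0-1). Values are the package's fixed stated world; the
#' qualitative directions follow the movement-emotion literature and the
#' numbers are documented in the methods vignette.
#'
#' @return data.frame with columns emotion, speed, expansion, jitter,
#'   head_tilt, pause.
#' @export
emotion_profiles <- function() {
  data.frame(
    emotion = c("neutrality", "joy", "contentment", "sadness", "fear",
                "anger"),
    speed = c(1.00, 1.50, 0.80, 0.55, 0.65, 1.80),
    expansion = c(1.00, 1.20, 1.05, 0.80, 0.75, 1.15),
    jitter = c(0.0010, 0.0015, 0.0008, 0.0010, 0.0030, 0.0040),
    head_tilt = c(0.00, -0.10, 0.00, 0.40, 0.10, 0.00),
    pause = c(0.10, 0.05, 0.15, 0.30, 0.35, 0.10),
    stringsAsFactors = FALSE)
}

# order in which the emotion takes of one sequence are performed
.take_order <- function() {
  c("neutrality", "joy", "contentment", "sadness", "fear", "anger")
}

.profile_for <- function(emotion) {
  profs <- emotion_profiles()
  row <- profs[profs$emotion == emotion, ]
  if (!nrow(row)) stop(sprintf("unknown emotion %s", dQuote(emotion)))
  as.list(row)
}

# rest-pose constants (meters) ------------------------------------------

.rest_pose <- function() {
  list(
    pelvis = c(0, 0, 0.96),
    spine_up = c(0.10, 0.10, 0.10, 0.12, 0.12),   # L5 L3 T12 T8 Neck
    head_len = 0.16,
    shoulder_off = 0.075,   # T8 -> shoulder lateral offset (plus 0.08 up)
    gh_off = 0.135,         # shoulder -> glenohumeral lateral offset
    upper_arm = 0.28, forearm = 0.26,
    hip_off = c(0, 0.09, 0.04),  # pelvis -> hip (lateral, down)
    upper_leg = 0.42, lower_leg = 0.42,
    toe_off = c(0.16, 0, -0.07))
}

# smooth monotone time warp with pauses: maps [0,1] to [0,1], derivative
# 1 - pause * cos(2*pi*holds*tau) >= 0
.time_warp <- function(tau, pause, holds = 4L) {
  tau - pause * sin(2 * pi * holds * tau) / (2 * pi * holds)
}

# unit-variance noise band-limited at ~4 Hz in physical time (moving
# average over framerate/4 frames, rescaled), so jitter statistics do not
# depend on the sampling rate
.smooth_noise <- function(n, framerate) {
  win <- max(1L, round(framerate / 4))
  x <- stats::rnorm(n + 2L * win)
  x <- stats::filter(x, rep(1 / win, win), sides = 2)
  x <- x[!is.na(x)][seq_len(n)]
  s <- stats::sd(x)
  if (is.na(s) || s == 0) rep(0, n) else x / s
}

#' Generate one synthetic choreography take
#'
#' Deterministic given `(sequence_id, profile, seed)`. Produces a full-body
#' 23-keypoint series: arm keypoints follow smooth periodic keyframe curves
#' time-warped by the profile's speed scale, radially modulated by its
#' expansion scale and perturbed by its jitter amplitude; the head is
#' pitched by the head-tilt bias; legs are near-static; the center of mass
#' is a fixed-weight average of the keypoints.
#'
#' @param sequence_id integer 1..9 selecting the phrase variant.
#' @param profile one row of [emotion_profiles()] (as list or data.frame
#'   row), or an emotion name.
#' @param duration phrase length in seconds (default 6, the nominal phrase
#'   of eight counts).
#' @param framerate sampling rate in Hz (default 240, the capture rate).
#' @param seed integer seed for the jitter noise.
#' @return A [keypoint_series] with 23 keypoints.
#' @export
generate_choreography <- function(sequence_id, profile = "neutrality",
                                  duration = 6, framerate = 240, seed = 1L) {
  if (!sequence_id %in% 1:9)
    stop(sprintf("unknown sequence id %s (valid: 1..9)", sequence_id))
  stopifnot(duration > 0, framerate > 0)
  if (is.character(profile)) profile <- .profile_for(profile)
  profile <- as.list(profile)
  for (f in c("speed", "expansion", "jitter", "head_tilt", "pause"))
    if (is.null(profile[[f]]))
      stop(sprintf("profile lacks field %s", dQuote(f)))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed((as.integer(seed) * 97L + as.integer(sequence_id) * 131L) %%
             2147483629L)

  n <- max(4L, as.integer(round(duration * framerate)) + 1L)
  tau <- seq(0, 1, length.out = n)
  rp <- .rest_pose()
  labels <- mocap_keypoint_labels()
  pos <- array(NA_real_, c(n, 23L, 3L))
  ori <- array(0, c(n, 23L, 3L))

  # per-sequence phrase constants (deterministic in the id)
  cycles <- 1L + (sequence_id - 1L) %% 3L
  ph0 <- (sequence_id - 1L) * pi / 4.5
  phase <- 2 * pi * cycles * profile$speed *
    .time_warp(tau, min(1, max(0, profile$pause)))  + ph0

  # torso sway and (sequences 7-9) a lateral step
  sway_x <- 0.015 * sin(phase * 0.5)
  sway_y <- 0.02 * sin(phase * 0.35 + 1)
  if (sequence_id >= 7L) sway_y <- sway_y + 0.10 * sin(pi * tau)
  root <- cbind(sway_x, sway_y, rp$pelvis[3] + 0.005 * sin(phase * 0.7))

  set_kp <- function(label, xyz) pos[, match(label, labels), ] <<- xyz
  kp_of <- function(label) pos[, match(label, labels), , drop = TRUE]

  set_kp("Pelvis", root)
  z <- root
  spine_labels <- c("L5", "L3", "T12", "T8", "Neck")
  for (i in seq_along(spine_labels)) {
    z <- z + rep(c(0, 0, rp$spine_up[i]), each = n)  # upright trunk
    set_kp(spine_labels[i], z)
  }
  neck <- kp_of("Neck")
  # head pitched forward (toward +x, the facing direction) by the tilt bias
  gamma <- profile$head_tilt + 0.06 * sin(phase + 0.4)
  head_dir <- cbind(sin(gamma), 0 * gamma, cos(gamma))
  set_kp("Head", neck + rp$head_len * head_dir)
  ori[, match("Head", labels), 2] <- gamma

  t8 <- kp_of("T8")
  ext <- min(1, max(0.1, 0.55 + 0.9 * (profile$expansion - 1)))
  jit_ang <- profile$jitter / (rp$upper_arm + rp$forearm)
  for (side in c(-1, 1)) {   # -1 = right (east, -y), +1 = left
    side_lab <- if (side < 0) "Right" else "Left"
    shoulder <- t8 + rep(c(0, side * rp$shoulder_off, 0.08), each = n)
    set_kp(paste(side_lab, "shoulder"), shoulder)
    gh <- shoulder + rep(c(0, side * rp$gh_off, -0.01), each = n)
    set_kp(paste(side_lab, "upper arm"), gh)
    ph_side <- if (side < 0) 0 else pi / 2 * (1 + (sequence_id %% 2))
    el <- (0.55 + 0.45 * sin(phase + ph_side)) *
      (0.9 + 0.35 * (profile$expansion - 1))
    el <- pmin(pmax(el + jit_ang * .smooth_noise(n, framerate), 0.02), 1.45)
    psi <- 0.35 + 0.4 * sin(0.5 * phase + ph_side + 0.7) +
      jit_ang * .smooth_noise(n, framerate)
    u <- cbind(sin(el) * sin(psi), side * sin(el) * cos(psi), -cos(el))
    elbow <- gh + rp$upper_arm * u
    set_kp(paste(side_lab, "forearm"), elbow)
    bend <- pmax(0.05, (1 - ext) * 2.1 + 0.25 * sin(2 * phase + ph_side) +
                   jit_ang * .smooth_noise(n, framerate))
    # bend the forearm about an axis perpendicular to the arm, toward the
    # front-up halfspace
    axis_ref <- cbind(rep(1, n), 0.2 * side, rep(0.35, n))
    ax <- cbind(u[, 2] * axis_ref[, 3] - u[, 3] * axis_ref[, 2],
                u[, 3] * axis_ref[, 1] - u[, 1] * axis_ref[, 3],
                u[, 1] * axis_ref[, 2] - u[, 2] * axis_ref[, 1])
    ax <- ax / pmax(sqrt(rowSums(ax^2)), 1e-9)
    axu <- cbind(ax[, 2] * u[, 3] - ax[, 3] * u[, 2],
                 ax[, 3] * u[, 1] - ax[, 1] * u[, 3],
                 ax[, 1] * u[, 2] - ax[, 2] * u[, 1])
    v <- u * cos(bend) + axu * sin(bend)
    set_kp(paste(side_lab, "hand"), elbow + rp$forearm * v)
    iu <- match(paste(side_lab, "upper arm"), labels)
    ifo <- match(paste(side_lab, "forearm"), labels)
    ih <- match(paste(side_lab, "hand"), labels)
    ori[, iu, ] <- cbind(el, psi, 0 * el)
    ori[, ifo, ] <- cbind(el + bend * 0.5, psi, bend)
    ori[, ih, ] <- cbind(el + bend * 0.5, psi, bend)
  }

  pelvis <- kp_of("Pelvis")
  knee_osc <- 0.02 * sin(phase * 0.5)
  for (side in c(-1, 1)) {
    side_lab <- if (side < 0) "Right" else "Left"
    hip <- pelvis + rep(c(0, side * rp$hip_off[2], -rp$hip_off[3]), each = n)
    set_kp(paste(side_lab, "upper leg"), hip)
    bendk <- pmax(0, 0.04 + knee_osc)
    leg_dir <- cbind(sin(bendk), 0 * bendk, -cos(bendk))
    knee <- hip + rp$upper_leg * leg_dir
    set_kp(paste(side_lab, "lower leg"), knee)
    shin_dir <- cbind(-sin(bendk), 0 * bendk, -cos(bendk))
    ankle <- knee + rp$lower_leg * shin_dir
    set_kp(paste(side_lab, "foot"), ankle)
    set_kp(paste(side_lab, "toe"), ankle + rep(rp$toe_off, each = n))
    ori[, match(paste(side_lab, "upper leg"), labels), 1] <- bendk
    ori[, match(paste(side_lab, "lower leg"), labels), 1] <- -bendk
  }

  # torso orientations: gentle sway, so angular features are nonzero but
  # small for the trunk
  for (lb in c("Pelvis", "L5", "L3", "T12", "T8", "Neck"))
    ori[, match(lb, labels), 3] <- 0.05 * sin(phase * 0.35 + 1)

  # fixed anthropometric-style keypoint weights for the center of mass
  w <- c(0.14, 0.09, 0.09, 0.09, 0.08, 0.03, 0.07,
         0.015, 0.027, 0.016, 0.006, 0.015, 0.027, 0.016, 0.006,
         0.10, 0.0465, 0.0145, 0.002, 0.10, 0.0465, 0.0145, 0.002)
  w <- w / sum(w)
  com <- apply(pos, c(1, 3), function(v) sum(v * w))

  fc <- matrix(TRUE, n, 4)
  if (sequence_id >= 7L) {
    mid <- tau > 0.35 & tau < 0.65
    fc[mid, 3:4] <- FALSE   # right foot lifts during the side step
  }
  keypoint_series(positions = pos, orientations = ori, com = com,
                  framerate = framerate, keypoint_labels = labels,
                  foot_contacts = fc)
}

#' Render a silhouette clip from a keypoint series
#'
#' Projects the skeleton through a pinhole camera and rasterizes each bone
#' as a filled capsule (head and torso thicker than limbs), producing the
#' Boolean mask stack the silhouette features consume. Deterministic.
#'
#' @param series a [keypoint_series].
#' @param camera a [camera_model].
#' @param fps output frames per second (default 25; must not exceed the
#'   series framerate).
#' @param size image size as c(height, width) in pixels (default the
#'   nominal 1080 x 1920; tests use far smaller rasters).
#' @return A [silhouette_clip].
#' @export
render_silhouette <- function(series, camera = camera_model(), fps = 25,
                              size = c(1080, 1920)) {
  stopifnot(inherits(series, "keypoint_series"))
  cp <- project_campos(series, camera, out_hz = min(fps, series$framerate))
  h <- size[1]; w <- size[2]
  edges <- .skeleton_edges()
  # capsule radius per bone (meters), keyed by the child keypoint
  radius <- c("L5" = 0.11, "L3" = 0.11, "T12" = 0.11, "T8" = 0.11,
              "Neck" = 0.05, "Head" = 0.09,
              "Right shoulder" = 0.05, "Right upper arm" = 0.045,
              "Right forearm" = 0.04, "Right hand" = 0.04,
              "Left shoulder" = 0.05, "Left upper arm" = 0.045,
              "Left forearm" = 0.04, "Left hand" = 0.04,
              "Right upper leg" = 0.07, "Right lower leg" = 0.06,
              "Right foot" = 0.05, "Right toe" = 0.04,
              "Left upper leg" = 0.07, "Left lower leg" = 0.06,
              "Left foot" = 0.05, "Left toe" = 0.04)
  labels <- series$keypoint_labels
  tanh2 <- tan(camera$fov / 2)
  n <- nrow(cp$x)
  off_frame <- 0L
  frames <- lapply(seq_len(n), function(t) {
    mask <- matrix(FALSE, h, w)
    px <- cp$x[t, ] * w
    py <- (1 - cp$y[t, ]) * h
    if (all(px < 0 | px > w | py < 0 | py > h)) off_frame <<- off_frame + 1L
    for (e in seq_len(nrow(edges))) {
      ic <- edges[e, 1]; ip <- edges[e, 2]
      dz <- (cp$depth[t, ic] + cp$depth[t, ip]) / 2
      if (dz <= 0) next
      r <- radius[[labels[ic]]] / (2 * dz * tanh2) * w
      x1 <- px[ip]; y1 <- py[ip]; x2 <- px[ic]; y2 <- py[ic]
      c0 <- max(1L, floor(min(x1, x2) - r)); c1 <- min(w, ceiling(max(x1, x2) + r))
      r0 <- max(1L, floor(min(y1, y2) - r)); r1 <- min(h, ceiling(max(y1, y2) + r))
      if (c0 > c1 || r0 > r1) next
      cols <- c0:c1; rows <- r0:r1
      cx <- matrix(cols - 0.5, length(rows), length(cols), byrow = TRUE)
      cy <- matrix(rows - 0.5, length(rows), length(cols))
      ddx <- x2 - x1; ddy <- y2 - y1
      len2 <- ddx^2 + ddy^2
      tt <- if (len2 < 1e-12) 0 else
        pmin(1, pmax(0, ((cx - x1) * ddx + (cy - y1) * ddy) / len2))
      d2 <- (cx - (x1 + tt * ddx))^2 + (cy - (y1 + tt * ddy))^2
      mask[rows, cols] <- mask[rows, cols] | (d2 <= r^2)
    }
    mask
  })
  if (off_frame > 0L)
    warning(sprintf("figure fully outside the frame in %d frame(s)",
                    off_frame))
  silhouette_clip(frames, fps = fps)
}

#' Build a synthetic stimulus dataset
#'
#' Reproduces the pilot-dataset design: `n_sequences` phrases, each
#' performed once per emotion in the fixed take order (neutrality, joy,
#' contentment, sadness, fear, anger) plus one explanation take (a neutral
#' walk-through), i.e. 9 x 6 = 54 emotional entries and 63 total entries at
#' the defaults. Per entry it writes the MVNX-style XML, the CSV file set,
#' the camera-relative JSON and the silhouette PBM frames, plus a
#' `manifest.json` recording ids, labels, paths and seeds.
#'
#' @param out_dir output directory; must not already contain files unless
#'   `force = TRUE`.
#' @param seed master seed; per-entry seeds are derived from it and recorded.
#' @param n_sequences number of phrases (default 9).
#' @param duration,framerate mocap parameters passed to
#'   [generate_choreography()] (defaults 6 s, 240 Hz).
#' @param sil_fps,sil_size silhouette rendering parameters (defaults 25 fps,
#'   1080 x 1920; use smaller rasters for quick builds).
#' @param campos_hz camera-relative series rate (default 60).
#' @param camera a [camera_model].
#' @param modalities subset of c("mvnx", "csv", "campos", "silhouette") to
#'   write (default all).
#' @param force overwrite a non-empty `out_dir`.
#' @return The manifest as a data.frame, invisibly; also written as JSON.
#' @export
build_dataset <- function(out_dir, seed = 7L, n_sequences = 9L,
                          duration = 6, framerate = 240,
                          sil_fps = 25, sil_size = c(1080, 1920),
                          campos_hz = 60, camera = camera_model(),
                          modalities = c("mvnx", "csv", "campos",
                                         "silhouette"),
                          force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) && !force)
    stop(sprintf("%s is not empty; use force = TRUE to overwrite", out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  modalities <- match.arg(modalities, several.ok = TRUE)
  takes <- c(.take_order(), "explanation")
  rows <- list()
  for (sid in seq_len(n_sequences)) {
    for (ti in seq_along(takes)) {
      take <- takes[ti]
      entry_seed <- (as.integer(seed) * 1009L + sid * 101L + ti * 17L) %%
        2147483629L
      prof <- .profile_for(if (take == "explanation") "neutrality" else take)
      series <- generate_choreography(sid, prof, duration = duration,
                                      framerate = framerate,
                                      seed = entry_seed)
      stem <- sprintf("seq%d_%s", sid, take)
      entry_dir <- file.path(out_dir, stem)
      dir.create(entry_dir, showWarnings = FALSE)
      paths <- list(mvnx = NA_character_, csv = NA_character_,
                    campos = NA_character_, silhouette = NA_character_)
      if ("mvnx" %in% modalities) {
        paths$mvnx <- file.path(entry_dir, paste0(stem, ".mvnx"))
        write_mvnx(series, paths$mvnx)
      }
      if ("csv" %in% modalities) {
        paths$csv <- file.path(entry_dir, "csv")
        write_series_csv(series, paths$csv)
      }
      if ("campos" %in% modalities) {
        paths$campos <- file.path(entry_dir, paste0(stem, "_campos.json"))
        write_campos(project_campos(series, camera,
                                    min(campos_hz, framerate)),
                     paths$campos)
      }
      if ("silhouette" %in% modalities) {
        paths$silhouette <- file.path(entry_dir, "silhouette")
        clip <- render_silhouette(series, camera,
                                  fps = min(sil_fps, framerate),
                                  size = sil_size)
        write_pbm_frames(clip, paths$silhouette)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = sid, take = take,
        emotional = take != "explanation", seed = entry_seed,
        mvnx = paths$mvnx, csv = paths$csv, campos = paths$campos,
        silhouette = paths$silhouette, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(list(master_seed = as.integer(seed),
                            duration = duration, framerate = framerate,
                            sil_fps = sil_fps, sil_size = sil_size,
                            entries = manifest),
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
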