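# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no binary fixtures.

# single-keypoint series from an [n, 3] position matrix
mk_series1 <- function(p, framerate, com = NULL, orientations = NULL) {
  p <- as.matrix(p)
  arr <- array(0, c(nrow(p), 1, 3))
  arr[, 1, ] <- p
  oarr <- NULL
  if (!is.null(orientations)) {
    oarr <- array(0, c(nrow(p), 1, 3))
    oarr[, 1, ] <- as.matrix(orientations)
  }
  keypoint_series(arr, orientations = oarr, com = com,
                  framerate = framerate, keypoint_labels = "Pelvis")
}

# full-body series with all 23 keypoints at given static positions
mk_static_body <- function(pos23, n = 5, framerate = 60) {
  arr <- array(0, c(n, 23, 3))
  for (t in seq_len(n)) arr[t, , ] <- pos23
  keypoint_series(arr, framerate = framerate)
}

# a small but fully dynamic full-body fixture
mk_fixture_series <- function(seed = 3, duration = 1, framerate = 60,
                              sequence_id = 1, emotion = "neutrality") {
  generate_choreography(sequence_id, emotion, duration = duration,
                        framerate = framerate, seed = seed)
}

# random rotation matrix (deterministic given seed)
random_rotation <- function(seed) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m)) * sign(det(qr.Q(qr(m))))
}

rotate_series <- function(series, R) {
  rot <- series
  for (j in seq_along(series$keypoint_labels))
    rot$positions[, j, ] <- series$positions[, j, ] %*% t(R)
  rot$com <- series$com %*% t(R)
  keypoint_series(rot$positions, series$orientations, rot$com,
                  series$framerate, series$keypoint_labels,
                  series$foot_contacts)
}

translate_series <- function(series, v) {
  tr <- series
  for (j in seq_along(series$keypoint_labels))
    tr$positions[, j, ] <- sweep(series$positions[, j, ], 2, v, "+")
  tr$com <- sweep(series$com, 2, v, "+")
  keypoint_series(tr$positions, series$orientations, tr$com,
                  series$framerate, series$keypoint_labels,
                  series$foot_contacts)
}

reverse_series <- function(series) {
  rev_i <- rev(seq_len(series$frame_count))
  keypoint_series(series$positions[rev_i, , , drop = FALSE],
                  series$orientations[rev_i, , , drop = FALSE],
                  series$com[rev_i, , drop = FALSE],
                  series$framerate, series$keypoint_labels,
                  series$foot_contacts[rev_i, , drop = FALSE])
}

# ---- independent oracles ----------------------------------------------

# O(n^3) 2D convex hull area: find directed hull edges by testing that all
# other points lie to the left, then chain them into a polygon and apply
# the shoelace formula. Independent of grDevices::chull.
oracle_hull2d_area <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- pts[i, ]; b <- pts[j, ]
    cr <- (b[1] - a[1]) * (pts[, 2] - a[2]) -
          (b[2] - a[2]) * (pts[, 1] - a[1])
    if (all(cr >= -1e-12)) edges[[length(edges) + 1L]] <- c(i, j)
  }
  if (!length(edges)) return(0)
  em <- do.call(rbind, edges)
  # walk the edge cycle; collinear inputs have no cycle -> area 0
  start <- em[1, 1]
  ring <- start
  cur <- em[1, 2]
  for (step in seq_len(n + 1)) {
    if (cur == start) break
    ring <- c(ring, cur)
    nxt <- em[em[, 1] == cur, 2]
    nxt <- setdiff(nxt, ring[length(ring) - 1])
    if (!length(nxt)) return(0)
    cur <- nxt[1]
  }
  if (length(ring) < 3) return(0)
  x <- pts[ring, 1]; y <- pts[ring, 2]
  j <- c(seq_along(ring)[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# per-pixel loop implementation of the quantity of motion
oracle_qom <- function(frames, delta) {
  n <- length(frames)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  q <- numeric(n)
  for (t in seq_len(n)) {
    moved <- 0L; active <- 0L
    for (r in seq_len(h)) for (cl in seq_len(w)) {
      cur <- frames[[t]][r, cl]
      if (cur) active <- active + 1L
      hist <- FALSE
      for (i in seq_len(delta)) {
        if (t - i < 1) break
        if (frames[[t - i]][r, cl]) { hist <- TRUE; break }
      }
      if (hist && !cur) moved <- moved + 1L
    }
    q[t] <- if (active > 0) moved / active else NA_real_
  }
  q
}

# homography-style pinhole projection oracle built from an explicit
# camera matrix (independent of project_campos internals)
oracle_project <- function(p, cam_pos, cam_target, fov, aspect) {
  fwd <- (cam_target - cam_pos); fwd <- fwd / sqrt(sum(fwd^2))
  up0 <- c(0, 0, 1)
  right <- c(fwd[2] * up0[3] - fwd[3] * up0[2],
             fwd[3] * up0[1] - fwd[1] * up0[3],
             fwd[1] * up0[2] - fwd[2] * up0[1])
  right <- right / sqrt(sum(right^2))
  up <- c(right[2] * fwd[3] - right[3] * fwd[2],
          right[3] * fwd[1] - right[1] * fwd[3],
          right[1] * fwd[2] - right[2] * fwd[1])
  K <- rbind(right, up, fwd)
  rel <- K %*% (p - cam_pos)
  d <- rel[3]
  c(0.5 + rel[1] / (d * tan(fov / 2)) / 2,
    0.5 + rel[2] / (d * tan(fov / 2) / aspect) / 2,
    d)
}

expect_feature_nonneg <- function(fs) {
  expect_true(all(fs$values >= 0 | is.na(fs$values)))
}
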