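# 3D convex hulls of body keypoints.
#
# Hull facets are found by brute-force supporting-plane enumeration: a
# triplet of points spans a hull facet iff all points lie on one side of its
# plane. Coplanar hull faces (e.g. the square faces of a cube) are merged by
# their on-plane point sets and fan-triangulated, so volumes are exact up to
# floating point. This is O(n^3 * n) and intended for the small point sets
# that arise here (23 keypoints per frame; merged hull vertex sets for the
# global aggregation).

# facets/normals/volume of the hull of an [n, 3] matrix.
# Returns list(volume, normals [F,3] outward unit-scaled, offsets [F],
# vertices (indices of points on the hull), degenerate flag).
# deterministic Fibonacci-sphere directions for the interior-point prefilter
.sphere_directions <- function(d = 80L) {
  k <- seq_len(d)
  z <- 1 - 2 * (k - 0.5) / d
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- k * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

.hull3d <- function(pts) {
  pts <- as.matrix(pts)
  storage.mode(pts) <- "double"
  pts <- unique(pts)
  n <- nrow(pts)
  if (n > 80L) {
    # prune points that are provably interior: anything strictly inside the
    # hull of the directional extremes is inside the full hull
    dirs <- .sphere_directions()
    proj <- pts %*% t(dirs)
    ext <- unique(apply(proj, 2, which.max))
    he <- .hull3d(pts[ext, , drop = FALSE])
    if (!isTRUE(he$degenerate)) {
      margin <- 1e-7 * max(apply(pts, 2, function(v) diff(range(v))))
      s <- pts %*% t(he$normals)
      interior <- rowSums(s <= rep(he$offsets - margin,
                                   each = n)) == ncol(s)
      keep <- sort(unique(c(ext, which(!interior))))
      pts <- pts[keep, , drop = FALSE]
      n <- nrow(pts)
    }
  }
  scale <- max(apply(pts, 2, function(v) diff(range(v))), 0)
  if (n < 4L || scale == 0)
    return(list(volume = 0, degenerate = TRUE, points = pts))
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))$d
  if (sv[3] < 1e-10 * max(sv[1], 1e-300))
    return(list(volume = 0, degenerate = TRUE, points = pts))
  tol <- 1e-9 * scale
  idx <- utils::combn(n, 3L)
  a <- pts[idx[1, ], , drop = FALSE]
  b <- pts[idx[2, ], , drop = FALSE]
  cc <- pts[idx[3, ], , drop = FALSE]
  u <- b - a; v <- cc - a
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  nlen <- sqrt(nx^2 + ny^2 + nz^2)
  ok <- nlen > tol * scale          # non-degenerate triangles
  d <- nx * a[, 1] + ny * a[, 2] + nz * a[, 3]
  # side of every point w.r.t. every candidate plane, without materialising
  # the full M x n matrix
  mx <- rep(-Inf, length(d)); mn <- rep(Inf, length(d))
  for (j in seq_len(n)) {
    s <- nx * pts[j, 1] + ny * pts[j, 2] + nz * pts[j, 3] - d
    mx <- pmax(mx, s); mn <- pmin(mn, s)
  }
  planetol <- tol * nlen
  sup <- ok & (mx <= planetol | mn >= -planetol)
  if (!any(sup))
    return(list(volume = 0, degenerate = TRUE, points = pts))
  # orient supporting planes outward (all points on the non-positive side)
  flip <- sup & mx > planetol
  nx[flip] <- -nx[flip]; ny[flip] <- -ny[flip]; nz[flip] <- -nz[flip]
  d[flip] <- -d[flip]
  sup_i <- which(sup)
  # group coplanar supporting triplets into faces via their on-plane sets
  side <- function(i) pts %*% c(nx[i], ny[i], nz[i]) - d[i]
  keys <- character(length(sup_i))
  members <- vector("list", length(sup_i))
  for (m in seq_along(sup_i)) {
    i <- sup_i[m]
    on <- which(abs(side(i)) <= planetol[i])
    members[[m]] <- on
    keys[m] <- paste(on, collapse = ",")
  }
  first <- !duplicated(keys)
  faces <- members[first]
  fidx <- sup_i[first]
  normals <- cbind(nx[fidx], ny[fidx], nz[fidx]) / nlen[fidx]
  offsets <- d[fidx] / nlen[fidx]
  # fan-triangulate each (possibly polygonal) face and accumulate signed
  # tetrahedra volumes from the centroid
  vol <- 0
  hull_vertices <- integer(0)
  for (f in seq_along(faces)) {
    on <- faces[[f]]
    nrml <- normals[f, ]
    p0 <- pts[on[1], ]
    u1 <- pts[on[2], ] - p0
    u1 <- u1 / sqrt(sum(u1^2))
    u2 <- .cross3(nrml, u1)
    rel <- sweep(pts[on, , drop = FALSE], 2, p0)
    xy <- cbind(rel %*% u1, rel %*% u2)
    ord <- grDevices::chull(xy[, 1], xy[, 2])
    if (.shoelace(xy[ord, , drop = FALSE]) < 0) ord <- rev(ord)
    ring <- on[ord]
    hull_vertices <- c(hull_vertices, ring)
    for (k in 2:(length(ring) - 1L)) {
      aa <- pts[ring[1], ] - ctr
      bb <- pts[ring[k], ] - ctr
      cc2 <- pts[ring[k + 1L], ] - ctr
      vol <- vol + sum(aa * .cross3(bb, cc2)) / 6
    }
  }
  list(volume = abs(vol), normals = normals, offsets = offsets,
       vertices = sort(unique(hull_vertices)), points = pts,
       degenerate = FALSE)
}

# TRUE for rows of `p` inside (or on) the hull described by outward unit
# normals/offsets
.in_hull3d <- function(hull, p, tol = 1e-9) {
  if (isTRUE(hull$degenerate)) return(rep(FALSE, nrow(p)))
  s <- p %*% t(hull$normals)
  rowSums(s <= rep(hull$offsets + tol, each = nrow(p))) == ncol(s)
}

# hull vertices of a large point set by incremental merging (hull of a union
# is the hull of the union of hull vertices)
.hull3d_vertices_merge <- function(frames_pts, chunk = 6L) {
  verts <- NULL
  buf <- list(); nbuf <- 0L
  flush <- function() {
    pool <- rbind(verts, do.call(rbind, buf))
    h <- .hull3d(pool)
    if (isTRUE(h$degenerate)) pool else h$points[h$vertices, , drop = FALSE]
  }
  for (pts in frames_pts) {
    buf[[length(buf) + 1L]] <- pts
    nbuf <- nbuf + 1L
    if (nbuf >= chunk) {
      verts <- flush(); buf <- list(); nbuf <- 0L
    }
  }
  if (nbuf > 0L) verts <- flush()
  verts
}

#' 3D convex hull volume of the body keypoints
#'
#' Volume (in cubic meters) of the smallest convex polytope containing the
#' keypoints: a per-frame proxy for how much space the body occupies.
#'
#' The `"global"` aggregation is the hull of all keypoints over all frames;
#' `"union"` is the volume of the union of the per-frame hulls, which is a
#' subset of the global hull (and typically not convex). The union volume is
#' estimated on a voxel grid of resolution `voxel` (meters): both the union
#' and the global hull are counted on the same grid and the union volume is
#' reported as `global_volume * union_count / global_count`, which guarantees
#' `union <= global` and makes a static pose give `union == global` exactly.
#' The grid is refined automatically (halving `voxel`) until the global hull
#' spans at least 500 voxels.
#'
#' @param series a [keypoint_series].
#' @param mode `"per-frame"`, `"global"` or `"union"`.
#' @param voxel voxel edge length in meters for the union estimate
#'   (default 0.01).
#' @return A [feature_series] in m^3 for `"per-frame"`, otherwise a scalar.
#'   Degenerate (coplanar) frames yield volume 0 with a warning.
#' @export
convex_hull_3d <- function(series, mode = c("per-frame", "global", "union"),
                           voxel = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "keypoint_series"))
  n <- series$frame_count
  frame_pts <- function(t) series$positions[t, , , drop = TRUE]
  if (mode == "per-frame") {
    degen <- 0L
    vals <- vapply(seq_len(n), function(t) {
      h <- .hull3d(frame_pts(t))
      if (isTRUE(h$degenerate)) degen <<- degen + 1L
      h$volume
    }, numeric(1))
    if (degen > 0L)
      warning(sprintf("%d degenerate (coplanar) frame(s): hull volume 0", degen))
    return(feature_series(vals, "convex_hull_3d", "ALL", "m^3",
                          series$framerate))
  }
  verts <- .hull3d_vertices_merge(lapply(seq_len(n), frame_pts))
  gh <- .hull3d(verts)
  if (mode == "global") return(gh$volume)
  if (isTRUE(gh$degenerate)) return(0)
  hulls <- lapply(seq_len(n), function(t) .hull3d(frame_pts(t)))
  bb <- apply(gh$points, 2, range)
  repeat {
    gx <- seq(bb[1, 1] + voxel / 2, bb[2, 1], by = voxel)
    gy <- seq(bb[1, 2] + voxel / 2, bb[2, 2], by = voxel)
    gz <- seq(bb[1, 3] + voxel / 2, bb[2, 3], by = voxel)
    ncell <- length(gx) * length(gy) * length(gz)
    if (ncell > 4e6)
      stop(sprintf("voxel grid too large (%d cells); increase `voxel`", ncell))
    grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
    in_global <- .in_hull3d(gh, grid)
    if (sum(in_global) >= 500L || voxel <= 1e-4) break
    voxel <- voxel / 2
  }
  gcount <- sum(in_global)
  if (gcount == 0L) return(0)
  cand <- grid[in_global, , drop = FALSE]
  in_union <- rep(FALSE, nrow(cand))
  for (h in hulls) {
    todo <- which(!in_union)
    if (!length(todo)) break
    if (isTRUE(h$degenerate)) next
    in_union[todo] <- .in_hull3d(h, cand[todo, , drop = FALSE])
  }
  gh$volume * sum(in_union) / gcount
}
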