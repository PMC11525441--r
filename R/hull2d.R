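# 2D convex hulls of camera-relative landmark coordinates.
#
# Per-frame hulls are convex polygons of the (x, y) screen ratios; their area
# is itself a ratio in [0, 1] of the screen covered. The "global" aggregation
# is the hull of all landmarks over all frames; the "union" aggregation is
# the exact area of the union of the per-frame hull polygons (computed by a
# vertical slab decomposition, exact for unions of convex polygons).

# ordered convex hull polygon (counterclockwise) of a 2-column matrix,
# or NULL if degenerate (fewer than 3 unique points / collinear)
.hull2d_poly <- function(pts) {
  pts <- unique(as.matrix(pts))
  if (nrow(pts) < 3L) return(NULL)
  idx <- grDevices::chull(pts[, 1], pts[, 2])
  if (length(idx) < 3L) return(NULL)
  poly <- pts[idx, , drop = FALSE]
  if (.shoelace(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  poly
}

# signed polygon area (positive for counterclockwise)
.shoelace <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

.hull2d_area <- function(pts) {
  poly <- .hull2d_poly(pts)
  if (is.null(poly)) 0 else abs(.shoelace(poly))
}

# Exact union area of convex polygons via vertical slabs. Breakpoints are
# placed at every vertex and every pairwise edge crossing, so inside each
# slab the vertical cross-section structure is fixed and the midpoint
# cross-section length integrates exactly.
.poly_union_area <- function(polys) {
  polys <- Filter(Negate(is.null), polys)
  if (!length(polys)) return(0)
  edges <- do.call(rbind, lapply(seq_along(polys), function(i) {
    p <- polys[[i]]
    j <- c(seq_len(nrow(p))[-1], 1L)
    cbind(p[, 1], p[, 2], p[j, 1], p[j, 2], i)
  }))
  xs <- c(edges[, 1], edges[, 3])
  scale <- max(diff(range(xs)), 1e-12)
  # pairwise edge crossings between different polygons
  ne <- nrow(edges)
  if (ne >= 2L && length(polys) >= 2L) {
    pr <- which(upper.tri(matrix(0, ne, ne)), arr.ind = TRUE)
    pr <- pr[edges[pr[, 1], 5] != edges[pr[, 2], 5], , drop = FALSE]
    if (nrow(pr)) {
      e1 <- edges[pr[, 1], , drop = FALSE]
      e2 <- edges[pr[, 2], , drop = FALSE]
      # quick bounding-box rejection
      keep <- pmax(pmin(e1[, 1], e1[, 3]), pmin(e2[, 1], e2[, 3])) <=
                pmin(pmax(e1[, 1], e1[, 3]), pmax(e2[, 1], e2[, 3])) &
              pmax(pmin(e1[, 2], e1[, 4]), pmin(e2[, 2], e2[, 4])) <=
                pmin(pmax(e1[, 2], e1[, 4]), pmax(e2[, 2], e2[, 4]))
      e1 <- e1[keep, , drop = FALSE]; e2 <- e2[keep, , drop = FALSE]
      if (nrow(e1)) {
        d1x <- e1[, 3] - e1[, 1]; d1y <- e1[, 4] - e1[, 2]
        d2x <- e2[, 3] - e2[, 1]; d2y <- e2[, 4] - e2[, 2]
        den <- d1x * d2y - d1y * d2x
        rx <- e2[, 1] - e1[, 1]; ry <- e2[, 2] - e1[, 2]
        ok <- abs(den) > 1e-14
        t1 <- (rx * d2y - ry * d2x) / den
        t2 <- (rx * d1y - ry * d1x) / den
        ok <- ok & t1 >= 0 & t1 <= 1 & t2 >= 0 & t2 <= 1
        xs <- c(xs, (e1[, 1] + t1 * d1x)[ok])
      }
    }
  }
  xs <- sort(unique(xs))
  xs <- xs[c(TRUE, diff(xs) > 1e-13 * scale)]
  if (length(xs) < 2L) return(0)
  # per-polygon bounding range for quick slab filtering
  xr <- t(vapply(polys, function(p) range(p[, 1]), numeric(2)))
  area <- 0
  for (s in seq_len(length(xs) - 1L)) {
    x1 <- xs[s]; x2 <- xs[s + 1L]
    xm <- (x1 + x2) / 2
    active <- which(xr[, 1] < xm & xr[, 2] > xm)
    if (!length(active)) next
    ints <- vapply(active, function(i) {
      p <- polys[[i]]
      j <- c(seq_len(nrow(p))[-1], 1L)
      span <- (p[, 1] - xm) * (p[j, 1] - xm) <= 0 & p[, 1] != p[j, 1]
      y <- p[span, 2] + (xm - p[span, 1]) *
        (p[j, 2][span] - p[span, 2]) / (p[j, 1][span] - p[span, 1])
      range(y)
    }, numeric(2))
    # merge the vertical intervals of the active polygons
    o <- order(ints[1, ])
    lo <- ints[1, o]; hi <- ints[2, o]
    len <- 0; cur_lo <- lo[1]; cur_hi <- hi[1]
    for (i in seq_along(lo)[-1]) {
      if (lo[i] <= cur_hi) cur_hi <- max(cur_hi, hi[i])
      else { len <- len + (cur_hi - cur_lo); cur_lo <- lo[i]; cur_hi <- hi[i] }
    }
    len <- len + (cur_hi - cur_lo)
    area <- area + len * (x2 - x1)
  }
  area
}

#' 2D convex hull of camera-relative landmarks
#'
#' Area of the convex polygon spanned by the landmark screen coordinates
#' (ratios in `[0, 1]` from the bottom-left corner of the rendered frame), so
#' the result is the dimensionless fraction of the screen covered by the
#' hull of the figure.
#'
#' @param campos a [campos_series].
#' @param mode `"per-frame"` (a [feature_series] of per-frame areas),
#'   `"global"` (scalar: area of the hull of all landmarks over all frames)
#'   or `"union"` (scalar: exact area of the union of per-frame hulls; always
#'   `<=` the global hull area).
#' @param landmarks optional character vector restricting the hull to a
#'   subset of landmark names (default: all).
#' @return A [feature_series] for `"per-frame"`, otherwise a scalar.
#' @export
convex_hull_2d <- function(campos, mode = c("per-frame", "global", "union"),
                           landmarks = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(campos, "campos_series"))
  sel <- seq_along(campos$landmark_names)
  if (!is.null(landmarks))
    sel <- vapply(landmarks, function(l) {
      i <- match(l, campos$landmark_names)
      if (is.na(i)) stop(sprintf("unknown landmark %s", dQuote(l)))
      i
    }, integer(1))
  xy_t <- function(t) cbind(campos$x[t, sel], campos$y[t, sel])
  n <- nrow(campos$x)
  if (mode == "per-frame") {
    vals <- vapply(seq_len(n), function(t) .hull2d_area(xy_t(t)), numeric(1))
    return(feature_series(vals, "convex_hull_2d", "ALL", "screen-ratio^2",
                          campos$framerate))
  }
  if (mode == "global")
    return(.hull2d_area(cbind(as.vector(campos$x[, sel]),
                              as.vector(campos$y[, sel]))))
  polys <- lapply(seq_len(n), function(t) .hull2d_poly(xy_t(t)))
  .poly_union_area(polys)
}
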