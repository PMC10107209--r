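# Planar geometry layer.
#
# A geometry is a list of rings; each ring is list(x = numeric, y = numeric)
# with vertices *not* repeated at closure. Orientation follows the nonzero
# fill rule as normalised by Clipper (outer rings positive, holes negative);
# readers repair/normalise on ingest so downstream code can assume it.
# An empty geometry is list().
#
# Polygon booleans, repair and offsetting are delegated to polyclip (Clipper);
# areas, centroids, hulls and predicates are the standard closed forms.

EARTH_RADIUS_KM <- 6371.0088

# Relative area below which a polygon intersection is treated as empty:
# boolean operations on polygons sharing a boundary (e.g. a range built as a
# union of countries against an adjacent country) can leave hairline slivers
# of relative area ~1e-12; anything under this fraction of the reference
# polygon is numerical noise, not overlap.
AREA_REL_TOL <- 1e-8

#' Is an intersection area real overlap rather than a numerical sliver?
#' @param area intersection area
#' @param ref_area area of the smaller operand (reference scale)
#' @return logical
#' @export
area_positive <- function(area, ref_area) {
  area > AREA_REL_TOL * ref_area
}

#' Signed area of a single ring (shoelace formula)
#' @param ring list with numeric `x` and `y`
#' @return signed area; positive for counterclockwise rings
#' @keywords internal
ring_signed_area <- function(ring) {
  x <- ring$x; y <- ring$y
  n <- length(x)
  if (n < 3) return(0)
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

ring_centroid <- function(ring) {
  x <- ring$x; y <- ring$y
  a <- ring_signed_area(ring)
  if (abs(a) < .Machine$double.xmin) {
    return(c(mean(x), mean(y)))
  }
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr) / (6 * a), sum((y + yn) * cr) / (6 * a))
}

#' Area of a geometry
#'
#' Net area of a (normalised) multipolygon: outer rings count positively,
#' holes negatively.
#'
#' @param g geometry (list of rings)
#' @return non-negative numeric area, in squared units of the coordinates
#' @export
geom_area <- function(g) {
  if (length(g) == 0) return(0)
  abs(sum(vapply(g, ring_signed_area, numeric(1))))
}

#' Area-weighted centroid of a geometry
#'
#' @param g geometry (list of rings)
#' @return numeric length-2 `c(x, y)`, or `NULL` for an empty geometry
#' @export
geom_centroid <- function(g) {
  if (length(g) == 0) return(NULL)
  areas <- vapply(g, ring_signed_area, numeric(1))
  if (sum(abs(areas)) == 0) {
    xs <- unlist(lapply(g, `[[`, "x")); ys <- unlist(lapply(g, `[[`, "y"))
    return(c(mean(xs), mean(ys)))
  }
  cents <- vapply(g, ring_centroid, numeric(2))
  c(sum(areas * cents[1, ]) / sum(areas), sum(areas * cents[2, ]) / sum(areas))
}

#' Repair a geometry by resolving self-intersections
#'
#' The zero-width-buffer equivalent: rings are re-expressed as the boundary of
#' the nonzero-fill region they enclose, which removes self-intersections and
#' normalises orientations.
#'
#' @param g geometry
#' @return repaired geometry
#' @export
geom_repair <- function(g) {
  if (length(g) == 0) return(list())
  out <- polyclip::polysimplify(g, filltype = "nonzero",
                                eps = clip_eps(g))
  lapply(out, function(r) list(x = as.numeric(r$x), y = as.numeric(r$y)))
}

# Clipper snaps coordinates to an integer grid of spacing eps; its default
# (~1e-9 of the coordinate range) is too coarse for 1e-9-relative area
# invariants, so every boolean call uses a grid 1e-13 of the extent.
clip_eps <- function(a, b = list()) {
  max(geom_scale(a), geom_scale(b)) * 1e-13
}

#' @rdname geom_boolean
#' @export
geom_intersection <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(list())
  polyclip::polyclip(a, b, op = "intersection",
                     fillA = "nonzero", fillB = "nonzero",
                     eps = clip_eps(a, b))
}

#' Polygon boolean operations
#'
#' Thin wrappers around Clipper with the nonzero fill rule on both operands.
#'
#' @param a,b geometries (lists of rings)
#' @return a geometry
#' @name geom_boolean
#' @export
geom_union <- function(a, b) {
  if (length(a) == 0) return(b)
  if (length(b) == 0) return(a)
  polyclip::polyclip(a, b, op = "union", fillA = "nonzero",
                     fillB = "nonzero", eps = clip_eps(a, b))
}

geom_union_all <- function(gs) {
  Reduce(geom_union, gs, accumulate = FALSE, right = FALSE, init = list())
}

#' Project a geometry for area computation
#'
#' `"cea"` is the Lambert cylindrical equal-area projection on a spherical
#' earth (standard parallel at the equator; units km), applied vertex-wise to
#' lon/lat degrees. `"planar"` treats coordinates as already planar.
#'
#' @param g geometry
#' @param crs `"cea"` or `"planar"`
#' @return projected geometry
#' @export
geom_project <- function(g, crs = "cea") {
  crs <- match.arg(crs, c("cea", "planar"))
  if (crs == "planar" || length(g) == 0) return(g)
  lapply(g, function(r) list(
    x = EARTH_RADIUS_KM * r$x * pi / 180,
    y = EARTH_RADIUS_KM * sin(r$y * pi / 180)
  ))
}

project_point <- function(p, crs = "cea") {
  if (crs == "planar") return(p)
  c(EARTH_RADIUS_KM * p[1] * pi / 180, EARTH_RADIUS_KM * sin(p[2] * pi / 180))
}

geom_bbox <- function(g) {
  xs <- unlist(lapply(g, `[[`, "x")); ys <- unlist(lapply(g, `[[`, "y"))
  c(xmin = min(xs), xmax = max(xs), ymin = min(ys), ymax = max(ys))
}

geom_scale <- function(g) {
  if (length(g) == 0) return(1)
  b <- geom_bbox(g)
  max(b["xmax"] - b["xmin"], b["ymax"] - b["ymin"], .Machine$double.eps)
}

#' Point-in-polygon test (even-odd crossing rule over all rings)
#' @keywords internal
point_in_geom <- function(p, g) {
  if (length(g) == 0) return(FALSE)
  px <- p[1]; py <- p[2]
  inside <- FALSE
  for (r in g) {
    x <- r$x; y <- r$y
    n <- length(x)
    j <- n
    for (i in seq_len(n)) {
      if ((y[i] > py) != (y[j] > py)) {
        xint <- x[i] + (py - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
        if (px < xint) inside <- !inside
      }
      j <- i
    }
  }
  inside
}

# Orientation of the triple (p, q, r): >0 counterclockwise, <0 clockwise,
# 0 collinear (within a relative tolerance).
orient3 <- function(px, py, qx, qy, rx, ry, tol = 1e-12) {
  v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
  scale <- max(abs(c(px, py, qx, qy, rx, ry)), 1)
  if (abs(v) < tol * scale * scale) 0 else sign(v)
}

on_segment <- function(px, py, qx, qy, rx, ry) {
  # r collinear with p-q assumed; is r within the bounding box of p-q?
  rx >= min(px, qx) - 0 && rx <= max(px, qx) &&
    ry >= min(py, qy) && ry <= max(py, qy)
}

segments_intersect <- function(p1, p2, p3, p4) {
  d1 <- orient3(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])
  d2 <- orient3(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])
  d3 <- orient3(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])
  d4 <- orient3(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2])
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && on_segment(p3[1], p3[2], p4[1], p4[2], p1[1], p1[2])) ||
    (d2 == 0 && on_segment(p3[1], p3[2], p4[1], p4[2], p2[1], p2[2])) ||
    (d3 == 0 && on_segment(p1[1], p1[2], p2[1], p2[2], p3[1], p3[2])) ||
    (d4 == 0 && on_segment(p1[1], p1[2], p2[1], p2[2], p4[1], p4[2]))
}

geom_edges <- function(g) {
  do.call(rbind, lapply(g, function(r) {
    n <- length(r$x)
    cbind(r$x, r$y, c(r$x[-1], r$x[1]), c(r$y[-1], r$y[1]))
  }))
}

geoms_touch <- function(a, b) {
  ea <- geom_edges(a); eb <- geom_edges(b)
  if (is.null(ea) || is.null(eb)) return(FALSE)
  for (i in seq_len(nrow(ea))) {
    for (j in seq_len(nrow(eb))) {
      if (segments_intersect(ea[i, 1:2], ea[i, 3:4], eb[j, 1:2], eb[j, 3:4]))
        return(TRUE)
    }
  }
  FALSE
}

#' Do two geometries intersect (boundary contact counts)?
#'
#' True when the interiors overlap with positive area, when boundaries touch
#' (including a single shared point), or when one geometry contains the other.
#'
#' @param a,b geometries
#' @return logical
#' @export
geom_intersects <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) return(FALSE)
  ba <- geom_bbox(a); bb <- geom_bbox(b)
  if (ba["xmin"] > bb["xmax"] || bb["xmin"] > ba["xmax"] ||
      ba["ymin"] > bb["ymax"] || bb["ymin"] > ba["ymax"]) return(FALSE)
  if (geom_area(geom_intersection(a, b)) > 0) return(TRUE)
  if (point_in_geom(c(a[[1]]$x[1], a[[1]]$y[1]), b)) return(TRUE)
  if (point_in_geom(c(b[[1]]$x[1], b[[1]]$y[1]), a)) return(TRUE)
  geoms_touch(a, b)
}

segment_intersects_geom <- function(p1, p2, g) {
  if (length(g) == 0) return(FALSE)
  if (point_in_geom(p1, g) || point_in_geom(p2, g)) return(TRUE)
  eg <- geom_edges(g)
  for (j in seq_len(nrow(eg))) {
    if (segments_intersect(p1, p2, eg[j, 1:2], eg[j, 3:4])) return(TRUE)
  }
  FALSE
}

#' Minimum convex polygon of a point set
#'
#' Returns the convex hull classified by its degeneracy: a polygon for three
#' or more non-collinear points, the extreme segment for collinear sets of at
#' least two distinct points, and a point otherwise.
#'
#' @param x,y point coordinates
#' @return list with `type` (`"polygon"`, `"segment"`, `"point"`) and either
#'   `ring` (a geometry ring) or `p1`/`p2` endpoints
#' @export
convex_hull <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  pts <- unique(data.frame(x = x, y = y))
  if (nrow(pts) == 1) {
    return(list(type = "point", p1 = c(pts$x, pts$y)))
  }
  idx <- grDevices::chull(pts$x, pts$y)
  hx <- pts$x[idx]; hy <- pts$y[idx]
  ring <- list(x = hx, y = hy)
  if (length(idx) >= 3 && abs(ring_signed_area(ring)) >
      1e-12 * max(diff(range(pts$x)), diff(range(pts$y)))^2) {
    return(list(type = "polygon", ring = ring))
  }
  # collinear: take the two most distant points
  d <- as.matrix(stats::dist(pts))
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  list(type = "segment",
       p1 = c(pts$x[ij[1]], pts$y[ij[1]]),
       p2 = c(pts$x[ij[2]], pts$y[ij[2]]))
}

#' Does a convex hull (possibly degenerate) intersect a geometry?
#' @param hull result of [convex_hull()]
#' @param g geometry
#' @return logical
#' @export
hull_intersects <- function(hull, g) {
  switch(hull$type,
    polygon = geom_intersects(list(hull$ring), g),
    segment = segment_intersects_geom(hull$p1, hull$p2, g),
    point   = point_in_geom(hull$p1, g) ||
              segment_intersects_geom(hull$p1, hull$p1 + 1e-12, g)
  )
}

#' Approximate length of the shared boundary between two polygons
#'
#' Estimated as `area(offset(a, delta) ∩ b) / delta`: offsetting `a`
#' outward by a sliver `delta` sweeps a band of width `delta` along its
#' boundary, so the overlap with a true edge-sharing neighbour scales with the
#' shared length while a corner-only contact contributes O(delta).
#'
#' @param a,b geometries
#' @param delta band width; default 1e-6 of the larger bounding-box extent
#' @return estimated shared length (same units as coordinates)
#' @export
shared_boundary_length <- function(a, b, delta = NULL) {
  if (length(a) == 0 || length(b) == 0) return(0)
  if (is.null(delta)) delta <- 1e-6 * max(geom_scale(a), geom_scale(b))
  grown <- polyclip::polyoffset(a, delta, jointype = "miter", miterlim = 4,
                                eps = clip_eps(a, b))
  band <- geom_intersection(grown, b)
  geom_area(band) / delta
}

#' Are two polygons boundary-sharing neighbours?
#'
#' True when the estimated shared boundary length exceeds `100 * delta`,
#' which separates edge sharing (length of order the polygon size) from
#' corner-point contact (length of order `delta`).
#'
#' @inheritParams shared_boundary_length
#' @return logical
#' @export
geom_adjacent <- function(a, b, delta = NULL) {
  if (length(a) == 0 || length(b) == 0) return(FALSE)
  if (is.null(delta)) delta <- 1e-6 * max(geom_scale(a), geom_scale(b))
  shared_boundary_length(a, b, delta) > 100 * delta
}
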