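# Planar geometry helpers for fence polygons and regular grids.
# All coordinates are projected metres on an abstract local grid; no geodesy.

#' Close a polygon coordinate matrix
#'
#' Ensures the first vertex is repeated as the last row.
#' @param poly two-column matrix of vertices (x, y).
#' @return closed two-column matrix.
#' @keywords internal
close_polygon <- function(poly) {
  poly <- as.matrix(poly)
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  if (any(poly[1L, ] != poly[nrow(poly), ])) poly <- rbind(poly, poly[1L, ])
  poly
}

#' Polygon area by the shoelace formula
#'
#' @param poly two-column matrix of vertices (x, y), closed or open.
#' @return area in square metres.
#' @export
polygon_area <- function(poly) {
  p <- close_polygon(poly)
  n <- nrow(p)
  x <- p[, 1L]; y <- p[, 2L]
  abs(sum(x[-n] * y[-1L] - x[-1L] * y[-n])) / 2
}

#' Test whether points fall inside a polygon
#'
#' @param pts two-column matrix (or length-2 vector) of point coordinates.
#' @param poly two-column polygon vertex matrix.
#' @return logical vector, one element per point.
#' @export
point_in_polygon <- function(pts, poly) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  pts <- as.matrix(pts)
  mgcv::in.out(close_polygon(poly), pts)
}

#' Minimum distance from points to a polygon boundary
#'
#' Scans every boundary segment and returns, per point, the distance to the
#' nearest point on the boundary (and optionally that point itself).
#'
#' @param pts two-column matrix of points.
#' @param poly two-column polygon vertex matrix.
#' @param nearest if TRUE also return the nearest boundary points.
#' @return numeric vector of distances, or if `nearest` a list with
#'   `distance` and `point` (matrix) components.
#' @export
dist_to_boundary <- function(pts, poly, nearest = FALSE) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  pts <- as.matrix(pts)
  p <- close_polygon(poly)
  n_seg <- nrow(p) - 1L
  best <- rep(Inf, nrow(pts))
  bx <- numeric(nrow(pts)); by <- numeric(nrow(pts))
  for (s in seq_len(n_seg)) {
    a <- p[s, ]; b <- p[s + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      t <- rep(0, nrow(pts))
    } else {
      t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L]) / len2
      t <- pmin(1, pmax(0, t))
    }
    qx <- a[1L] + t * ab[1L]
    qy <- a[2L] + t * ab[2L]
    d <- sqrt((pts[, 1L] - qx)^2 + (pts[, 2L] - qy)^2)
    upd <- d < best
    best[upd] <- d[upd]
    bx[upd] <- qx[upd]; by[upd] <- qy[upd]
  }
  if (nearest) list(distance = best, point = cbind(x = bx, y = by)) else best
}

#' Rounded-rectangle polygon of a given area
#'
#' Default fence geometry for synthetic paddocks: a rectangle with
#' quarter-circle corners, scaled so the enclosed area matches `area_m2`
#' exactly (to floating point).
#'
#' @param area_m2 target area in square metres.
#' @param aspect width/height ratio of the rectangle.
#' @param corner_frac corner radius as a fraction of the short side.
#' @param n_arc vertices per corner arc.
#' @return closed two-column vertex matrix with lower-left of the bounding
#'   box at the origin.
#' @export
rounded_rect_polygon <- function(area_m2, aspect = 1.4, corner_frac = 0.25,
                                 n_arc = 10L) {
  stopifnot(area_m2 > 0, aspect > 0, corner_frac > 0, corner_frac <= 0.5)
  h <- 1; w <- aspect
  r <- corner_frac * min(w, h)
  arc <- function(cx, cy, from, to) {
    th <- seq(from, to, length.out = n_arc)
    cbind(cx + r * cos(th), cy + r * sin(th))
  }
  pts <- rbind(
    arc(w - r, h - r, 0, pi / 2),      # NE corner
    arc(r,     h - r, pi / 2, pi),     # NW
    arc(r,     r,     pi, 3 * pi / 2), # SW
    arc(w - r, r,     3 * pi / 2, 2 * pi) # SE
  )
  sc <- sqrt(area_m2 / polygon_area(pts))
  pts <- pts * sc
  pts[, 1L] <- pts[, 1L] - min(pts[, 1L])
  pts[, 2L] <- pts[, 2L] - min(pts[, 2L])
  close_polygon(pts)
}
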