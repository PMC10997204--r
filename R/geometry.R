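# Minimal planar geometry on lon/lat coordinates for toy-scale worlds.
# Polygons are tibbles of ordered vertices (closed implicitly); none of the
# shapes handled here cross the dateline, so planar tests suffice. Grid
# adjacency and dilation (see world.R) do wrap in longitude.

#' Point-in-polygon test (even-odd rule)
#'
#' Vectorised crossing-number test of points against a single polygon.
#' Points exactly on an edge are resolved by the crossing parity and should
#' not be relied upon; rasterisation breaks such ties by sampled overlap.
#'
#' @param px,py Point coordinates (equal-length vectors).
#' @param poly_x,poly_y Polygon vertex coordinates in order (not repeated at
#'   the end).
#' @return Logical vector.
#' @keywords internal
#' @export
point_in_polygon <- function(px, py, poly_x, poly_y) {
  n <- length(poly_x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly_x[i]; yi <- poly_y[i]
    xj <- poly_x[j]; yj <- poly_y[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' @noRd
seg_seg_intersects <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  orient <- function(px, py, qx, qy, rx, ry) {
    v <- (qx - px) * (ry - py) - (qy - py) * (rx - px)
    sign(v)
  }
  o1 <- orient(ax, ay, bx, by, cx, cy)
  o2 <- orient(ax, ay, bx, by, dx, dy)
  o3 <- orient(cx, cy, dx, dy, ax, ay)
  o4 <- orient(cx, cy, dx, dy, bx, by)
  if (o1 != o2 && o3 != o4) return(TRUE)
  on_seg <- function(px, py, qx, qy, rx, ry) {
    orient(px, py, qx, qy, rx, ry) == 0 &&
      min(px, qx) <= rx && rx <= max(px, qx) &&
      min(py, qy) <= ry && ry <= max(py, qy)
  }
  on_seg(ax, ay, bx, by, cx, cy) || on_seg(ax, ay, bx, by, dx, dy) ||
    on_seg(cx, cy, dx, dy, ax, ay) || on_seg(cx, cy, dx, dy, bx, by)
}

#' @noRd
seg_intersects_rect <- function(x1, y1, x2, y2, xlo, xhi, ylo, yhi) {
  inside <- function(x, y) x >= xlo && x <= xhi && y >= ylo && y <= yhi
  if (inside(x1, y1) || inside(x2, y2)) return(TRUE)
  seg_seg_intersects(x1, y1, x2, y2, xlo, ylo, xhi, ylo) ||
    seg_seg_intersects(x1, y1, x2, y2, xhi, ylo, xhi, yhi) ||
    seg_seg_intersects(x1, y1, x2, y2, xhi, yhi, xlo, yhi) ||
    seg_seg_intersects(x1, y1, x2, y2, xlo, yhi, xlo, ylo)
}

#' Does a polygon intersect an axis-aligned rectangle?
#'
#' True if any polygon vertex lies in the rectangle, any rectangle corner or
#' its centre lies in the polygon, or any polygon edge crosses the
#' rectangle boundary. Exact for simple polygons.
#'
#' @param poly Tibble with columns `lon`, `lat` (ordered vertices).
#' @param xlo,xhi,ylo,yhi Rectangle bounds.
#' @return Logical scalar.
#' @keywords internal
#' @export
polygon_intersects_rect <- function(poly, xlo, xhi, ylo, yhi) {
  px <- poly$lon; py <- poly$lat
  if (any(px >= xlo & px <= xhi & py >= ylo & py <= yhi)) return(TRUE)
  cx <- c((xlo + xhi) / 2, xlo, xhi, xhi, xlo)
  cy <- c((ylo + yhi) / 2, ylo, ylo, yhi, yhi)
  if (any(point_in_polygon(cx, cy, px, py))) return(TRUE)
  n <- length(px)
  j <- n
  for (i in seq_len(n)) {
    if (seg_intersects_rect(px[j], py[j], px[i], py[i],
                            xlo, xhi, ylo, yhi)) {
      return(TRUE)
    }
    j <- i
  }
  FALSE
}

#' Does a polyline intersect an axis-aligned rectangle?
#'
#' @param line Tibble with columns `lon`, `lat` (ordered vertices of an open
#'   polyline).
#' @inheritParams polygon_intersects_rect
#' @return Logical scalar.
#' @keywords internal
#' @export
polyline_intersects_rect <- function(line, xlo, xhi, ylo, yhi) {
  px <- line$lon; py <- line$lat
  n <- length(px)
  if (n == 1) {
    return(px >= xlo && px <= xhi && py >= ylo && py <= yhi)
  }
  for (i in seq_len(n - 1)) {
    if (seg_intersects_rect(px[i], py[i], px[i + 1], py[i + 1],
                            xlo, xhi, ylo, yhi)) {
      return(TRUE)
    }
  }
  FALSE
}
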