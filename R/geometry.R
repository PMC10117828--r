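# Low-level planar geometry on matrices of (x, y) coordinates in micrometres.
# These back the region module; no spatial-geometry package is assumed.

#' Polygon area by the shoelace formula
#'
#' @param poly two-column numeric matrix of vertices (closed or open ring;
#'   the closing edge is implied).
#' @return Area in the square of the coordinate unit (always >= 0).
#' @keywords internal
polygon_area <- function(poly) {
  poly <- close_ring(poly, open = TRUE)
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

# Drop (open = TRUE) or append (open = FALSE) a duplicated closing vertex.
close_ring <- function(poly, open = FALSE) {
  stopifnot(is.matrix(poly), ncol(poly) == 2, nrow(poly) >= 3)
  n <- nrow(poly)
  closed <- isTRUE(all.equal(poly[1, ], poly[n, ], check.attributes = FALSE))
  if (open && closed) poly <- poly[-n, , drop = FALSE]
  if (!open && !closed) poly <- rbind(poly, poly[1, ])
  poly
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' @param x,y numeric coordinate vectors.
#' @param poly two-column vertex matrix.
#' @return Logical vector.
#' @keywords internal
point_in_polygon <- function(x, y, poly) {
  poly <- close_ring(poly, open = TRUE)
  cpp_point_in_polygon(as.numeric(x), as.numeric(y), poly)
}

#' Distance from points to a polyline
#'
#' Minimum Euclidean distance from each point to the union of the segments of
#' `line`. If `closed`, the segment from the last to the first vertex is
#' included.
#'
#' @param x,y numeric coordinate vectors.
#' @param line two-column vertex matrix (>= 2 vertices).
#' @param closed treat the polyline as a closed ring.
#' @return Numeric vector of distances.
#' @keywords internal
dist_to_polyline <- function(x, y, line, closed = TRUE) {
  stopifnot(is.matrix(line), ncol(line) == 2, nrow(line) >= 2)
  seg <- if (closed) close_ring(line, open = TRUE) else line
  n <- nrow(seg)
  j <- if (closed) c(2:n, 1L) else 2:n
  i <- if (closed) 1:n else 1:(n - 1L)
  if (all((seg[j, 1] - seg[i, 1])^2 + (seg[j, 2] - seg[i, 2])^2 == 0))
    stop("degenerate polyline: all segments have zero length")
  cpp_dist_to_polyline(as.numeric(x), as.numeric(y), seg, closed)
}

#' Clip a polygon to an axis-aligned rectangle (Sutherland-Hodgman)
#'
#' @param poly two-column vertex matrix (convexity not required of `poly`;
#'   the clip window is the rectangle, which is convex, so the algorithm is
#'   exact up to floating point).
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return Vertex matrix of the clipped polygon (possibly 0 rows).
#' @keywords internal
clip_polygon_rect <- function(poly, xmin, xmax, ymin, ymax) {
  poly <- close_ring(poly, open = TRUE)
  clip_half <- function(pts, inside, intersect) {
    n <- nrow(pts)
    if (n == 0) return(pts)
    out <- vector("list", 2L * n)
    k <- 0L
    ins <- inside(pts)
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      p <- pts[i, ]; q <- pts[j, ]
      if (ins[i]) {
        k <- k + 1L; out[[k]] <- p
        if (!ins[j]) { k <- k + 1L; out[[k]] <- intersect(p, q) }
      } else if (ins[j]) {
        k <- k + 1L; out[[k]] <- intersect(p, q)
      }
    }
    if (k == 0L) matrix(numeric(0), 0, 2) else do.call(rbind, out[seq_len(k)])
  }
  ix <- function(p, q, edge, coord) {
    t <- (edge - p[coord]) / (q[coord] - p[coord])
    p + t * (q - p)
  }
  pts <- poly
  pts <- clip_half(pts, function(m) m[, 1] >= xmin, function(p, q) ix(p, q, xmin, 1))
  pts <- clip_half(pts, function(m) m[, 1] <= xmax, function(p, q) ix(p, q, xmax, 1))
  pts <- clip_half(pts, function(m) m[, 2] >= ymin, function(p, q) ix(p, q, ymin, 2))
  pts <- clip_half(pts, function(m) m[, 2] <= ymax, function(p, q) ix(p, q, ymax, 2))
  pts
}

#' Area of the intersection of a polygon and a rectangle
#' @keywords internal
clip_area_rect <- function(poly, xmin, xmax, ymin, ymax) {
  clipped <- clip_polygon_rect(poly, xmin, xmax, ymin, ymax)
  if (nrow(clipped) < 3) return(0)
  polygon_area(clipped)
}

# TRUE iff a ring is simple (no two non-adjacent edges intersect). O(n^2);
# used only on generated geometries with ~100 vertices.
ring_is_simple <- function(poly) {
  poly <- close_ring(poly, open = TRUE)
  n <- nrow(poly)
  seg <- function(i) list(p = poly[i, ], q = poly[if (i == n) 1L else i + 1L, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  intersects <- function(s1, s2) {
    d1 <- cross(s2$p, s2$q, s1$p); d2 <- cross(s2$p, s2$q, s1$q)
    d3 <- cross(s1$p, s1$q, s2$p); d4 <- cross(s1$p, s1$q, s2$q)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next  # adjacent through the closing edge
      if (intersects(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}
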