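# Low-level polygon geometry on a plain n x 2 numeric matrix of vertices.
# Polygons are implicitly closed (last vertex connects to the first) and,
# after normalization, counterclockwise with no duplicate consecutive
# vertices. All lengths in micrometres.

DEGENERATE_AREA <- 1e-9 # um^2; anything smaller is treated as no polygon

# Remove duplicate consecutive vertices (including a repeated closing
# vertex) within tolerance, in um.
dedupe_vertices <- function(v, tol = 1e-9) {
  stopifnot(is.matrix(v), ncol(v) == 2)
  n <- nrow(v)
  if (n < 2) return(v)
  nxt <- c(2:n, 1)
  keep <- sqrt((v[, 1] - v[nxt, 1])^2 + (v[, 2] - v[nxt, 2])^2) > tol
  # keep[i] FALSE means v[i+1] duplicates v[i]; drop the successor
  drop <- nxt[!keep]
  if (length(drop) > 0) v <- v[-drop, , drop = FALSE]
  v
}

signed_area <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2]) / 2
}

#' Polygon area by the shoelace formula
#'
#' Area of a simple closed polygon, independent of vertex winding
#' direction and of the starting vertex.
#'
#' @param v An n x 2 numeric matrix of vertices (implicitly closed).
#' @return Area in square micrometres.
#' @keywords internal
polygon_area_xy <- function(v) {
  a <- abs(signed_area(v))
  if (a < DEGENERATE_AREA) {
    abort("invalid contour: degenerate polygon (area below 1e-9 um^2)",
          class = "somamorph_invalid_contour")
  }
  a
}

#' Polygon perimeter
#'
#' Sum of Euclidean edge lengths including the closing edge.
#' @inheritParams polygon_area_xy
#' @return Length in micrometres.
#' @keywords internal
polygon_perimeter_xy <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  sum(sqrt((v[, 1] - v[nxt, 1])^2 + (v[, 2] - v[nxt, 2])^2))
}

# TRUE if the closed polygon is simple (no two non-adjacent edges
# intersect). O(n^2) pairwise segment tests, vectorized over pairs;
# soma contours are small (well under 1000 vertices).
is_simple_polygon <- function(v, tol = 1e-12) {
  n <- nrow(v)
  if (n < 3) return(FALSE)
  nxt <- c(2:n, 1)
  p1 <- v
  p2 <- v[nxt, , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) j > i + 1), arr.ind = TRUE)
  # edge n is adjacent to edge 1: exclude that wrap-around pair
  idx <- idx[!(idx[, 1] == 1 & idx[, 2] == n), , drop = FALSE]
  if (nrow(idx) == 0) return(TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  !segments_intersect_any(p1[i, , drop = FALSE], p2[i, , drop = FALSE],
                          p1[j, , drop = FALSE], p2[j, , drop = FALSE], tol)
}

# Vectorized proper/improper segment intersection test; returns TRUE if
# any pair (a1-a2) x (b1-b2) intersects.
segments_intersect_any <- function(a1, a2, b1, b2, tol = 1e-12) {
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  d1 <- cross2(b1[, 1], b1[, 2], b2[, 1], b2[, 2], a1[, 1], a1[, 2])
  d2 <- cross2(b1[, 1], b1[, 2], b2[, 1], b2[, 2], a2[, 1], a2[, 2])
  d3 <- cross2(a1[, 1], a1[, 2], a2[, 1], a2[, 2], b1[, 1], b1[, 2])
  d4 <- cross2(a1[, 1], a1[, 2], a2[, 1], a2[, 2], b2[, 1], b2[, 2])
  proper <- (((d1 > tol & d2 < -tol) | (d1 < -tol & d2 > tol)) &
               ((d3 > tol & d4 < -tol) | (d3 < -tol & d4 > tol)))
  if (any(proper)) return(TRUE)
  # collinear overlap / endpoint touching between non-adjacent edges
  on_seg <- function(px, py, qx, qy, rx, ry) {
    # r collinear with p-q assumed; is r within the bounding box?
    rx <= pmax(px, qx) + tol & rx >= pmin(px, qx) - tol &
      ry <= pmax(py, qy) + tol & ry >= pmin(py, qy) - tol
  }
  t1 <- abs(d1) <= tol & on_seg(b1[, 1], b1[, 2], b2[, 1], b2[, 2], a1[, 1], a1[, 2])
  t2 <- abs(d2) <= tol & on_seg(b1[, 1], b1[, 2], b2[, 1], b2[, 2], a2[, 1], a2[, 2])
  t3 <- abs(d3) <= tol & on_seg(a1[, 1], a1[, 2], a2[, 1], a2[, 2], b1[, 1], b1[, 2])
  t4 <- abs(d4) <= tol & on_seg(a1[, 1], a1[, 2], a2[, 1], a2[, 2], b2[, 1], b2[, 2])
  any(t1 | t2 | t3 | t4)
}

# Convex hull vertices in counterclockwise order.
hull_vertices <- function(v) {
  h <- grDevices::chull(v[, 1], v[, 2]) # clockwise indices
  v[rev(h), , drop = FALSE]
}

#' Convex hull area and perimeter
#'
#' @inheritParams polygon_area_xy
#' @return Named list with `hull_area` (um^2) and `hull_perimeter` (um).
#' @keywords internal
convex_hull_xy <- function(v) {
  h <- hull_vertices(v)
  if (nrow(h) < 3 || abs(signed_area(h)) < DEGENERATE_AREA) {
    abort("invalid contour: collinear vertices (zero-width hull)",
          class = "somamorph_invalid_contour")
  }
  list(
    hull_area = abs(signed_area(h)),
    hull_perimeter = polygon_perimeter_xy(h)
  )
}

#' Feret extremes by rotating calipers
#'
#' `feret_max` is the largest vertex-pair distance of the convex hull
#' (the maximum caliper diameter); `feret_min` is the minimum width,
#' i.e. the smallest over hull edges of the maximal perpendicular
#' distance of hull vertices to that edge's supporting line. Exact for
#' polygons (the minimum width of a convex polygon is attained flush
#' against one of its edges).
#'
#' @inheritParams polygon_area_xy
#' @return Named list with `feret_max` and `feret_min`, in micrometres.
#' @keywords internal
caliper_extremes_xy <- function(v) {
  h <- hull_vertices(v)
  if (nrow(h) < 3 || abs(signed_area(h)) < DEGENERATE_AREA) {
    abort("invalid contour: collinear vertices (zero-width hull)",
          class = "somamorph_invalid_contour")
  }
  fmax <- max(dist(h))
  n <- nrow(h)
  nxt <- c(2:n, 1)
  ex <- h[nxt, 1] - h[, 1]
  ey <- h[nxt, 2] - h[, 2]
  elen <- sqrt(ex^2 + ey^2)
  # perpendicular distance of every hull vertex to every edge line:
  # |cross((v - p_edge), e)| / |e|, rows = vertices, cols = edges
  dx <- outer(h[, 1], h[, 1], "-") # dx[k, i] = x_k - x_i
  dy <- outer(h[, 2], h[, 2], "-")
  perp <- abs(sweep(dx, 2, ey, "*") - sweep(dy, 2, ex, "*"))
  widths <- apply(perp, 2, max) / elen
  list(feret_max = fmax, feret_min = min(widths))
}

# Normalize a raw vertex matrix: dedupe, check simplicity, rewind CCW.
normalize_polygon <- function(v, validate = TRUE, tol = 1e-9) {
  if (!is.matrix(v)) v <- as.matrix(v)
  storage.mode(v) <- "double"
  if (ncol(v) != 2) abort("vertices must be an n x 2 matrix")
  if (any(!is.finite(v))) abort("non-numeric or non-finite vertex coordinate")
  v <- dedupe_vertices(v, tol)
  if (nrow(v) < 3) abort("contour needs at least 3 distinct vertices",
                         class = "somamorph_invalid_contour")
  sa <- signed_area(v)
  if (abs(sa) < DEGENERATE_AREA) {
    abort("invalid contour: degenerate polygon (area below 1e-9 um^2)",
          class = "somamorph_invalid_contour")
  }
  if (validate && !is_simple_polygon(v)) {
    abort("invalid contour: polygon is self-intersecting",
          class = "somamorph_invalid_contour")
  }
  if (sa < 0) v <- v[nrow(v):1, , drop = FALSE]
  v
}
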