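# Shared fixtures and independent geometry oracles, all built in code.

unit_square <- function() rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

regular_ngon <- function(n, r = 1) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(r * cos(t), r * sin(t))
}

ellipse_ngon <- function(a, b, n = 256) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(a * cos(t), b * sin(t))
}

# Star-shaped random polygon about the origin: sorted angles with random
# radii. Angles are resampled until every circular gap is below pi so the
# origin is interior; the polygon is then simple and fan-triangulable
# from the origin.
random_simple_polygon <- function(n_vertices = 12, r_range = c(0.5, 2)) {
  repeat {
    th <- sort(runif(n_vertices, 0, 2 * pi))
    gaps <- c(diff(th), th[1] + 2 * pi - th[n_vertices])
    if (min(diff(th)) > 1e-6 && max(gaps) < 0.95 * pi) break
  }
  r <- runif(n_vertices, r_range[1], r_range[2])
  cbind(r * cos(th), r * sin(th))
}

# Four-pointed star whose convex hull is the enclosing square: outer
# points at the corners of the square with half-side `outer`, inner
# points pulled in at the edge-midpoint directions.
four_point_star <- function(outer = 2, inner = 0.5) {
  corners <- outer * rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  mids <- inner * rbind(c(0, 1), c(-1, 0), c(0, -1), c(1, 0))
  v <- matrix(NA_real_, 8, 2)
  v[seq(1, 8, 2), ] <- corners
  v[seq(2, 8, 2), ] <- mids
  v
}

# Deeply notched star: low solidity and form factor (polymorphic region).
notched_star <- function(n_points = 7, r_out = 10, r_in = 4) {
  th <- seq(0, 2 * pi, length.out = 2 * n_points + 1)[-(2 * n_points + 1)]
  r <- rep(c(r_out, r_in), n_points)
  cbind(r * cos(th), r * sin(th))
}

# --- independent oracles ------------------------------------------------

# Fan-triangulation area (star-shaped polygons, fan from vertex 1 works
# for convex; use origin fan for star-shaped-from-origin polygons).
fan_area_oracle <- function(v) {
  n <- nrow(v)
  nxt <- c(2:n, 1)
  sum(abs(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])) / 2
}

perimeter_oracle <- function(v) {
  n <- nrow(v)
  total <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    total <- total + sqrt(sum((v[i, ] - v[j, ])^2))
  }
  total
}

# Exhaustive directional width sweep in 0.01-degree steps.
feret_sweep_oracle <- function(v, step_deg = 0.01) {
  ang <- seq(0, 180 - step_deg, by = step_deg) * pi / 180
  proj <- v %*% rbind(cos(ang), sin(ang))
  widths <- apply(proj, 2, function(p) diff(range(p)))
  list(feret_min = min(widths), feret_max_lb = max(widths))
}

max_pairwise_distance_oracle <- function(v) {
  mx <- 0
  n <- nrow(v)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    mx <- max(mx, sqrt(sum((v[i, ] - v[j, ])^2)))
  }
  mx
}

# Gift-wrapping (Jarvis march) convex hull oracle.
gift_wrap_hull_oracle <- function(v) {
  n <- nrow(v)
  start <- which.min(v[, 1] + 1e-9 * v[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (p == 1) 2 else 1
    for (q in seq_len(n)) {
      if (q == p) next
      cr <- (v[cand, 1] - v[p, 1]) * (v[q, 2] - v[p, 2]) -
        (v[cand, 2] - v[p, 2]) * (v[q, 1] - v[p, 1])
      d_cand <- sum((v[cand, ] - v[p, ])^2)
      d_q <- sum((v[q, ] - v[p, ])^2)
      if (cr < 0 || (abs(cr) < 1e-12 && d_q > d_cand)) cand <- q
    }
    if (cand == start) break
    hull <- c(hull, cand)
    if (length(hull) > n) stop("gift wrap failed")
  }
  v[hull, , drop = FALSE]
}

rotate_mat <- function(v, ang) {
  cbind(cos(ang) * v[, 1] - sin(ang) * v[, 2],
        sin(ang) * v[, 1] + cos(ang) * v[, 2])
}

# Features of a raw vertex matrix via the package's public surface.
features_of <- function(v, ...) {
  somamorph::compute_features(somamorph::contour_table(list(v), ...))
}
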