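# Internal planar geometry on axis-aligned rectangles and simple polygons.
# All coordinates are projected planar meters.

new_rect <- function(xmin, ymin, xmax, ymax) {
  c(xmin = unname(xmin), ymin = unname(ymin),
    xmax = unname(xmax), ymax = unname(ymax))
}

rect_area <- function(r) {
  max(0, r["xmax"] - r["xmin"]) * max(0, r["ymax"] - r["ymin"])
}

rect_intersects <- function(a, b) {
  a["xmin"] < b["xmax"] && b["xmin"] < a["xmax"] &&
    a["ymin"] < b["ymax"] && b["ymin"] < a["ymax"]
}

# A \ B for axis-aligned rectangles: up to four residual rectangles.
rect_subtract <- function(a, b, eps = 1e-9) {
  if (!rect_intersects(a, b)) return(list(a))
  ix0 <- max(a["xmin"], b["xmin"]); ix1 <- min(a["xmax"], b["xmax"])
  iy0 <- max(a["ymin"], b["ymin"]); iy1 <- min(a["ymax"], b["ymax"])
  out <- list()
  if (ix0 - a["xmin"] > eps)
    out[[length(out) + 1L]] <- new_rect(a["xmin"], a["ymin"], ix0, a["ymax"])
  if (a["xmax"] - ix1 > eps)
    out[[length(out) + 1L]] <- new_rect(ix1, a["ymin"], a["xmax"], a["ymax"])
  if (iy0 - a["ymin"] > eps)
    out[[length(out) + 1L]] <- new_rect(ix0, a["ymin"], ix1, iy0)
  if (a["ymax"] - iy1 > eps)
    out[[length(out) + 1L]] <- new_rect(ix0, iy1, ix1, a["ymax"])
  out
}

# Closed CCW ring (5 x 2 matrix) from a rectangle.
rect_ring <- function(r) {
  matrix(c(r["xmin"], r["ymin"],
           r["xmax"], r["ymin"],
           r["xmax"], r["ymax"],
           r["xmin"], r["ymax"],
           r["xmin"], r["ymin"]),
         ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("x", "y")))
}

ring_bbox <- function(ring) {
  c(xmin = min(ring[, 1]), ymin = min(ring[, 2]),
    xmax = max(ring[, 1]), ymax = max(ring[, 2]))
}

# Shoelace area (positive for CCW rings).
ring_area <- function(ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  0.5 * sum(x[-n] * y[-1] - x[-1] * y[-n])
}

# Vectorized: are points strictly inside the ring (even-odd rule)?
# Uses the half-open crossing rule; boundary points are handled separately.
points_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n - 1L
  for (i in seq_len(n - 1L)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Vectorized: do points lie on the ring's boundary (within tol meters)?
points_on_ring <- function(px, py, ring, tol = 1e-9) {
  n <- nrow(ring)
  on <- rep(FALSE, length(px))
  for (i in seq_len(n - 1L)) {
    x1 <- ring[i, 1]; y1 <- ring[i, 2]
    x2 <- ring[i + 1L, 1]; y2 <- ring[i + 1L, 2]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - x1)^2 + (py - y1)^2
      on <- on | d2 <= tol^2
      next
    }
    t <- ((px - x1) * dx + (py - y1) * dy) / len2
    t <- pmin(1, pmax(0, t))
    d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    on <- on | d2 <= tol^2
  }
  on
}

# Containment in a polygon (outer ring + optional hole rings), boundary
# inclusive: on the outer boundary, or strictly inside the outer ring and
# not strictly inside a hole (a hole's boundary still belongs to the polygon).
points_in_polygon <- function(px, py, outer, holes = list(), tol = 1e-9) {
  inside_outer <- points_in_ring(px, py, outer)
  on_outer <- points_on_ring(px, py, outer, tol)
  strict_in_hole <- rep(FALSE, length(px))
  for (h in holes) {
    strict_in_hole <- strict_in_hole |
      (points_in_ring(px, py, h) & !points_on_ring(px, py, h, tol))
  }
  on_outer | (inside_outer & !strict_in_hole)
}
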