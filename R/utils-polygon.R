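# Planar polygon primitives shared by the geometry, tracking and meshing code.
# Polygons are n x 2 matrices of vertices in order; closure is implicit
# (vertex n connects back to vertex 1). Coordinates are millimetres.

#' Signed polygon area (shoelace formula)
#'
#' Positive for counter-clockwise (outward-oriented) polygons.
#'
#' @param p numeric matrix, n x 2, polygon vertices in order.
#' @return signed area in the square of the coordinate unit.
#' @keywords internal
polygon_area <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

#' Polygon centroid (area-weighted)
#' @keywords internal
polygon_centroid <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  cr <- p[, 1] * p[j, 2] - p[j, 1] * p[, 2]
  a <- sum(cr) / 2
  c(sum((p[, 1] + p[j, 1]) * cr), sum((p[, 2] + p[j, 2]) * cr)) / (6 * a)
}

#' Edge lengths of a closed polygon
#' @keywords internal
polygon_edge_lengths <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sqrt(rowSums((p[j, , drop = FALSE] - p)^2))
}

#' Test points for inclusion in a closed polygon
#'
#' Thin wrapper around [mgcv::in.out()].
#'
#' @param pts m x 2 matrix of query points.
#' @param poly n x 2 polygon.
#' @return logical vector of length m.
#' @keywords internal
points_in_polygon <- function(pts, poly) {
  bnd <- rbind(poly, poly[1, , drop = FALSE])
  mgcv::in.out(bnd, matrix(as.numeric(pts), ncol = 2))
}

# Proper-intersection test between segment sets (a1->a2) x (b1->b2),
# used for polygon simplicity checks. Vectorized over rows.
segments_intersect <- function(a1, a2, b1, b2) {
  cross <- function(o, p, q) {
    (p[, 1] - o[, 1]) * (q[, 2] - o[, 2]) - (p[, 2] - o[, 2]) * (q[, 1] - o[, 1])
  }
  d1 <- cross(b1, b2, a1)
  d2 <- cross(b1, b2, a2)
  d3 <- cross(a1, a2, b1)
  d4 <- cross(a1, a2, b2)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Check that a closed polygon is simple (no self-intersections)
#'
#' All non-adjacent edge pairs are tested for proper crossings.
#'
#' @param p polygon matrix.
#' @return TRUE if simple, FALSE otherwise.
#' @keywords internal
polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n < 3) return(FALSE)
  jj <- c(2:n, 1L)
  a1 <- p
  a2 <- p[jj, , drop = FALSE]
  pairs <- which(outer(seq_len(n), seq_len(n), function(i, j) {
    j > i + 1 & !(i == 1 & j == n)
  }), arr.ind = TRUE)
  if (nrow(pairs) == 0) return(TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  !any(segments_intersect(a1[i, , drop = FALSE], a2[i, , drop = FALSE],
                          a1[j, , drop = FALSE], a2[j, , drop = FALSE]))
}

#' Clip a polygon by a half-plane
#'
#' Sutherland–Hodgman clipping against the half-plane
#' \eqn{(x - point) \cdot normal \le 0} (keeps the side the normal points
#' away from).
#'
#' @param p polygon matrix.
#' @param point,normal plane point and normal (length-2 numerics).
#' @return clipped polygon matrix (possibly 0 rows).
#' @keywords internal
clip_polygon_halfplane <- function(p, point, normal) {
  n <- nrow(p)
  s <- as.vector((p[, 1] - point[1]) * normal[1] + (p[, 2] - point[2]) * normal[2])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    in_i <- s[i] <= 0
    in_j <- s[j] <= 0
    if (in_i) out <- rbind(out, p[i, ])
    if (xor(in_i, in_j)) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, p[i, ] + t * (p[j, ] - p[i, ]))
    }
  }
  out
}

# Closest points on a closed polyline (target) for a set of query points.
# Returns list(points = m x 2 foot points, dist = m distances).
closest_point_on_polyline <- function(query, poly) {
  n <- nrow(poly)
  j <- c(2:n, 1L)
  a <- poly
  b <- poly[j, , drop = FALSE]
  ab <- b - a
  len2 <- pmax(rowSums(ab^2), .Machine$double.eps)
  m <- nrow(query)
  # m x n parameter of the projection, clamped to the segment
  tx <- (outer(query[, 1], a[, 1], "-") * rep(ab[, 1], each = m) +
         outer(query[, 2], a[, 2], "-") * rep(ab[, 2], each = m)) /
        rep(len2, each = m)
  tx[tx < 0] <- 0
  tx[tx > 1] <- 1
  fx <- rep(a[, 1], each = m) + tx * rep(ab[, 1], each = m)
  fy <- rep(a[, 2], each = m) + tx * rep(ab[, 2], each = m)
  d2 <- (fx - query[, 1])^2 + (fy - query[, 2])^2
  k <- max.col(-d2, ties.method = "first")
  idx <- cbind(seq_len(m), k)
  list(points = cbind(fx[idx], fy[idx]), dist = sqrt(d2[idx]), segment = k)
}

# Resample a closed polygon to approximately uniform spacing h, preserving
# a per-edge label vector. Returns list(vertices, label) where label[i] is the
# label of edge (i, i+1).
resample_polygon <- function(p, labels, h) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  el <- polygon_edge_lengths(p)
  cum <- c(0, cumsum(el))
  total <- cum[n + 1]
  m <- max(8L, round(total / h))
  s <- seq(0, total, length.out = m + 1)[-(m + 1)]
  edge <- findInterval(s, cum, rightmost.closed = TRUE)
  edge[edge > n] <- n
  t <- (s - cum[edge]) / el[edge]
  v <- p[edge, , drop = FALSE] + t * (p[j, , drop = FALSE] - p)[edge, , drop = FALSE]
  # label of the outgoing edge from each resampled vertex: take the label at
  # the midpoint of each resampled edge
  smid <- (s + c(s[-1], total)) / 2
  emid <- findInterval(smid, cum, rightmost.closed = TRUE)
  emid[emid > n] <- n
  list(vertices = v, label = labels[emid])
}
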