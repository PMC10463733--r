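# Graded unstructured triangle meshing of a closed polygonal chamber.
# Boundary nodes are fixed (a resampling of the input polygon at the wall
# edge length); interior nodes start from a quasi-random graded seed and are
# relaxed by a few force-equilibrium sweeps (DistMesh-style truss forces with
# repulsion only), re-triangulating with Delaunay (deldir) between sweeps.
# Triangles whose centroid falls outside the polygon are discarded, which
# also removes convex-hull slivers across the appendage neck.

# deldir prints allocation diagnostics to stdout; keep the console clean
.quiet_deldir <- function(nodes) {
  out <- NULL
  utils::capture.output(
    out <- deldir::deldir(nodes[, 1], nodes[, 2], suppressMsge = TRUE))
  out
}

#' Build a graded triangle mesh of a chamber cross-section
#'
#' @param boundary n x 2 closed CCW polygon (mm).
#' @param labels per-edge region labels of `boundary` (length n); defaults
#'   to `"wall"`.
#' @param wall_edge_length target boundary edge length (mm).
#' @param max_edge_length maximum interior edge length (mm).
#' @param grading growth rate of the target edge length with distance from
#'   the wall (dimensionless).
#' @param n_sweeps relaxation sweeps.
#' @return object of class `flow_mesh`: `nodes` (N x 2 mm), `tri` (T x 3,
#'   CCW), `boundary` (tibble: `a`, `b` node ids along the boundary,
#'   `label`), `n_boundary` (boundary nodes come first), and `h_wall`.
#' @export
build_mesh <- function(boundary, labels = NULL,
                       wall_edge_length = 2, max_edge_length = 8,
                       grading = 0.35, n_sweeps = 16L) {
  stopifnot(is.matrix(boundary), ncol(boundary) == 2)
  if (polygon_area(boundary) <= 0) {
    stop("boundary must be closed and counter-clockwise oriented",
         call. = FALSE)
  }
  if (!polygon_is_simple(boundary)) {
    stop("boundary polygon is self-intersecting", call. = FALSE)
  }
  if (is.null(labels)) labels <- rep("wall", nrow(boundary))
  rs <- resample_polygon(boundary, labels, wall_edge_length)
  bnd <- rs$vertices
  nb <- nrow(bnd)
  hsize <- function(p) {
    d <- closest_point_on_polyline(p, bnd)$dist
    pmin(wall_edge_length + grading * d, max_edge_length)
  }
  # quasi-random graded interior seed (golden-ratio thinning: deterministic)
  lo <- apply(bnd, 2, min); hi <- apply(bnd, 2, max)
  gx <- seq(lo[1], hi[1], by = wall_edge_length)
  gy <- seq(lo[2], hi[2], by = wall_edge_length * sqrt(3) / 2)
  cand <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  odd <- rep(seq_along(gy) %% 2 == 1, each = length(gx))
  cand[odd, 1] <- cand[odd, 1] + wall_edge_length / 2
  inside <- points_in_polygon(cand, bnd)
  d2b <- closest_point_on_polyline(cand, bnd)$dist
  keep <- inside & d2b > 0.6 * wall_edge_length
  cand <- cand[keep, , drop = FALSE]
  prob <- (wall_edge_length / hsize(cand))^2
  u <- (0.5 + (seq_len(nrow(cand)) * 0.6180339887498949)) %% 1
  pts <- cand[u < prob, , drop = FALSE]

  nodes <- rbind(bnd, pts)
  for (sweep in seq_len(n_sweeps)) {
    dd <- .quiet_deldir(nodes)
    e <- cbind(dd$delsgs$ind1, dd$delsgs$ind2)
    mid <- (nodes[e[, 1], , drop = FALSE] + nodes[e[, 2], , drop = FALSE]) / 2
    vec <- nodes[e[, 2], , drop = FALSE] - nodes[e[, 1], , drop = FALSE]
    len <- sqrt(rowSums(vec^2))
    l0 <- 1.2 * hsize(mid)
    f <- pmax(l0 - len, 0) / pmax(len, 1e-12)
    fx <- f * vec[, 1]; fy <- f * vec[, 2]
    mvx <- mvy <- numeric(nrow(nodes))
    mvx <- mvx + unname(tapply(c(-fx, fx), c(e[, 1], e[, 2]), sum)[
      as.character(seq_len(nrow(nodes)))])
    mvy <- mvy + unname(tapply(c(-fy, fy), c(e[, 1], e[, 2]), sum)[
      as.character(seq_len(nrow(nodes)))])
    mvx[is.na(mvx)] <- 0; mvy[is.na(mvy)] <- 0
    mv <- cbind(mvx, mvy) * 0.25
    mv[seq_len(nb), ] <- 0
    nodes <- nodes + mv
    # project escaped interior nodes back inside
    int_idx <- (nb + 1):nrow(nodes)
    out <- !points_in_polygon(nodes[int_idx, , drop = FALSE], bnd)
    if (any(out)) {
      cp <- closest_point_on_polyline(
        nodes[int_idx[out], , drop = FALSE], bnd)
      inward <- polygon_centroid(bnd)
      prj <- cp$points
      prj <- prj + 0.3 * wall_edge_length *
        (matrix(inward, nrow(prj), 2, byrow = TRUE) - prj) /
        pmax(sqrt(rowSums((matrix(inward, nrow(prj), 2, byrow = TRUE) - prj)^2)), 1e-9)
      nodes[int_idx[out], ] <- prj
    }
  }
  # drop interior nodes that ended up hugging the boundary (slivers)
  int_idx <- (nb + 1):nrow(nodes)
  if (length(int_idx) > 0 && int_idx[1] <= nrow(nodes)) {
    dmin <- closest_point_on_polyline(nodes[int_idx, , drop = FALSE], bnd)$dist
    nodes <- rbind(bnd, nodes[int_idx[dmin > 0.45 * wall_edge_length], ,
                              drop = FALSE])
  }
  mesh <- .finalize_mesh(nodes, nb, bnd, rs$label, wall_edge_length)
  mesh
}

.finalize_mesh <- function(nodes, nb, bnd, bnd_label, h_wall) {
  dd <- .quiet_deldir(nodes)
  tri <- deldir::triMat(dd)
  cen <- (nodes[tri[, 1], , drop = FALSE] + nodes[tri[, 2], , drop = FALSE] +
          nodes[tri[, 3], , drop = FALSE]) / 3
  tri <- tri[points_in_polygon(cen, bnd), , drop = FALSE]
  # enforce CCW triangles
  d <- (nodes[tri[, 2], 1] - nodes[tri[, 1], 1]) *
       (nodes[tri[, 3], 2] - nodes[tri[, 1], 2]) -
       (nodes[tri[, 3], 1] - nodes[tri[, 1], 1]) *
       (nodes[tri[, 2], 2] - nodes[tri[, 1], 2])
  flip <- d < 0
  tri[flip, ] <- tri[flip, c(1, 3, 2)]
  if (any(abs(d) < 1e-12)) {
    stop("meshing produced a degenerate (zero-area) cell", call. = FALSE)
  }
  # verify that all consecutive boundary segments are mesh edges
  edge_key <- c(paste(tri[, 1], tri[, 2]), paste(tri[, 2], tri[, 3]),
                paste(tri[, 3], tri[, 1]),
                paste(tri[, 2], tri[, 1]), paste(tri[, 3], tri[, 2]),
                paste(tri[, 1], tri[, 3]))
  bseq <- cbind(seq_len(nb), c(2:nb, 1L))
  missing <- !(paste(bseq[, 1], bseq[, 2]) %in% edge_key)
  if (any(missing)) {
    stop("mesh does not conform to the boundary near segment(s) ",
         paste(which(missing)[seq_len(min(3, sum(missing)))], collapse = ", "),
         "; refine wall_edge_length", call. = FALSE)
  }
  structure(list(nodes = nodes, tri = tri, n_boundary = nb,
                 boundary = tibble::tibble(a = bseq[, 1], b = bseq[, 2],
                                           label = bnd_label),
                 h_wall = h_wall),
            class = "flow_mesh")
}

#' Triangle areas of a flow mesh
#' @param mesh a `flow_mesh` (or list with `nodes`, `tri`).
#' @return numeric vector of triangle areas (coordinate units squared).
#' @export
mesh_areas <- function(mesh) {
  n <- mesh$nodes; tr <- mesh$tri
  ((n[tr[, 2], 1] - n[tr[, 1], 1]) * (n[tr[, 3], 2] - n[tr[, 1], 2]) -
   (n[tr[, 3], 1] - n[tr[, 1], 1]) * (n[tr[, 2], 2] - n[tr[, 1], 2])) / 2
}

#' @export
print.flow_mesh <- function(x, ...) {
  cat("<flow_mesh>", nrow(x$nodes), "nodes,", nrow(x$tri), "cells,",
      x$n_boundary, "boundary nodes, area",
      sprintf("%.1f mm^2\n", sum(mesh_areas(x))))
  invisible(x)
}

# Locate query points in a mesh: returns triangle index (NA if outside) and
# barycentric coordinates. Vectorized over points x triangles.
locate_points <- function(mesh, pts, tol = 1e-9) {
  n <- mesh$nodes; tr <- mesh$tri
  m <- nrow(pts)
  Tn <- nrow(tr)
  x1 <- n[tr[, 1], 1]; y1 <- n[tr[, 1], 2]
  x2 <- n[tr[, 2], 1]; y2 <- n[tr[, 2], 2]
  x3 <- n[tr[, 3], 1]; y3 <- n[tr[, 3], 2]
  det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
  # m x T barycentric coordinate matrices
  px3 <- outer(pts[, 1], x3, "-")
  py3 <- outer(pts[, 2], y3, "-")
  w1 <- (px3 * rep((y2 - y3) / det, each = m) +
         py3 * rep((x3 - x2) / det, each = m))
  w2 <- (px3 * rep((y3 - y1) / det, each = m) +
         py3 * rep((x1 - x3) / det, each = m))
  w3 <- 1 - w1 - w2
  ok <- w1 >= -tol & w2 >= -tol & w3 >= -tol
  hit <- max.col(ok, ties.method = "first")
  found <- ok[cbind(seq_len(m), hit)]
  tri_id <- ifelse(found, hit, NA_integer_)
  bary <- matrix(NA_real_, m, 3)
  idx <- which(found)
  bary[idx, 1] <- w1[cbind(idx, hit[idx])]
  bary[idx, 2] <- w2[cbind(idx, hit[idx])]
  bary[idx, 3] <- w3[cbind(idx, hit[idx])]
  list(tri = tri_id, bary = bary)
}
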