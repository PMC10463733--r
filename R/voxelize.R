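# Rasterization of chamber boundaries to binary masks, emulating
# threshold-based segmentations, and contour extraction back from masks.
# Masks are voxel-centred with 0-based index origin stored in world
# coordinates (mm).

#' Voxelize a surface series to per-phase binary masks
#'
#' Rasterizes each phase of a chamber boundary on a regular voxel grid:
#' a voxel belongs to a chamber if its centre lies inside the closed
#' boundary. In 2D the "voxels" are pixels of size `voxel_size` squared;
#' the mask volume follows the same depth convention as the series.
#'
#' @param series a `surface_series`, or a single closed polygon matrix
#'   (2D) / `vertices`-`triangles` list (3D).
#' @param voxel_size isotropic voxel edge length (mm); must be positive and
#'   finer than the chambers.
#' @param component for a series: `"la"`, `"lv"` or `"both"` (labels 1, 2).
#' @param padding_mm grid margin around the union bounding box.
#' @return an object of class `mask_series`: list with `masks` (per-phase
#'   integer arrays: 0 background, 1 LA, 2 LV), `origin` (world coordinate
#'   of the centre of voxel \[1, 1(, 1)\]), `voxel_size`, and `depth_mm`.
#'   For a single boundary input, a single-phase `mask_series`.
#' @export
voxelize <- function(series, voxel_size, component = c("both", "la", "lv"),
                     padding_mm = 3 * voxel_size) {
  component <- match.arg(component)
  if (!is.numeric(voxel_size) || length(voxel_size) != 1 ||
      !is.finite(voxel_size) || voxel_size <= 0) {
    stop("voxel_size must be a positive length in mm", call. = FALSE)
  }
  single <- !inherits(series, "surface_series")
  if (single) {
    polys <- list(list(series))
    labels <- 1L
    depth <- attr(series, "depth_mm") %||% NA_real_
    dim_n <- if (is.matrix(series)) 2L else 3L
  } else {
    dim_n <- series$dimension
    depth <- series$depth_mm
    labels <- switch(component, both = c(1L, 2L), la = 1L, lv = 2L)
    polys <- lapply(seq_along(series$phases), function(k) {
      lapply(labels, function(comp) {
        if (dim_n == 2L) {
          series_polygon(series, k, if (comp == 1L) "la" else "lv")$vertices
        } else {
          idx <- series$component_vertices[[if (comp == 1L) "la" else "lv"]]
          keep <- series$component == comp
          fl <- series$facets[keep, , drop = FALSE]
          fl[] <- match(fl, idx)
          list(vertices = series$phases[[k]][idx, , drop = FALSE],
               triangles = fl)
        }
      })
    })
  }
  # common grid over the union of all phases
  allv <- do.call(rbind, lapply(polys, function(ph) {
    do.call(rbind, lapply(ph, function(p) if (is.matrix(p)) p else p$vertices))
  }))
  lo <- apply(allv, 2, min) - padding_mm
  hi <- apply(allv, 2, max) + padding_mm
  nvox <- pmax(2L, ceiling((hi - lo) / voxel_size))
  origin <- lo + voxel_size / 2
  axes <- lapply(seq_len(dim_n), function(d) {
    origin[d] + voxel_size * (seq_len(nvox[d]) - 1)
  })
  masks <- lapply(polys, function(ph) {
    m <- array(0L, dim = nvox)
    for (ci in seq_along(ph)) {
      p <- ph[[ci]]
      if (is.matrix(p)) {
        pts <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]]))
        inside <- points_in_polygon(pts, p)
        m[array(inside, dim = nvox)] <- labels[ci]
      } else {
        inside <- .points_in_trimesh(axes, p$vertices, p$triangles)
        m[inside] <- labels[ci]
      }
    }
    m
  })
  for (k in seq_along(masks)) {
    if (!any(masks[[k]] > 0)) {
      stop("voxel_size too coarse: empty mask at phase ", k, call. = FALSE)
    }
  }
  structure(list(masks = masks, origin = origin, voxel_size = voxel_size,
                 depth_mm = depth, dimension = dim_n,
                 phase_fractions = if (single) 0 else series$phase_fractions,
                 rr_interval = if (single) NA_real_ else series$rr_interval),
            class = "mask_series")
}

# z-column parity ray casting against a closed triangulated surface
.points_in_trimesh <- function(axes, v, f) {
  nx <- length(axes[[1]]); ny <- length(axes[[2]]); nz <- length(axes[[3]])
  inside <- array(FALSE, dim = c(nx, ny, nz))
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  for (ix in seq_len(nx)) {
    px <- axes[[1]][ix]
    for (iy in seq_len(ny)) {
      py <- axes[[2]][iy]
      # 2D point-in-triangle test in the xy projection
      d <- (b[, 2] - cc[, 2]) * (a[, 1] - cc[, 1]) +
           (cc[, 1] - b[, 1]) * (a[, 2] - cc[, 2])
      w1 <- ((b[, 2] - cc[, 2]) * (px - cc[, 1]) +
             (cc[, 1] - b[, 1]) * (py - cc[, 2])) / d
      w2 <- ((cc[, 2] - a[, 2]) * (px - cc[, 1]) +
             (a[, 1] - cc[, 1]) * (py - cc[, 2])) / d
      w3 <- 1 - w1 - w2
      hit <- which(is.finite(w1) & w1 >= 0 & w2 >= 0 & w3 >= 0)
      if (length(hit) == 0) next
      zhit <- w1[hit] * a[hit, 3] + w2[hit] * b[hit, 3] + w3[hit] * cc[hit, 3]
      zhit <- sort(zhit)
      cnt <- vapply(axes[[3]], function(z) sum(zhit > z), integer(1))
      inside[ix, iy, ] <- cnt %% 2L == 1L
    }
  }
  inside
}

#' Total mask volume
#'
#' @param mask a `mask_series`.
#' @param phase phase index.
#' @param label chamber label (1 LA, 2 LV); 0 counts all nonzero voxels.
#' @return volume in ml (2D masks use the series depth convention).
#' @export
mask_volume <- function(mask, phase = 1L, label = 0L) {
  m <- mask$masks[[phase]]
  n <- if (label == 0L) sum(m > 0) else sum(m == label)
  if (mask$dimension == 2L) {
    n * mask$voxel_size^2 * mask$depth_mm / 1000
  } else {
    n * mask$voxel_size^3 / 1000
  }
}

#' Extract the boundary contour of a 2D mask
#'
#' Marching-squares isocontour at level 0.5 via [grDevices::contourLines()];
#' the largest closed contour of the requested label is returned in world
#' coordinates.
#'
#' @param mask a `mask_series` (2D).
#' @param phase phase index.
#' @param label chamber label to contour.
#' @return an n x 2 polygon matrix (mm), counter-clockwise.
#' @export
mask_contour <- function(mask, phase = 1L, label = 1L) {
  stopifnot(inherits(mask, "mask_series"))
  if (mask$dimension != 2L) {
    stop("mask_contour() supports 2D masks", call. = FALSE)
  }
  m <- mask$masks[[phase]] == label
  if (!any(m)) stop("mask has no voxels with label ", label, call. = FALSE)
  x <- mask$origin[1] + mask$voxel_size * (seq_len(nrow(m)) - 1)
  y <- mask$origin[2] + mask$voxel_size * (seq_len(ncol(m)) - 1)
  cl <- grDevices::contourLines(x, y, m + 0, levels = 0.5)
  if (length(cl) == 0) stop("no contour found", call. = FALSE)
  areas <- vapply(cl, function(cc) abs(polygon_area(cbind(cc$x, cc$y))),
                  numeric(1))
  best <- cl[[which.max(areas)]]
  p <- cbind(best$x, best$y)
  # drop duplicated closing vertex if present
  if (all(abs(p[1, ] - p[nrow(p), ]) < 1e-12)) p <- p[-nrow(p), , drop = FALSE]
  if (polygon_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  p
}
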