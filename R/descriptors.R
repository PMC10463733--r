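# Morphological and functional chamber descriptors: volumes by the
# divergence theorem, ejection fractions, the LA retention ratio, peak
# transvalvular flow rates from the LV volume curve, BSA indexing, and the
# ostium-plane split of the appendage.

#' Volume enclosed by a closed boundary
#'
#' Computes the signed divergence-theorem volume of a closed, consistently
#' outward-oriented boundary: the shoelace area times the out-of-plane depth
#' for a planar polygon, or the summed signed tetrahedron volumes for a
#' triangulated surface. Coordinates are in mm; the result is in ml.
#'
#' @param boundary either an n x 2 matrix (closed planar polygon, vertices
#'   in order) or a list with `vertices` (n x 3) and `triangles` (m x 3).
#' @param depth_mm out-of-plane depth (mm), required for 2D polygons.
#' @param check if TRUE (default) verify closedness/simplicity and
#'   orientation, erroring on violation.
#' @return volume in ml.
#' @examples
#' sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
#' mesh_volume(sq, depth_mm = 10)  # 1 ml
#' @export
mesh_volume <- function(boundary, depth_mm = NULL, check = TRUE) {
  if (is.matrix(boundary) && ncol(boundary) == 2) {
    if (is.null(depth_mm)) {
      stop("depth_mm is required to express a planar area as a volume",
           call. = FALSE)
    }
    a <- polygon_area(boundary)
    if (check) {
      if (nrow(boundary) < 3) stop("boundary is degenerate", call. = FALSE)
      if (a < 0) {
        stop("orientation error: boundary is clockwise (signed volume < 0)",
             call. = FALSE)
      }
      if (!polygon_is_simple(boundary)) {
        stop("boundary is self-intersecting", call. = FALSE)
      }
    }
    return(a * depth_mm / 1000)
  }
  if (is.list(boundary) && !is.null(boundary$vertices) &&
      !is.null(boundary$triangles)) {
    v <- boundary$vertices
    f <- boundary$triangles
    vol <- .tri_mesh_volume(v, f)
    if (check) {
      if (!.trimesh_is_closed(f)) {
        stop("boundary surface is not closed", call. = FALSE)
      }
      if (vol < 0) {
        stop("orientation error: surface is inward-oriented (signed volume < 0)",
             call. = FALSE)
      }
    }
    return(vol / 1000)
  }
  stop("boundary must be an n x 2 polygon matrix or a vertices/triangles list",
       call. = FALSE)
}

# every directed edge must appear exactly once together with its reverse
.trimesh_is_closed <- function(f) {
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  key <- paste(e[, 1], e[, 2])
  rev <- paste(e[, 2], e[, 1])
  !anyDuplicated(key) && all(rev %in% key)
}

#' Ejection fraction
#'
#' @param v_max,v_min maximal and minimal chamber volume (ml).
#' @return ejection fraction in percent: `100 * (v_max - v_min) / v_max`.
#' @examples
#' ejection_fraction(100, 50)  # 50
#' @export
ejection_fraction <- function(v_max, v_min) {
  if (any(v_max <= 0)) stop("v_max must be > 0", call. = FALSE)
  if (any(v_min < 0)) stop("v_min must be >= 0", call. = FALSE)
  if (any(v_min > v_max)) stop("v_min exceeds v_max", call. = FALSE)
  100 * (v_max - v_min) / v_max
}

#' LA retention ratio
#'
#' The ratio of the maximum atrial volume to the ventricular stroke volume:
#' how much blood the atrium can hold relative to how much passes per
#' heartbeat. A dimensionless functional descriptor of atrial reservoir
#' function; values well above 1 indicate that the atrium holds more blood
#' than it passes on each beat.
#'
#' @param la_max_vol maximum LA volume (ml).
#' @param lv_sv LV stroke volume (ml), must be > 0.
#' @return dimensionless ratio.
#' @examples
#' retention_ratio(41 * 2.13, 98)   # control-like group means
#' retention_ratio(66 * 2.02, 106)  # AF-like group means
#' @export
retention_ratio <- function(la_max_vol, lv_sv) {
  if (any(lv_sv <= 0)) stop("lv_sv must be > 0", call. = FALSE)
  la_max_vol / lv_sv
}

#' Index a volume by body surface area
#'
#' @param value volume (ml).
#' @param bsa body surface area (m^2), must be > 0.
#' @return indexed value (ml/m^2).
#' @export
index_by_bsa <- function(value, bsa) {
  if (any(bsa <= 0)) stop("bsa must be > 0", call. = FALSE)
  value / bsa
}

#' Peak transvalvular flow rates from an LV volume curve
#'
#' Differentiates the periodic LV volume curve with a periodic cubic spline.
#' Flows are signed positive in the physiologic direction: the peak aortic
#' flow is the largest ejection rate (`max(-dV/dt)` while the ventricle
#' empties) and the peak mitral flow is the largest filling rate
#' (`max(+dV/dt)`).
#'
#' @param volume_curve per-phase LV volumes (ml) sampled at equal fractions
#'   of the cycle starting at phase 0 (no duplicated endpoint).
#' @param rr_interval cycle length (s).
#' @return tibble with `peak_mitral_flow` and `peak_aortic_flow` (ml/s).
#' @export
flow_rates <- function(volume_curve, rr_interval) {
  n <- length(volume_curve)
  if (n < 4) stop("volume curve needs at least 4 phases", call. = FALSE)
  if (!is.numeric(rr_interval) || rr_interval <= 0) {
    stop("rr_interval must be a positive duration in seconds", call. = FALSE)
  }
  t <- seq(0, rr_interval, length.out = n + 1)
  f <- stats::splinefun(t, c(volume_curve, volume_curve[1]), method = "periodic")
  tt <- seq(0, rr_interval, length.out = 20 * n + 1)
  dv <- f(tt, deriv = 1)
  tibble::tibble(peak_mitral_flow = max(pmax(dv, 0)),
                 peak_aortic_flow = max(pmax(-dv, 0)))
}

#' Split the appendage from the atrial body at the ostium plane
#'
#' Partitions a closed LA boundary into the appendage (the part on the side
#' the plane normal points to) and the atrial body, capping the cut
#' cross-section so both parts are closed. The two part volumes sum to the
#' total volume up to floating-point error.
#'
#' @param surface an n x 2 polygon matrix (2D) or `vertices`/`triangles`
#'   list (3D); alternatively a `surface_series`, in which case `phase` and
#'   its stored ostium plane are used.
#' @param point,normal the ostium plane; `normal` points towards the
#'   appendage. Taken from the series when `surface` is a `surface_series`.
#' @param depth_mm depth for the 2D volume convention (taken from the series
#'   if available).
#' @param phase phase index when `surface` is a series.
#' @return list with `la_body` and `laa` (closed boundaries of the two
#'   parts), and `v_la_body`, `v_laa`, `v_total` in ml.
#' @export
split_laa <- function(surface, point = NULL, normal = NULL, depth_mm = NULL,
                      phase = 1L) {
  if (inherits(surface, "surface_series")) {
    os <- surface$ostium[[phase]]
    if (is.null(point)) point <- os$point
    if (is.null(normal)) normal <- os$normal
    if (is.null(depth_mm)) depth_mm <- surface$depth_mm
    if (surface$dimension == 2L) {
      surface <- series_polygon(surface, phase, "la")$vertices
    } else {
      idx <- surface$component_vertices$la
      keep <- surface$component == 1L
      surface <- list(vertices = surface$phases[[phase]][idx, , drop = FALSE],
                      triangles = surface$facets[keep, , drop = FALSE])
    }
  }
  normal <- normal / sqrt(sum(normal^2))
  if (is.matrix(surface) && ncol(surface) == 2) {
    s <- (surface[, 1] - point[1]) * normal[1] +
         (surface[, 2] - point[2]) * normal[2]
    eps <- 1e-9 * max(abs(s))
    sgn <- sign(s)[abs(s) > eps]            # ignore on-plane vertices
    crossings <- sum(diff(c(sgn, sgn[1])) != 0)
    if (all(s <= eps)) stop("ostium plane misses the appendage (empty LAA)",
                            call. = FALSE)
    if (all(s >= -eps)) stop("ostium plane misses the atrial body",
                             call. = FALSE)
    if (crossings > 2) {
      stop("ostium plane produces more than one appendage component",
           call. = FALSE)
    }
    laa <- clip_polygon_halfplane(surface, point, -normal)
    body <- clip_polygon_halfplane(surface, point, normal)
    v_laa <- polygon_area(laa) * depth_mm / 1000
    v_body <- polygon_area(body) * depth_mm / 1000
    return(list(la_body = body, laa = laa,
                v_la_body = v_body, v_laa = v_laa,
                v_total = polygon_area(surface) * depth_mm / 1000))
  }
  if (is.list(surface) && !is.null(surface$triangles)) {
    laa <- clip_trimesh_halfplane(surface$vertices, surface$triangles,
                                  point, -normal)
    body <- clip_trimesh_halfplane(surface$vertices, surface$triangles,
                                   point, normal)
    if (nrow(laa$triangles) == 0) {
      stop("ostium plane misses the appendage (empty LAA)", call. = FALSE)
    }
    if (nrow(body$triangles) == 0) {
      stop("ostium plane misses the atrial body", call. = FALSE)
    }
    return(list(la_body = body, laa = laa,
                v_la_body = .tri_mesh_volume(body$vertices, body$triangles) / 1000,
                v_laa = .tri_mesh_volume(laa$vertices, laa$triangles) / 1000,
                v_total = .tri_mesh_volume(surface$vertices,
                                           surface$triangles) / 1000))
  }
  stop("unsupported surface representation", call. = FALSE)
}

# Clip a closed triangulated surface against the half-space
# (x - point) . normal <= 0 and cap the cut with a fan, keeping the surface
# closed and outward-oriented.
clip_trimesh_halfplane <- function(v, f, point, normal) {
  s <- as.vector((v[, 1] - point[1]) * normal[1] +
                 (v[, 2] - point[2]) * normal[2] +
                 (v[, 3] - point[3]) * normal[3])
  keep_tri <- list()
  cap_a <- NULL
  cap_b <- NULL
  verts <- v
  add_vertex <- function(p) {
    verts <<- rbind(verts, p)
    nrow(verts)
  }
  isect <- function(i, j) {
    t <- s[i] / (s[i] - s[j])
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  for (k in seq_len(nrow(f))) {
    id <- f[k, ]
    inside <- s[id] <= 0
    n_in <- sum(inside)
    if (n_in == 3) {
      keep_tri[[length(keep_tri) + 1L]] <- id
    } else if (n_in == 0) {
      next
    } else {
      # rotate so that the pattern starts with the kept vertices
      for (r in 0:2) {
        idr <- id[(c(0, 1, 2) + r) %% 3 + 1]
        insr <- s[idr] <= 0
        if ((n_in == 1 && insr[1] && !insr[2] && !insr[3]) ||
            (n_in == 2 && insr[1] && insr[2] && !insr[3])) {
          id <- idr; inside <- insr; break
        }
      }
      if (n_in == 1) {
        p1 <- add_vertex(isect(id[1], id[2]))
        p2 <- add_vertex(isect(id[1], id[3]))
        keep_tri[[length(keep_tri) + 1L]] <- c(id[1], p1, p2)
        cap_a <- c(cap_a, p1); cap_b <- c(cap_b, p2)
      } else {
        p1 <- add_vertex(isect(id[2], id[3]))
        p2 <- add_vertex(isect(id[1], id[3]))
        keep_tri[[length(keep_tri) + 1L]] <- c(id[1], id[2], p1)
        keep_tri[[length(keep_tri) + 1L]] <- c(id[1], p1, p2)
        cap_a <- c(cap_a, p1); cap_b <- c(cap_b, p2)
      }
    }
  }
  if (length(keep_tri) == 0) {
    return(list(vertices = verts, triangles = matrix(integer(0), 0, 3)))
  }
  tri <- do.call(rbind, keep_tri)
  if (length(cap_a) > 0) {
    c0 <- add_vertex(colMeans(verts[c(cap_a, cap_b), , drop = FALSE]))
    # kept surface traverses each cut edge a -> b; the cap takes b -> a
    cap <- cbind(rep(c0, length(cap_a)), cap_b, cap_a)
    tri <- rbind(tri, cap)
  }
  list(vertices = verts, triangles = tri)
}

#' Compute the full descriptor set of a chamber series
#'
#' Extracts per-phase LA body, LAA and LV volumes from the surface geometry
#' (splitting the appendage at the stored ostium plane), then derives the
#' scalar descriptors: extreme volumes, ejection fractions, stroke volume,
#' peak transvalvular flow rates, BSA-indexed variants and the LA retention
#' ratio.
#'
#' @param series a `surface_series`.
#' @param bsa body surface area (m^2); defaults to the generating spec's.
#' @return a one-row tibble (class `descriptor_set`) of descriptors; the
#'   per-phase volume curves are attached as the `"curves"` attribute.
#' @examples
#' d <- compute_descriptors(generate_chamber_series(chamber_spec()))
#' d$la_ef
#' @export
compute_descriptors <- function(series, bsa = NULL) {
  stopifnot(inherits(series, "surface_series"))
  if (is.null(bsa)) bsa <- series$spec$bsa %||% NA_real_
  np <- length(series$phases)
  v_la <- v_laa <- v_lv <- numeric(np)
  for (k in seq_len(np)) {
    sp <- split_laa(series, phase = k)
    v_la[k] <- sp$v_la_body
    v_laa[k] <- sp$v_laa
    if (series$dimension == 2L) {
      v_lv[k] <- mesh_volume(series_polygon(series, k, "lv")$vertices,
                             depth_mm = series$depth_mm, check = FALSE)
    } else {
      idx <- series$component_vertices$lv
      keep <- series$component == 2L
      fl <- series$facets[keep, , drop = FALSE]
      fl[] <- match(fl, idx)
      v_lv[k] <- mesh_volume(list(vertices = series$phases[[k]][idx, , drop = FALSE],
                                  triangles = fl), check = FALSE)
    }
  }
  lv_edv <- max(v_lv); lv_esv <- min(v_lv)
  lv_sv <- lv_edv - lv_esv
  pk <- flow_rates(v_lv, series$rr_interval)
  out <- tibble::tibble(
    la_min_vol = min(v_la), la_max_vol = max(v_la),
    laa_min_vol = min(v_laa), laa_max_vol = max(v_laa),
    lv_esv = lv_esv, lv_edv = lv_edv,
    la_ef = ejection_fraction(max(v_la), min(v_la)),
    laa_ef = ejection_fraction(max(v_laa), min(v_laa)),
    lv_ef = ejection_fraction(lv_edv, lv_esv),
    lv_sv = lv_sv,
    peak_mitral_flow = pk$peak_mitral_flow,
    peak_aortic_flow = pk$peak_aortic_flow,
    la_retention_ratio = retention_ratio(max(v_la), lv_sv),
    bsa = bsa,
    la_min_vol_idx = index_by_bsa(min(v_la), bsa),
    la_max_vol_idx = index_by_bsa(max(v_la), bsa),
    laa_min_vol_idx = index_by_bsa(min(v_laa), bsa),
    laa_max_vol_idx = index_by_bsa(max(v_laa), bsa),
    lv_esv_idx = index_by_bsa(lv_esv, bsa),
    lv_edv_idx = index_by_bsa(lv_edv, bsa)
  )
  attr(out, "curves") <- tibble::tibble(
    phase_fraction = series$phase_fractions,
    v_la = v_la, v_laa = v_laa, v_lv = v_lv
  )
  class(out) <- c("descriptor_set", class(out))
  out
}

#' Render descriptors with clinical report column names
#'
#' Returns the descriptor record with display headers as used in clinical
#' group-comparison tables (indexed volumes in ml/m^2, EFs in percent).
#'
#' @param descriptors output of [compute_descriptors()] (any number of rows).
#' @return tibble with renamed columns.
#' @export
descriptor_table <- function(descriptors) {
  map <- c(
    "LA Min Volume,Idx (ml/m^2)" = "la_min_vol_idx",
    "LA Max Volume,Idx (ml/m^2)" = "la_max_vol_idx",
    "LA EF (%)" = "la_ef",
    "LAA Min Volume,Idx (ml/m^2)" = "laa_min_vol_idx",
    "LAA Max Volume,Idx (ml/m^2)" = "laa_max_vol_idx",
    "LAA EF (%)" = "laa_ef",
    "LV End Systolic Volume,Idx (ml/m^2)" = "lv_esv_idx",
    "LV End Diastolic Volume,Idx (ml/m^2)" = "lv_edv_idx",
    "LV EF (%)" = "lv_ef",
    "LV Stroke Volume (ml)" = "lv_sv",
    "LA retention ratio (-)" = "la_retention_ratio"
  )
  out <- descriptors[, map, drop = FALSE]
  names(out) <- names(map)
  tibble::as_tibble(out)
}
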