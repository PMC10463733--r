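# Coarse optional 3D mode: the 2D cross-section (spherical LA body,
# cone-frustum neck, spherical pouch, spherical LV) revolved about the neck
# axis. Region volumes are analytic (sphere minus cap plus frustum), so the
# radii at each phase are solved exactly; the triangulated surface
# underestimates them by O(h^2), which stays well below a percent at the
# default resolution. Tracking and the flow solvers operate on the 2D mode;
# the 3D series supports the geometric descriptor layer.

.cap_volume <- function(R, h) pi * h^2 * (3 * R - h) / 3

.pouch_volume_3d <- function(R, w2) {
  h_p <- sqrt(pmax(R^2 - w2^2, 0))
  4 / 3 * pi * R^3 - .cap_volume(R, R - h_p)
}

.solve_pouch_radius_3d <- function(vol, w) {
  w2 <- w / 2
  lo <- w2 * 1.000001
  if (.pouch_volume_3d(lo, w2) >= vol) {
    stop("LAA volume too small for the requested ostium width", call. = FALSE)
  }
  stats::uniroot(function(R) .pouch_volume_3d(R, w2) - vol,
                 lower = lo, upper = max(10 * w, (vol * 3 / (4 * pi))^(1 / 3) * 4),
                 tol = 1e-12)$root
}

.body_volume_3d <- function(R, w_b, w_n, L_n) {
  w2 <- w_b / 2
  h_b <- sqrt(pmax(R^2 - w2^2, 0))
  r1 <- w_b / 2; r2 <- w_n / 2
  4 / 3 * pi * R^3 - .cap_volume(R, R - h_b) +
    pi * L_n * (r1^2 + r1 * r2 + r2^2) / 3
}

.solve_body_radius_3d <- function(vol, w_b, w_n, L_n) {
  lo <- (w_b / 2) * 1.000001
  if (.body_volume_3d(lo, w_b, w_n, L_n) >= vol) {
    stop("LA volume too small for the requested neck width", call. = FALSE)
  }
  stats::uniroot(function(R) .body_volume_3d(R, w_b, w_n, L_n) - vol,
                 lower = lo, upper = max(10 * w_b, (vol * 3 / (4 * pi))^(1 / 3) * 4),
                 tol = 1e-12)$root
}

# revolve a profile (x, r>=0) about the x axis; first and last profile
# points must have r == 0 (poles). Returns vertices and CCW-outward triangles.
.revolve_profile <- function(x, r, n_theta) {
  m <- length(x)
  r[c(1, m)][r[c(1, m)] < 1e-9 * max(r)] <- 0
  stopifnot(m >= 3, r[1] == 0, r[m] == 0)
  tau <- 2 * pi * (seq_len(n_theta) - 1) / n_theta
  verts <- rbind(c(x[1], 0, 0))
  ring_start <- integer(m)
  for (i in 2:(m - 1)) {
    ring_start[i] <- nrow(verts) + 1L
    verts <- rbind(verts, cbind(x[i], r[i] * cos(tau), r[i] * sin(tau)))
  }
  last <- nrow(verts) + 1L
  verts <- rbind(verts, c(x[m], 0, 0))
  tri <- list()
  nxt <- function(j) if (j == n_theta) 1L else j + 1L
  # fan at first pole
  rs <- ring_start[2]
  for (j in seq_len(n_theta)) {
    tri[[length(tri) + 1L]] <- c(1L, rs + j - 1L, rs + nxt(j) - 1L)
  }
  # strips
  if (m > 3) {
    for (i in 2:(m - 2)) {
      a <- ring_start[i]; b <- ring_start[i + 1]
      for (j in seq_len(n_theta)) {
        j2 <- nxt(j)
        tri[[length(tri) + 1L]] <- c(a + j - 1L, b + j - 1L, b + j2 - 1L)
        tri[[length(tri) + 1L]] <- c(a + j - 1L, b + j2 - 1L, a + j2 - 1L)
      }
    }
  }
  # fan at last pole
  rs <- ring_start[m - 1]
  for (j in seq_len(n_theta)) {
    tri[[length(tri) + 1L]] <- c(last, rs + nxt(j) - 1L, rs + j - 1L)
  }
  tri <- do.call(rbind, tri)
  # enforce outward orientation (positive signed volume)
  if (.tri_mesh_volume(verts, tri) < 0) tri <- tri[, c(1, 3, 2)]
  list(vertices = verts, triangles = tri)
}

# signed volume of a triangulated closed surface (divergence theorem)
.tri_mesh_volume <- function(v, f) {
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# see generate_chamber_series(); 3D branch
generate_chamber_series_3d <- function(spec, target_edge_mm = 4) {
  np <- spec$phase_count
  u <- (seq_len(np) - 1) / np
  v_la <- atrial_volume_waveform(u, spec$la_max_volume, spec$la_ef) * 1000
  v_laa <- atrial_volume_waveform(u, spec$laa_max_volume, spec$laa_ef) * 1000
  v_lv <- lv_volume_waveform(u, spec$lv_edv, spec$lv_esv) * 1000  # mm^3

  w_b <- spec$neck_base_width_mm
  L_n <- spec$neck_length_mm
  r_laa_min <- (min(v_laa) * 3 / (2 * pi))^(1 / 3)
  w_n <- min(spec$neck_ostium_width_mm, 1.6 * r_laa_min, w_b * 0.95)

  R_p <- vapply(v_laa, .solve_pouch_radius_3d, numeric(1), w = w_n)
  R_b <- vapply(v_la, .solve_body_radius_3d, numeric(1),
                w_b = w_b, w_n = w_n, L_n = L_n)
  R_v <- (v_lv * 3 / (4 * pi))^(1 / 3)

  n_theta <- max(40L, round(2 * pi * max(R_b) / target_edge_mm))
  n_pp <- max(16L, round(pi * R_p[1] / target_edge_mm))
  n_nn <- max(2L, round(L_n / target_edge_mm))
  n_bb <- max(24L, round(pi * R_b[1] / target_edge_mm))

  phases <- vector("list", np)
  ostium <- vector("list", np)
  tri_all <- NULL; region <- NULL; component <- NULL
  n_la_v <- NULL
  for (k in seq_len(np)) {
    h_b <- sqrt(R_b[k]^2 - (w_b / 2)^2)
    h_p <- sqrt(R_p[k]^2 - (w_n / 2)^2)
    x_o <- -(h_b + L_n)
    x_c <- x_o - h_p
    bp <- atan2(w_n / 2, h_p)
    gam <- atan2(w_b / 2, h_b)
    phi <- seq(pi, bp, length.out = n_pp)
    prof_pouch <- cbind(x_c + R_p[k] * cos(phi), R_p[k] * sin(phi))
    s <- seq_len(n_nn) / (n_nn + 1)
    prof_neck <- cbind(x_o + s * (-h_b - x_o), w_n / 2 + s * (w_b / 2 - w_n / 2))
    th <- seq(pi - gam, 0, length.out = n_bb)
    prof_body <- cbind(R_b[k] * cos(th), R_b[k] * sin(th))
    prof <- rbind(prof_pouch, prof_neck, prof_body)
    la <- .revolve_profile(prof[, 1], pmax(prof[, 2], 0), n_theta)
    # LV sphere below, same topology each phase
    phi_v <- seq(pi, 0, length.out = n_bb)
    y_lv <- -(max(R_b) + max(R_v) + 12)
    lv <- .revolve_profile(R_v[k] * cos(phi_v), R_v[k] * sin(phi_v), n_theta)
    lv$vertices[, 2] <- lv$vertices[, 2] + y_lv  # offset along y
    if (k == 1L) {
      n_la_v <- nrow(la$vertices)
      tri_all <- rbind(la$triangles, lv$triangles + n_la_v)
      storage.mode(tri_all) <- "integer"
      component <- c(rep(1L, nrow(la$triangles)), rep(2L, nrow(lv$triangles)))
      cen <- (la$vertices[la$triangles[, 1], ] +
              la$vertices[la$triangles[, 2], ] +
              la$vertices[la$triangles[, 3], ]) / 3
      region <- rep("la_body", nrow(la$triangles))
      region[cen[, 1] < x_o] <- "laa"
      dirs <- cen / sqrt(rowSums(cen^2))
      on_body <- cen[, 1] > -h_b
      region[on_body & acos(pmin(1, -dirs[, 2])) < 12 / R_b[1] &
               region == "la_body"] <- "mitral"
      pv_dirs <- rbind(
        c(cos(0.35 * pi), sin(0.35 * pi), 0.5),
        c(cos(0.65 * pi), sin(0.65 * pi), 0.5),
        c(cos(0.35 * pi), sin(0.35 * pi), -0.5),
        c(cos(0.65 * pi), sin(0.65 * pi), -0.5))
      pv_dirs <- pv_dirs / sqrt(rowSums(pv_dirs^2))
      n_pv <- min(spec$n_pv_inlets, 4L)
      for (i in seq_len(n_pv)) {
        ang <- acos(pmin(1, dirs %*% pv_dirs[i, ]))
        sel <- on_body & ang < 6 / R_b[1] & region == "la_body"
        if (!any(sel)) sel <- which.min(ifelse(on_body, ang, Inf))
        region[sel] <- paste0("pv_inlet_", i)
      }
      cen_lv <- (lv$vertices[lv$triangles[, 1], ] +
                 lv$vertices[lv$triangles[, 2], ] +
                 lv$vertices[lv$triangles[, 3], ]) / 3
      rel <- cen_lv - matrix(c(0, y_lv, 0), nrow(cen_lv), 3, byrow = TRUE)
      rel <- rel / sqrt(rowSums(rel^2))
      region_lv <- rep("lv", nrow(lv$triangles))
      region_lv[acos(pmin(1, rel[, 2])) < 10 / max(R_v)] <- "aortic"
      region <- c(region, region_lv)
    }
    phases[[k]] <- rbind(la$vertices, lv$vertices)
    ostium[[k]] <- list(point = c(x_o, 0, 0), normal = c(-1, 0, 0))
  }

  structure(list(
    dimension = 3L,
    phases = phases,
    facets = tri_all,
    region = region,
    component = component,
    component_vertices = list(la = seq_len(n_la_v),
                              lv = n_la_v + seq_len(nrow(phases[[1]]) - n_la_v)),
    phase_fractions = u,
    rr_interval = 60 / spec$heart_rate,
    depth_mm = NA_real_,
    spec = spec,
    ostium = ostium,
    ground_truth = tibble::tibble(
      phase = seq_len(np) - 1L, phase_fraction = u,
      v_la = v_la / 1000, v_laa = v_laa / 1000, v_lv = v_lv / 1000
    )
  ), class = "surface_series")
}

#' Triangulated icosphere
#'
#' Recursive subdivision of an icosahedron projected onto the sphere;
#' a standard analytic fixture for volume computations.
#'
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 subdivision passes (0 gives the
#'   icosahedron, 3 gives 1280 facets).
#' @param center sphere centre (length-3).
#' @return list with `vertices` (n x 3) and `triangles` (m x 3, outward).
#' @export
icosphere <- function(radius = 1, subdivisions = 3L, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
    c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
    c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- new.env(hash = TRUE)
    nv <- nrow(v)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      if (!is.null(edge_key[[key]])) return(edge_key[[key]])
      p <- (v[i, ] + v[j, ]) / 2
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      edge_key[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, nrow(f) * 4, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      nf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                       c(cc, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, center, "+")
  if (.tri_mesh_volume(v, f) < 0) f <- f[, c(1, 3, 2)]
  list(vertices = v, triangles = f)
}
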