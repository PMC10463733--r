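# Synthetic chamber geometry: an LA body (disc) with a neck-plus-pouch
# appendage and a separate LV disc, all breathing through the cardiac cycle
# so that the prescribed volume waveforms are met exactly (up to the
# polygonal discretization). Vertex count and connectivity are identical at
# every phase, so point correspondence across the cycle holds by
# construction.

# --- analytic area helpers -------------------------------------------------

# area of the circular segment of circle radius R beyond a chord of
# half-width w2 (w2 <= R)
.segment_area <- function(R, w2) {
  a <- asin(pmin(1, w2 / R))
  R^2 * (a - sin(a) * cos(a))
}

# LAA (pouch) area: part of a circle of radius R beyond a chord of
# half-width w2, on the far side (containing the centre)
.pouch_area <- function(R, w2) {
  b <- asin(pmin(1, w2 / R))
  R^2 * (pi - b + sin(b) * cos(b))
}

# solve pouch radius so that .pouch_area(R, w/2) == area
.solve_pouch_radius <- function(area, w) {
  w2 <- w / 2
  lo <- w2 * 1.000001
  if (.pouch_area(lo, w2) >= area) {
    stop("LAA area too small for the requested ostium width", call. = FALSE)
  }
  stats::uniroot(function(R) .pouch_area(R, w2) - area,
                 lower = lo, upper = max(10 * w, sqrt(area / pi) * 4),
                 tol = 1e-12)$root
}

# LA body area: disc minus the segment beyond the neck-attachment chord,
# plus the neck trapezoid up to the ostium chord
.body_area <- function(R, w_b, w_n, L_n) {
  pi * R^2 - .segment_area(R, w_b / 2) + L_n * (w_b + w_n) / 2
}

.solve_body_radius <- function(area, w_b, w_n, L_n) {
  lo <- (w_b / 2) * 1.000001
  if (.body_area(lo, w_b, w_n, L_n) >= area) {
    stop("LA body area too small for the requested neck width", call. = FALSE)
  }
  stats::uniroot(function(R) .body_area(R, w_b, w_n, L_n) - area,
                 lower = lo, upper = max(10 * w_b, sqrt(area / pi) * 4),
                 tol = 1e-12)$root
}

# ml -> mm^2 planar area under the 2D depth convention
.ml_to_area <- function(v_ml, depth_mm) v_ml * 1000 / depth_mm

# --- 2D construction -------------------------------------------------------

# Build the LA (body + neck + pouch) polygon for given radii. Returns the
# vertex matrix in CCW order plus the index ranges of the three parts.
.la_polygon <- function(R_b, R_p, w_b, w_n, L_n,
                        n_body, n_neck, n_pouch) {
  h_b <- sqrt(R_b^2 - (w_b / 2)^2)
  h_p <- sqrt(R_p^2 - (w_n / 2)^2)
  x_o <- -(h_b + L_n)          # ostium plane
  x_c <- x_o - h_p             # pouch centre
  gam <- atan2(w_b / 2, h_b)
  # body arc CCW from the lower gap endpoint to the upper one
  th <- seq(pi + gam, 3 * pi - gam, length.out = n_body)
  body <- cbind(R_b * cos(th), R_b * sin(th))
  up_from <- c(-h_b, w_b / 2)
  up_to <- c(x_o, w_n / 2)
  s <- seq_len(n_neck) / (n_neck + 1)
  neck_u <- cbind(up_from[1] + s * (up_to[1] - up_from[1]),
                  up_from[2] + s * (up_to[2] - up_from[2]))
  bp <- atan2(w_n / 2, h_p)
  ph <- seq(bp, 2 * pi - bp, length.out = n_pouch)
  pouch <- cbind(x_c + R_p * cos(ph), R_p * sin(ph))
  lo_from <- c(x_o, -w_n / 2)
  lo_to <- c(-h_b, -w_b / 2)
  neck_l <- cbind(lo_from[1] + s * (lo_to[1] - lo_from[1]),
                  lo_from[2] + s * (lo_to[2] - lo_from[2]))
  v <- rbind(body, neck_u, pouch, neck_l)
  list(vertices = v,
       idx_body = seq_len(n_body),
       idx_pouch = n_body + n_neck + seq_len(n_pouch),
       ostium_x = x_o)
}

#' Generate a moving synthetic chamber geometry
#'
#' Builds a closed, consistently oriented chamber boundary (LA body with a
#' neck-plus-pouch appendage, and a separate LV) at `phase_count` frames of
#' one cardiac cycle. The chamber radii at each frame are solved so that the
#' analytic region areas match the periodic volume waveforms
#' ([atrial_volume_waveform()], [lv_volume_waveform()]) for the prescribed
#' maximum volumes and ejection fractions. All phases share vertex count and
#' connectivity, so the motion of every boundary point across the cycle is
#' known by construction, and phase 0 coincides with a hypothetical phase
#' 1.0 (periodic motion).
#'
#' In the default 2D desk mode chambers are closed planar polygons and a
#' volume convention `V = area * depth_mm` applies; `dimension = 3` builds
#' triangulated surfaces of revolution of the same cross-section.
#'
#' @param spec a [chamber_spec()].
#' @param target_edge_mm approximate boundary facet length (mm); controls
#'   resolution only, not shape.
#' @return an object of class `surface_series`: a list with per-phase vertex
#'   matrices (`phases`, mm), shared `facets` (index pairs in 2D, triangles
#'   in 3D), per-facet `region` labels (`la_body`, `laa`, `mitral`,
#'   `aortic`, `pv_inlet_k`, `lv`), `component` ids (1 = LA, 2 = LV),
#'   `phase_fractions`, `rr_interval` (s), the per-phase `ostium` plane, and
#'   a `ground_truth` tibble of the analytic chamber volumes.
#' @examples
#' series <- generate_chamber_series(chamber_spec(la_max_volume = 80, la_ef = 0.5))
#' range(series$ground_truth$v_la)
#' @export
generate_chamber_series <- function(spec, target_edge_mm = 2) {
  validate_chamber_spec(spec)
  if (spec$dimension == 3L) {
    return(generate_chamber_series_3d(spec, target_edge_mm))
  }
  np <- spec$phase_count
  u <- (seq_len(np) - 1) / np
  depth <- spec$depth_mm
  v_la <- atrial_volume_waveform(u, spec$la_max_volume, spec$la_ef)
  v_laa <- atrial_volume_waveform(u, spec$laa_max_volume, spec$laa_ef)
  v_lv <- lv_volume_waveform(u, spec$lv_edv, spec$lv_esv)
  a_la <- .ml_to_area(v_la, depth)
  a_laa <- .ml_to_area(v_laa, depth)
  a_lv <- .ml_to_area(v_lv, depth)

  w_b <- spec$neck_base_width_mm
  L_n <- spec$neck_length_mm
  # clamp the ostium width so the smallest pouch over the cycle can still
  # accommodate the chord (narrowest point stays at the ostium)
  r_laa_min <- sqrt(2 * min(a_laa) / pi)   # radius if the chord were a diameter
  w_n <- min(spec$neck_ostium_width_mm, 1.8 * r_laa_min, w_b * 0.95)

  R_p <- vapply(a_laa, .solve_pouch_radius, numeric(1), w = w_n)
  R_b <- vapply(a_la, .solve_body_radius, numeric(1),
                w_b = w_b, w_n = w_n, L_n = L_n)
  R_v <- sqrt(a_lv / pi)

  # resolution chosen at phase 0
  gam0 <- atan2(w_b / 2, sqrt(R_b[1]^2 - (w_b / 2)^2))
  n_body <- max(48L, round(R_b[1] * (2 * pi - 2 * gam0) / target_edge_mm))
  n_neck <- max(3L, round(L_n / target_edge_mm))
  n_pouch <- max(16L, round(R_p[1] * 2 * pi / target_edge_mm))
  n_lv <- max(48L, round(2 * pi * max(R_v) / target_edge_mm))

  y_lv <- -(max(R_b) + max(R_v) + 12)
  psi <- 2 * pi * (seq_len(n_lv) - 1) / n_lv

  phases <- vector("list", np)
  ostium <- vector("list", np)
  for (k in seq_len(np)) {
    la <- .la_polygon(R_b[k], R_p[k], w_b, w_n, L_n, n_body, n_neck, n_pouch)
    lv <- cbind(R_v[k] * cos(psi), y_lv + R_v[k] * sin(psi))
    phases[[k]] <- rbind(la$vertices, lv)
    ostium[[k]] <- list(point = c(la$ostium_x, 0), normal = c(-1, 0))
  }
  n_la <- nrow(phases[[1]]) - n_lv

  # facets: consecutive edges within each component
  f_la <- cbind(seq_len(n_la), c(seq_len(n_la)[-1], 1L))
  f_lv <- cbind(n_la + seq_len(n_lv), n_la + c(seq_len(n_lv)[-1], 1L))
  facets <- rbind(f_la, f_lv)
  storage.mode(facets) <- "integer"
  component <- c(rep(1L, n_la), rep(2L, n_lv))

  # region labels, fixed at phase-0 stations
  region <- c(rep("la_body", n_la), rep("lv", n_lv))
  pouch_edges <- (n_body + n_neck) + seq_len(n_pouch - 1)
  region[pouch_edges] <- "laa"
  # body edge midpoint angles at phase 0
  a0 <- pi + gam0; a1 <- 3 * pi - gam0
  th0 <- a0 + ((seq_len(n_body) - 1) / (n_body - 1)) * (a1 - a0)
  mid <- ((th0[-n_body] + th0[-1]) / 2) %% (2 * pi)
  mitral_hw <- 12 / R_b[1]
  body_edge <- seq_len(n_body - 1)
  region[body_edge[abs(mid - 3 * pi / 2) <= mitral_hw]] <- "mitral"
  pv_centers <- if (spec$n_pv_inlets == 1) 0.6 * pi else
    seq(0.30 * pi, 0.88 * pi, length.out = spec$n_pv_inlets)
  pv_hw <- 4 / R_b[1]
  for (i in seq_along(pv_centers)) {
    sel <- abs(mid - pv_centers[i]) <= pv_hw
    if (!any(sel)) { # guarantee at least one facet per inlet
      sel <- which.min(abs(mid - pv_centers[i]))
    }
    region[body_edge[sel]] <- paste0("pv_inlet_", i)
  }
  # aortic opening on the LV, topmost arc
  mid_lv <- ((psi[c(2:n_lv, 1)] + psi) / 2)
  mid_lv[n_lv] <- (psi[n_lv] + 2 * pi) / 2
  aortic_hw <- 10 / max(R_v)
  lv_edge <- n_la + seq_len(n_lv)
  region[lv_edge[abs(mid_lv - pi / 2) <= aortic_hw]] <- "aortic"

  structure(list(
    dimension = 2L,
    phases = phases,
    facets = facets,
    region = region,
    component = component,
    component_vertices = list(la = seq_len(n_la), lv = n_la + seq_len(n_lv)),
    phase_fractions = u,
    rr_interval = 60 / spec$heart_rate,
    depth_mm = depth,
    spec = spec,
    ostium = ostium,
    ground_truth = tibble::tibble(
      phase = seq_len(np) - 1L, phase_fraction = u,
      v_la = v_la, v_laa = v_laa, v_lv = v_lv
    )
  ), class = "surface_series")
}

#' Extract one component of a surface series as an ordered polygon
#'
#' @param series a `surface_series` (2D).
#' @param phase 1-based phase index.
#' @param component `"la"` (body + appendage) or `"lv"`.
#' @return list with `vertices` (ordered CCW polygon, mm) and `label`
#'   (region label of each outgoing edge).
#' @export
series_polygon <- function(series, phase = 1L, component = c("la", "lv")) {
  component <- match.arg(component)
  if (series$dimension != 2L) {
    stop("series_polygon() requires a 2D surface series", call. = FALSE)
  }
  idx <- series$component_vertices[[component]]
  comp_id <- if (component == "la") 1L else 2L
  list(vertices = series$phases[[phase]][idx, , drop = FALSE],
       label = series$region[series$component == comp_id])
}

#' @export
print.surface_series <- function(x, ...) {
  cat("<surface_series>", x$dimension, "D,", length(x$phases), "phases,",
      nrow(x$phases[[1]]), "vertices,", nrow(x$facets), "facets, RR",
      sprintf("%.3f s\n", x$rr_interval))
  invisible(x)
}
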