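# Residence-time transport: dTres/dt + div(u Tres - D grad Tres) = 1,
# solved as a cell-centred finite-volume passive scalar on the flow mesh.
# First-order upwind fluxes (relative to the moving mesh) keep the scheme
# monotone and positivity-preserving at the essentially infinite Peclet
# number of blood (D = 1.14e-11 m^2/s); the price is numerical diffusion,
# which is measured on the plug-flow benchmark in the test suite. Fresh
# blood enters with Tres = 0; outflow boundaries are zero-gradient; walls
# are no-flux.

#' Default blood diffusivity for the residence-time scalar
#' @return diffusivity in m^2/s.
#' @export
blood_diffusivity <- function() 1.14e-11

# edge structure of a triangle mesh for finite-volume fluxes:
# for each unique edge, left triangle L (edge appears CCW in L), right
# triangle R (NA at the boundary), and the boundary-edge row it coincides
# with (NA for interior edges)
.fv_edges <- function(mesh) {
  tri <- mesh$tri
  Tn <- nrow(tri)
  ea <- c(tri[, 1], tri[, 2], tri[, 3])
  eb <- c(tri[, 2], tri[, 3], tri[, 1])
  owner <- rep(seq_len(Tn), 3)
  key <- paste(pmin(ea, eb), pmax(ea, eb))
  first <- !duplicated(key)
  idx <- match(key, key[first])
  a <- ea[first]; b <- eb[first]
  L <- owner[first]
  R <- rep(NA_integer_, sum(first))
  dup <- which(!first)
  R[idx[dup]] <- owner[dup]
  bkey <- paste(pmin(mesh$boundary$a, mesh$boundary$b),
                pmax(mesh$boundary$a, mesh$boundary$b))
  bnd_row <- match(key[first], bkey)
  list(a = a, b = b, L = L, R = R, bnd = bnd_row)
}

#' Advance the residence-time field one flow step
#'
#' Explicit donor-cell upwind update of the cell-centred residence time on
#' the (already advanced) flow state, in the advective ALE form
#' `dc/dt + (u - w) . grad c = 1` with sub-cycling to respect the scalar
#' CFL limit. Every update is a convex combination of the cell value and
#' its inflow donors plus the unit source, so residence times stay
#' non-negative and never exceed the elapsed scalar time (inflow carries
#' Tres = 0).
#'
#' @param state a `flow_state` advanced to the new time level (velocity
#'   `u`, mesh velocity `w`, moved mesh).
#' @param open_edge logical per boundary edge: pressure opening?
#' @param dt flow time step (s).
#' @param diffusivity scalar diffusivity (m^2/s).
#' @param fv optional precomputed [.fv_edges] structure for the mesh.
#' @return the state with updated `c` (s) and `scalar_time`.
#' @export
advance_residence <- function(state, open_edge, dt,
                              diffusivity = blood_diffusivity(), fv = NULL) {
  mesh <- state$mesh
  if (length(state$c) != nrow(mesh$tri)) {
    stop("residence field and flow mesh have different cell counts",
         call. = FALSE)
  }
  if (is.null(fv)) fv <- .fv_edges(mesh)
  nodes <- mesh$nodes * 1e-3
  A1 <- mesh_areas(mesh) * 1e-6
  u <- state$u
  w <- state$w
  if (is.null(w)) w <- matrix(0, nrow(nodes), 2)
  dx <- nodes[fv$b, 1] - nodes[fv$a, 1]
  dy <- nodes[fv$b, 2] - nodes[fv$a, 2]
  # relative velocity at the edge midpoint (P1: mean of endpoint values);
  # normal (dy, -dx) points out of the left triangle
  vx <- (u[fv$a, 1] + u[fv$b, 1] - w[fv$a, 1] - w[fv$b, 1]) / 2
  vy <- (u[fv$a, 2] + u[fv$b, 2] - w[fv$a, 2] - w[fv$b, 2]) / 2
  q <- vx * dy - vy * dx                 # volume flux per unit depth (m^2/s)
  is_bnd <- !is.na(fv$bnd)
  wall_bnd <- is_bnd & !open_edge[ifelse(is.na(fv$bnd), 1L, fv$bnd)]
  q[wall_bnd] <- 0                       # no-flux walls
  # advective (non-conservative) ALE form: dc/dt + (u - w).grad c = 1.
  # Donor-cell upwinding makes every update a convex combination of the
  # cell value and its inflow donors, so the discrete maximum principle
  # holds exactly (up to the unit source) even where the projected
  # velocity field carries a small residual divergence.
  cc <- state$c
  Tn <- nrow(mesh$tri)
  Rint <- !is.na(fv$R)
  pos <- pmax(q, 0); neg <- pmax(-q, 0)
  # per-cell total inflow coefficient for the CFL bound
  influx <- as.numeric(tapply(neg, factor(fv$L, levels = seq_len(Tn)), sum,
                              default = 0)) +
    as.numeric(tapply(pos[Rint], factor(fv$R[Rint], levels = seq_len(Tn)),
                      sum, default = 0))
  nsub <- max(1L, ceiling(dt * max(influx / A1) / 0.9))
  dts <- dt / nsub
  cen <- (nodes[mesh$tri[, 1], , drop = FALSE] +
          nodes[mesh$tri[, 2], , drop = FALSE] +
          nodes[mesh$tri[, 3], , drop = FALSE]) / 3
  elen <- sqrt(dx^2 + dy^2)
  dcen <- rep(1, length(q))
  dcen[Rint] <- sqrt((cen[fv$R[Rint], 1] - cen[fv$L[Rint], 1])^2 +
                     (cen[fv$R[Rint], 2] - cen[fv$L[Rint], 2])^2)
  dko <- diffusivity * elen / dcen       # two-point diffusive conductance
  fL <- factor(fv$L, levels = seq_len(Tn))
  fR <- factor(fv$R[Rint], levels = seq_len(Tn))
  for (s in seq_len(nsub)) {
    cL <- cc[fv$L]
    cR <- ifelse(Rint, cc[fv$R], 0)      # boundary: inflow carries 0
    # inflow contributions: edge inflow into L is -q < 0; into R is q > 0
    gainL <- neg * (cR - cL) + ifelse(Rint, dko * (cR - cL), 0)
    gainR <- pos * (cL - cR) + dko * (cL - cR)
    dcell <- as.numeric(tapply(gainL, fL, sum, default = 0)) +
      as.numeric(tapply(gainR[Rint], fR, sum, default = 0))
    cc <- cc + dts * dcell / A1 + dts    # unit source: blood ages 1 s/s
    cc[cc < 0] <- 0
  }
  state$c <- cc
  state$scalar_time <- state$scalar_time + dt
  state
}

#' Regional stasis summary of a residence-time field
#'
#' Volume-weighted mean residence time in the LA including the appendage,
#' the LA without the appendage, and the LAA alone, expressed in cardiac
#' cycles. The appendage is the set of cells whose centroid lies beyond the
#' ostium plane.
#'
#' @param field list with `mesh` (the evaluation mesh) and `c` (per-cell
#'   residence time, s), as stored by [run_residence()].
#' @param ostium_plane list with `point`, `normal` (mm; normal towards the
#'   appendage).
#' @param rr_interval cardiac cycle length (s).
#' @param evaluation_phase RR fraction of the evaluation instant (carried
#'   through to the output).
#' @param n_cycles number of scalar cycles simulated (carried through).
#' @return one-row tibble: `rt_la_with_laa`, `rt_la_without_laa`, `rt_laa`
#'   (cardiac cycles), region volumes (ml-equivalent areas), and metadata.
#' @export
regional_stasis <- function(field, ostium_plane, rr_interval,
                            evaluation_phase = NA_real_,
                            n_cycles = NA_integer_) {
  mesh <- field$mesh
  cc <- field$c
  A <- mesh_areas(mesh)
  cen <- (mesh$nodes[mesh$tri[, 1], , drop = FALSE] +
          mesh$nodes[mesh$tri[, 2], , drop = FALSE] +
          mesh$nodes[mesh$tri[, 3], , drop = FALSE]) / 3
  nrm <- ostium_plane$normal / sqrt(sum(ostium_plane$normal^2))
  s <- (cen[, 1] - ostium_plane$point[1]) * nrm[1] +
       (cen[, 2] - ostium_plane$point[2]) * nrm[2]
  in_laa <- s > 0
  if (!any(in_laa)) stop("ostium plane yields an empty appendage region",
                         call. = FALSE)
  if (all(in_laa)) stop("ostium plane yields an empty atrial body region",
                        call. = FALSE)
  wmean <- function(x, w) sum(x * w) / sum(w)
  tibble::tibble(
    rt_la_with_laa = wmean(cc, A) / rr_interval,
    rt_la_without_laa = wmean(cc[!in_laa], A[!in_laa]) / rr_interval,
    rt_laa = wmean(cc[in_laa], A[in_laa]) / rr_interval,
    volume_laa = sum(A[in_laa]),
    volume_la_body = sum(A[!in_laa]),
    evaluation_phase = evaluation_phase,
    n_cycles = n_cycles
  )
}


# Overlap-area remap of a cell-centred field between two triangulations of
# (nearly) the same domain. For every new triangle, candidate old triangles
# are found by centroid proximity and clipped against it; the new value is
# the overlap-area weighted mean.
.p0_remap <- function(old_mesh, new_mesh, c_old, old_cen = NULL,
                      new_cen = NULL) {
  if (is.null(old_cen)) {
    old_cen <- (old_mesh$nodes[old_mesh$tri[, 1], , drop = FALSE] +
                old_mesh$nodes[old_mesh$tri[, 2], , drop = FALSE] +
                old_mesh$nodes[old_mesh$tri[, 3], , drop = FALSE]) / 3
  }
  if (is.null(new_cen)) {
    new_cen <- (new_mesh$nodes[new_mesh$tri[, 1], , drop = FALSE] +
                new_mesh$nodes[new_mesh$tri[, 2], , drop = FALSE] +
                new_mesh$nodes[new_mesh$tri[, 3], , drop = FALSE]) / 3
  }
  Tn_new <- nrow(new_mesh$tri)
  k <- min(30L, nrow(old_mesh$tri))
  nn <- RANN::nn2(old_cen, new_cen, k = k)
  A_new <- mesh_areas(new_mesh)
  c_new <- numeric(Tn_new)
  for (i in seq_len(Tn_new)) {
    poly_i <- new_mesh$nodes[new_mesh$tri[i, ], , drop = FALSE]
    acc_w <- 0
    acc_c <- 0
    for (jj in seq_len(k)) {
      j <- nn$nn.idx[i, jj]
      tj <- old_mesh$nodes[old_mesh$tri[j, ], , drop = FALSE]
      clipped <- poly_i
      for (e in 1:3) {
        a <- tj[e, ]
        b <- tj[if (e == 3) 1 else e + 1, ]
        # keep the left side of edge a -> b (old triangles are CCW)
        nrm <- c(b[2] - a[2], a[1] - b[1])
        clipped <- clip_polygon_halfplane(clipped, a, nrm)
        if (nrow(clipped) < 3) break
      }
      if (nrow(clipped) >= 3) {
        w <- abs(polygon_area(clipped))
        acc_w <- acc_w + w
        acc_c <- acc_c + w * c_old[j]
      }
      if (acc_w >= A_new[i] * (1 - 1e-9)) break
    }
    c_new[i] <- if (acc_w > 1e-12 * A_new[i]) acc_c / acc_w else
      c_old[nn$nn.idx[i, 1]]
  }
  c_new
}
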