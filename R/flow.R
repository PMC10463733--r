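# Moving-boundary incompressible flow on the chamber cross-section.
# Incremental-pressure projection (fractional step) with P1/P1 elements:
# implicit viscous + implicit streamline-upwinded ALE convection, then a
# pressure Poisson solve with Dirichlet pressure at the openings, then a
# velocity correction. The flow is driven purely by the motion of the
# endocardial boundary; openings are pressure boundaries and closed valves
# are switched to no-slip walls facet by facet.

#' Fluid properties of blood
#'
#' @param viscosity dynamic viscosity (Pa s); default 3.5e-3.
#' @param density density (kg/m^3); default 1060.
#' @return list of class `fluid_properties`.
#' @export
fluid_properties <- function(viscosity = 3.5e-3, density = 1060) {
  stopifnot(viscosity > 0, density > 0)
  structure(list(viscosity = viscosity, density = density),
            class = "fluid_properties")
}

#' Flow solver configuration
#'
#' Defaults mirror a production fine-scale setup (time step 5e-4 s, wall
#' edge 0.25 mm, maximum edge 2 mm, remeshing every 50 steps, two
#' initialization cycles, boundary motion interpolated from the 5 closest
#' tracked points by inverse distance weighting, all openings at 0 Pa gauge).
#' The 2D desk mode scales the edge lengths by `desk_scale` (default 8) and
#' can override the time step via `steps_per_cycle`; see the package
#' vignette for the rationale and accuracy impact.
#'
#' @param dt time step (s).
#' @param remesh_interval_steps rebuild the mesh topology every this many
#'   steps.
#' @param wall_edge_length,max_edge_length target edge lengths (mm) before
#'   desk scaling.
#' @param desk_scale multiplier applied to both edge lengths in 2D desk
#'   mode.
#' @param init_cycles flow initialization cycles before the residence-time
#'   scalar is switched on.
#' @param idw_neighbors,idw_power inverse-distance-weighting neighbours and
#'   power for boundary-motion interpolation.
#' @param opening_pressure gauge pressure (Pa) at openings; a scalar, or a
#'   named vector by region label (e.g. `c(pv_inlet_1 = 0, mitral = 0)`).
#' @param valve_schedule optional explicit mitral-valve opening intervals
#'   as a 2-column matrix of RR fractions; by default the valve state is
#'   derived from the LV volume curve (open while the ventricle fills).
#' @param steps_per_cycle if given, `dt` is replaced by
#'   `rr_interval / steps_per_cycle` at run time (coarse desk stepping).
#' @param supg streamline-diffusion multiplier (0 disables upwinding).
#' @param pressure_stab weight of the Laplacian stabilization added to the
#'   discrete projection operator (suppresses equal-order pressure modes;
#'   0 recovers the unstabilized operator).
#' @param evaluation_phase RR fraction at which regional stasis is
#'   evaluated; defaults to end systole.
#' @param output_interval store a field snapshot every this many steps
#'   (0 = none).
#' @return list of class `solver_config`.
#' @export
solver_config <- function(dt = 5e-4,
                          remesh_interval_steps = 50L,
                          wall_edge_length = 0.25,
                          max_edge_length = 2,
                          desk_scale = 8,
                          init_cycles = 2L,
                          idw_neighbors = 5L,
                          idw_power = 2,
                          opening_pressure = 0,
                          valve_schedule = NULL,
                          steps_per_cycle = NULL,
                          supg = 1,
                          pressure_stab = 0.05,
                          evaluation_phase = end_systole_phase(),
                          output_interval = 0L) {
  stopifnot(dt > 0, remesh_interval_steps >= 1, idw_neighbors >= 1,
            idw_power > 0, wall_edge_length > 0,
            max_edge_length >= wall_edge_length, desk_scale > 0)
  structure(list(dt = dt,
                 remesh_interval_steps = as.integer(remesh_interval_steps),
                 wall_edge_length = wall_edge_length,
                 max_edge_length = max_edge_length,
                 desk_scale = desk_scale,
                 init_cycles = as.integer(init_cycles),
                 idw_neighbors = as.integer(idw_neighbors),
                 idw_power = idw_power,
                 opening_pressure = opening_pressure,
                 valve_schedule = valve_schedule,
                 steps_per_cycle = steps_per_cycle,
                 supg = supg,
                 pressure_stab = pressure_stab,
                 evaluation_phase = evaluation_phase,
                 output_interval = as.integer(output_interval)),
            class = "solver_config")
}

#' Interpolate boundary motion from tracked points
#'
#' Inverse-distance-weighted (IDW) interpolation of tracked-vertex
#' displacements onto arbitrary boundary points: each point takes the
#' weighted mean of its `idw_neighbors` nearest tracked vertices with
#' weights `1/d^idw_power`. A point coinciding with a tracked vertex takes
#' that vertex's displacement exactly (distance-zero tie rule).
#'
#' @param points m x 2 query points (mm), e.g. mesh boundary nodes.
#' @param motion a `motion_field`, or a list with `reference` (vertex
#'   positions) and a displacement matrix via `values`.
#' @param time time (s), wrapped periodically; ignored when `values` given.
#' @param config a [solver_config()] (for `idw_neighbors`, `idw_power`).
#' @param values optional n x 2 matrix of per-vertex values to interpolate
#'   instead of spline displacements at `time`.
#' @return m x 2 matrix of interpolated displacements (mm).
#' @export
interpolate_boundary_motion <- function(points, motion, time = 0,
                                        config = solver_config(),
                                        values = NULL) {
  ref <- motion$reference
  if (is.null(values)) {
    values <- motion_splines(motion)(time)
  }
  k <- min(config$idw_neighbors, nrow(ref))
  if (k < config$idw_neighbors) {
    warning("fewer tracked vertices (", nrow(ref), ") than idw_neighbors (",
            config$idw_neighbors, "); using all available", call. = FALSE)
  }
  w <- .idw_weights(points, ref, k, config$idw_power)
  .idw_apply(w, values)
}

.idw_weights <- function(points, ref, k, power) {
  nn <- RANN::nn2(ref, points, k = k)
  d <- nn$nn.dists
  exact <- d[, 1] < 1e-9
  w <- 1 / pmax(d, 1e-300)^power
  w <- w / rowSums(w)
  if (any(exact)) {
    w[exact, ] <- 0
    w[exact, 1] <- 1
  }
  list(idx = nn$nn.idx, w = w)
}

.idw_apply <- function(wts, values) {
  m <- nrow(wts$idx)
  out <- matrix(0, m, ncol(values))
  for (j in seq_len(ncol(wts$idx))) {
    out <- out + wts$w[, j] * values[wts$idx[, j], , drop = FALSE]
  }
  out
}

# classify boundary conditions for one step: returns node sets and edge sets
# given the per-edge open flag and pressures
.classify_bc <- function(mesh, open_edge, p_edge) {
  nb_edges <- nrow(mesh$boundary)
  stopifnot(length(open_edge) == nb_edges)
  wall_edges <- which(!open_edge)
  open_edges <- which(open_edge)
  wall_nodes <- unique(c(mesh$boundary$a[wall_edges],
                         mesh$boundary$b[wall_edges]))
  open_nodes <- setdiff(unique(c(mesh$boundary$a[open_edges],
                                 mesh$boundary$b[open_edges])), wall_nodes)
  p_node <- numeric(length(open_nodes))
  if (length(open_nodes) > 0) {
    for (i in seq_along(open_nodes)) {
      touching <- open_edges[mesh$boundary$a[open_edges] == open_nodes[i] |
                             mesh$boundary$b[open_edges] == open_nodes[i]]
      p_node[i] <- mean(p_edge[touching])
    }
  }
  list(wall_edges = wall_edges, open_edges = open_edges,
       wall_nodes = wall_nodes, open_nodes = open_nodes, p_node = p_node)
}

# boundary flux integral of nodal field v over the listed edges (SI units)
.boundary_flux <- function(nodes, edges, v) {
  if (nrow(edges) == 0) return(0)
  a <- edges[, 1]; b <- edges[, 2]
  dx <- nodes[b, 1] - nodes[a, 1]
  dy <- nodes[b, 2] - nodes[a, 2]
  vn_a <- v[a, 1] * dy - v[a, 2] * dx
  vn_b <- v[b, 1] * dy - v[b, 2] * dx
  sum((vn_a + vn_b) / 2)
}

#' Initialize a flow state on a mesh
#'
#' @param mesh a [build_mesh()] result (mm coordinates).
#' @param time initial time (s).
#' @return object of class `flow_state` with zero velocity and pressure and
#'   a zero residence-time field.
#' @export
flow_state <- function(mesh, time = 0) {
  structure(list(mesh = mesh,
                 u = matrix(0, nrow(mesh$nodes), 2),
                 p = numeric(nrow(mesh$nodes)),
                 c = numeric(nrow(mesh$tri)),
                 scalar_time = 0,
                 time = time),
            class = "flow_state")
}

#' Advance the flow one time step on the moving mesh
#'
#' One projection step of the incompressible Navier-Stokes equations in
#' arbitrary Lagrangian-Eulerian form: the mesh moves to `wall$nodes`,
#' convection uses the velocity relative to the mesh, no-slip walls take the
#' prescribed boundary velocity, and openings have fixed pressure with
#' traction-free tangential flow.
#'
#' @param state a `flow_state`.
#' @param wall list describing the step's boundary data: `nodes` (new node
#'   positions, mm, all nodes), `bc_velocity` (N x 2 m/s, used at no-slip
#'   nodes; defaults to the mesh velocity), `open_edge` (logical per
#'   boundary edge), `p_edge` (gauge pressure Pa per boundary edge).
#' @param props [fluid_properties()].
#' @param config [solver_config()] (uses `dt`, `supg`).
#' @return the advanced `flow_state`; diagnostics (`div_max`, `flux_open`,
#'   `dvdt`, `ke`) are attached as fields.
#' @export
advance_flow <- function(state, wall, props = fluid_properties(),
                         config = solver_config()) {
  mesh <- state$mesh
  tri <- mesh$tri
  n <- nrow(mesh$nodes)
  dt <- config$dt
  x0 <- mesh$nodes * 1e-3
  x1 <- wall$nodes * 1e-3
  w_all <- (x1 - x0) / dt
  bc_u <- wall$bc_velocity
  if (is.null(bc_u)) bc_u <- w_all
  open_edge <- wall$open_edge
  if (is.null(open_edge)) open_edge <- rep(FALSE, nrow(mesh$boundary))
  p_edge <- wall$p_edge
  if (is.null(p_edge)) p_edge <- rep(0, nrow(mesh$boundary))
  bc <- .classify_bc(mesh, open_edge, p_edge)

  g <- .tri_geom(x1, tri)
  if (any(g$A <= 0)) {
    stop("mesh motion inverted ", sum(g$A <= 0), " cell(s)", call. = FALSE)
  }
  nu <- props$viscosity / props$density
  Ml <- .fem_mass_lumped(g, tri, n)
  K <- .fem_stiffness(g, tri, n)
  a_elem <- cbind(
    (state$u[tri[, 1], 1] + state$u[tri[, 2], 1] + state$u[tri[, 3], 1]) / 3 -
      (w_all[tri[, 1], 1] + w_all[tri[, 2], 1] + w_all[tri[, 3], 1]) / 3,
    (state$u[tri[, 1], 2] + state$u[tri[, 2], 2] + state$u[tri[, 3], 2]) / 3 -
      (w_all[tri[, 1], 2] + w_all[tri[, 2], 2] + w_all[tri[, 3], 2]) / 3)
  C <- .fem_convection(g, tri, n, a_elem, supg = config$supg)
  A_mom <- Matrix::Diagonal(n, Ml / dt) + nu * K + C
  rhs <- cbind(Ml / dt * state$u[, 1], Ml / dt * state$u[, 2])
  dn <- bc$wall_nodes
  sys <- .apply_dirichlet(A_mom, rhs[, 1], dn, bc_u[dn, 1])
  A_d <- sys$A
  rhs1 <- sys$rhs
  rhs2 <- rhs[, 2]; rhs2[dn] <- bc_u[dn, 2]
  ustar <- as.matrix(Matrix::solve(A_d, cbind(rhs1, rhs2)))

  ustar[dn, ] <- bc_u[dn, , drop = FALSE]

  # pressure Poisson (kinematic pressure P = p / rho) built from the
  # discrete projection operator B = G^T M^-1 G with the velocity
  # correction masked at no-slip nodes, so the corrected field satisfies
  # the weak continuity equation exactly on every free node
  gops <- .fem_grad_ops(g, tri, n)
  mask <- rep(1, n); mask[dn] <- 0
  Gx_m <- Matrix::Diagonal(n, mask) %*% gops$Gx
  Gy_m <- Matrix::Diagonal(n, mask) %*% gops$Gy
  Mi <- Matrix::Diagonal(n, 1 / pmax(Ml, 1e-300))
  B <- Matrix::t(Gx_m) %*% Mi %*% Gx_m + Matrix::t(Gy_m) %*% Mi %*% Gy_m +
    config$pressure_stab * K
  rhs_p <- (.fem_div_rhs(g, tri, n, ustar) -
            .fem_boundary_flux_rhs(x1, as.matrix(
              mesh$boundary[bc$wall_edges, c("a", "b")]), n, bc_u)) / dt
  if (length(bc$open_nodes) > 0) {
    sysp <- .apply_dirichlet(B, rhs_p, bc$open_nodes,
                             bc$p_node / props$density)
  } else {
    free <- setdiff(seq_len(n), dn)
    sysp <- .apply_dirichlet(B, rhs_p, free[1], 0)   # closed domain: pin
  }
  P <- as.vector(Matrix::solve(sysp$A, sysp$rhs))

  u1 <- ustar - dt * cbind(as.vector(Gx_m %*% P),
                           as.vector(Gy_m %*% P)) / Ml
  u1[dn, ] <- bc_u[dn, , drop = FALSE]

  new_mesh <- mesh
  new_mesh$nodes <- wall$nodes
  out <- state
  out$mesh <- new_mesh
  out$u <- u1
  out$p <- P * props$density
  out$time <- state$time + dt
  out$w <- w_all
  out$div_max <- max(abs(.fem_div_elem(g, tri, u1)))
  out$flux_open <- .boundary_flux(
    x1, as.matrix(mesh$boundary[bc$open_edges, c("a", "b")]), u1)
  out$dvdt <- .boundary_flux(
    x1, as.matrix(mesh$boundary[, c("a", "b")]), w_all)
  g0 <- .tri_geom(x0, tri)
  out$dadt <- sum(g$A - g0$A) / dt
  # continuum identity: boundary flux relative to the moving wall balances
  # the rate of domain area change
  out$mass_resid <- .boundary_flux(
    x1, as.matrix(mesh$boundary[, c("a", "b")]), u1 - w_all) + out$dadt
  out$ke <- sum(Ml * rowSums(u1^2)) / 2 * props$density
  out$bc <- bc
  out
}

#' Rebuild the mesh and transfer the fields
#'
#' Generates a fresh graded mesh on the current (or a supplied) boundary and
#' transfers velocity and pressure by P1 interpolation and the cell-centred
#' residence-time scalar by centroid sampling with a conservative global
#' rescale, so the domain-integrated scalar content is preserved exactly.
#'
#' @param state a `flow_state`.
#' @param new_boundary optional replacement boundary polygon (mm) with
#'   attribute-free ordering matching the old boundary labels; defaults to
#'   the current mesh boundary.
#' @param config [solver_config()] (edge lengths, desk scale).
#' @return a `flow_state` on the new mesh.
#' @export
remesh_and_transfer <- function(state, new_boundary = NULL,
                                config = solver_config()) {
  mesh <- state$mesh
  if (is.null(new_boundary)) {
    new_boundary <- mesh$nodes[seq_len(mesh$n_boundary), , drop = FALSE]
  }
  labels <- mesh$boundary$label
  h <- config$wall_edge_length * config$desk_scale
  hmax <- config$max_edge_length * config$desk_scale
  new_mesh <- build_mesh(new_boundary, labels, wall_edge_length = h,
                         max_edge_length = hmax)
  # nodal transfer (relaxed tolerance catches boundary nodes that fall a
  # hair outside the old triangulation)
  loc <- locate_points(mesh, new_mesh$nodes, tol = 0.05)
  u_new <- matrix(0, nrow(new_mesh$nodes), 2)
  p_new <- numeric(nrow(new_mesh$nodes))
  inside <- !is.na(loc$tri)
  if (any(inside)) {
    tr <- mesh$tri[loc$tri[inside], , drop = FALSE]
    bw <- loc$bary[inside, , drop = FALSE]
    for (d in 1:2) {
      u_new[inside, d] <- rowSums(bw * cbind(state$u[tr[, 1], d],
                                             state$u[tr[, 2], d],
                                             state$u[tr[, 3], d]))
    }
    p_new[inside] <- rowSums(bw * cbind(state$p[tr[, 1]], state$p[tr[, 2]],
                                        state$p[tr[, 3]]))
  }
  if (any(!inside)) {
    nn <- RANN::nn2(mesh$nodes, new_mesh$nodes[!inside, , drop = FALSE], k = 1)
    u_new[!inside, ] <- state$u[nn$nn.idx[, 1], , drop = FALSE]
    p_new[!inside] <- state$p[nn$nn.idx[, 1]]
  }
  # scalar transfer (cell-centred): sample old field at new centroids, then
  # rescale to conserve the integral
  old_cen <- (mesh$nodes[mesh$tri[, 1], , drop = FALSE] +
              mesh$nodes[mesh$tri[, 2], , drop = FALSE] +
              mesh$nodes[mesh$tri[, 3], , drop = FALSE]) / 3
  new_cen <- (new_mesh$nodes[new_mesh$tri[, 1], , drop = FALSE] +
              new_mesh$nodes[new_mesh$tri[, 2], , drop = FALSE] +
              new_mesh$nodes[new_mesh$tri[, 3], , drop = FALSE]) / 3
  # exact piecewise-constant remap: each new cell takes the overlap-area
  # weighted mean of the old cells it intersects (convex-convex clipping),
  # which conserves the integral up to the boundary resampling sliver and
  # is a convex combination of old values (boundedness preserved)
  c_new <- .p0_remap(mesh, new_mesh, state$c, old_cen, new_cen)
  out <- state
  out$mesh <- new_mesh
  out$u <- u_new
  out$p <- p_new
  out$c <- c_new
  out
}
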