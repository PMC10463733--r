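# Cycle driver: runs the moving-boundary flow (and optionally the
# residence-time scalar) over whole cardiac cycles, handling boundary-motion
# interpolation, interior mesh motion, valve switching, remeshing, and
# per-step bookkeeping.

# harmonic extension operator of boundary displacements into the mesh
# interior, factorized once per mesh
.mesh_extension <- function(mesh) {
  n <- nrow(mesh$nodes)
  g <- .tri_geom(mesh$nodes, mesh$tri)
  K <- .fem_stiffness(g, mesh$tri, n)
  bnd <- seq_len(mesh$n_boundary)
  int <- setdiff(seq_len(n), bnd)
  if (length(int) == 0) {
    return(function(d_bnd) d_bnd)
  }
  Kii <- K[int, int, drop = FALSE]
  Kib <- K[int, bnd, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kii), LDL = FALSE)
  function(d_bnd) {
    d <- matrix(0, n, 2)
    d[bnd, ] <- d_bnd
    rhs <- -(Kib %*% d_bnd)
    d[int, 1] <- as.vector(Matrix::solve(ch, rhs[, 1]))
    d[int, 2] <- as.vector(Matrix::solve(ch, rhs[, 2]))
    d
  }
}

# ostium plane at an arbitrary time (linear interpolation between phases)
.ostium_at <- function(motion, time) {
  os <- motion$ostium
  if (is.null(os)) return(NULL)
  rr <- motion$rr_interval
  u <- (time / rr) %% 1
  fr <- c(motion$phase_fractions, 1)
  k <- findInterval(u, fr, rightmost.closed = TRUE)
  np <- length(os)
  k2 <- if (k >= np) 1L else k + 1L
  t0 <- fr[k]; t1 <- fr[k + 1]
  a <- if (t1 > t0) (u - t0) / (t1 - t0) else 0
  pt <- (1 - a) * os[[k]]$point + a * os[[k2]]$point
  nr <- (1 - a) * os[[k]]$normal + a * os[[k2]]$normal
  list(point = pt, normal = nr / sqrt(sum(nr^2)))
}

# mitral valve state function: open while the ventricle fills
.valve_fn <- function(motion, config) {
  if (!is.null(config$valve_schedule)) {
    sched <- config$valve_schedule
    rr <- motion$rr_interval
    return(function(t) {
      u <- (t / rr) %% 1
      any(u >= sched[, 1] & u < sched[, 2])
    })
  }
  if (!is.null(motion$series)) {
    gt <- motion$series$ground_truth
    rr <- motion$rr_interval
    tt <- c(gt$phase_fraction, 1) * rr
    f <- stats::splinefun(tt, c(gt$v_lv, gt$v_lv[1]), method = "periodic")
    return(function(t) f(t %% rr, deriv = 1) > 0)
  }
  function(t) TRUE   # no LV information: mitral always open
}

#' Run the moving-boundary flow over whole cardiac cycles
#'
#' Meshes the reference chamber cross-section, then advances the flow
#' (and, for [run_residence()], the residence-time scalar) through
#' `n_cycles` cardiac cycles. Boundary node motion is interpolated from
#' the tracked wall points by inverse distance weighting, extended
#' harmonically into the interior, and the mesh topology is rebuilt every
#' `remesh_interval_steps` steps. The mitral opening switches between a
#' pressure opening (ventricular filling) and a no-slip wall (systole);
#' pulmonary-vein inlets are always pressure openings.
#'
#' @param motion a `motion_field` for the LA boundary carrying per-edge
#'   region labels (as produced by [motion_from_series()]); tracked fields
#'   need `labels` supplied explicitly.
#' @param props [fluid_properties()].
#' @param config [solver_config()].
#' @param n_cycles number of cardiac cycles.
#' @param labels per-edge region labels of `motion$reference` (defaults to
#'   `motion$reference_labels`).
#' @param scalar_cycles additional cycles with the residence-time scalar
#'   active, appended after `n_cycles` initialization cycles.
#' @param verbose print one line per cycle.
#' @return an object of class `flow_run`: `state` (final `flow_state`),
#'   `log` (per-step tibble), `cycle_summary` (kinetic energy at matching
#'   phases, cycle-to-cycle convergence), `snapshot` (mesh + scalar at the
#'   stasis evaluation instant, when the scalar ran), `regional` (the
#'   [regional_stasis()] row, when available), and `per_cycle_regional`.
#' @export
run_cycles <- function(motion, props = fluid_properties(),
                       config = solver_config(), n_cycles = 2,
                       labels = NULL, scalar_cycles = 0, verbose = FALSE) {
  stopifnot(inherits(motion, "motion_field"))
  if (motion$dimension != 2L) {
    stop("the flow solver runs in the 2D desk mode", call. = FALSE)
  }
  labels <- labels %||% motion$reference_labels
  if (is.null(labels)) {
    stop("motion field carries no region labels; pass `labels`",
         call. = FALSE)
  }
  rr <- motion$rr_interval
  dt <- config$dt
  if (!is.null(config$steps_per_cycle)) dt <- rr / config$steps_per_cycle
  steps_per_cycle <- max(4L, round(rr / dt))
  dt <- rr / steps_per_cycle
  config$dt <- dt
  h <- config$wall_edge_length * config$desk_scale
  hmax <- config$max_edge_length * config$desk_scale

  total_cycles <- n_cycles + scalar_cycles
  n_steps <- total_cycles * steps_per_cycle
  times <- dt * seq_len(n_steps)
  scalar_start <- n_cycles * steps_per_cycle

  # displacement of every tracked vertex at every step time (periodic)
  spl <- motion_splines(motion)
  nv <- nrow(motion$reference)
  disp_v <- array(0, c(n_steps, nv, 2))
  for (k in seq_len(n_steps)) disp_v[k, , ] <- spl(times[k])

  mesh <- build_mesh(motion$reference, labels, wall_edge_length = h,
                     max_edge_length = hmax)
  st <- flow_state(mesh)
  valve_open <- .valve_fn(motion, config)
  p_open_cfg <- config$opening_pressure

  setup <- function(st, t_setup, k_setup) {
    mesh <- st$mesh
    bnd_pts <- mesh$nodes[seq_len(mesh$n_boundary), , drop = FALSE]
    # IDW neighbours in the configuration at setup time
    ref_now <- motion$reference +
      (if (k_setup == 0) 0 else disp_v[k_setup, , ])
    kn <- min(config$idw_neighbors, nv)
    idw <- .idw_weights(bnd_pts, ref_now, kn, config$idw_power)
    offset <- if (k_setup == 0) matrix(0, nrow(bnd_pts), 2) else
      .idw_apply(idw, disp_v[k_setup, , ])
    list(ext = .mesh_extension(mesh), idw = idw, offset = offset,
         nodes0 = mesh$nodes, fv = .fv_edges(mesh))
  }
  dom <- setup(st, 0, 0L)

  open_base <- grepl("^pv_inlet", mesh$boundary$label)
  mitral_edges <- mesh$boundary$label == "mitral"
  edge_pressure <- function(labels_now) {
    if (length(p_open_cfg) == 1 && is.null(names(p_open_cfg))) {
      rep(p_open_cfg, length(labels_now))
    } else {
      out <- rep(0, length(labels_now))
      hit <- labels_now %in% names(p_open_cfg)
      out[hit] <- p_open_cfg[labels_now[hit]]
      out
    }
  }

  log <- vector("list", n_steps)
  snapshot <- NULL
  per_cycle <- list()
  eval_step <- if (scalar_cycles > 0) {
    scalar_start +
      round((scalar_cycles - 1 + config$evaluation_phase) * steps_per_cycle)
  } else -1L
  ke_at_phase <- numeric(0)

  for (k in seq_len(n_steps)) {
    t1 <- times[k]
    d_b <- .idw_apply(dom$idw, disp_v[k, , ]) - dom$offset
    nodes1 <- dom$nodes0 + dom$ext(d_b)
    mitral_now <- valve_open(t1)
    open_edge <- open_base | (mitral_edges & mitral_now)
    p_edge <- edge_pressure(st$mesh$boundary$label)
    st <- advance_flow(st, list(nodes = nodes1, open_edge = open_edge,
                                p_edge = p_edge), props, config)
    scalar_active <- k > scalar_start
    if (scalar_active) {
      st <- advance_residence(st, open_edge, dt, fv = dom$fv)
    }
    log[[k]] <- tibble::tibble(
      step = k, time = t1, ke = st$ke, div_max = st$div_max,
      flux_open = st$flux_open, dvdt = st$dvdt,
      dadt = st$dadt, mass_resid = st$mass_resid,
      mitral_open = mitral_now,
      c_mean = if (scalar_active) mean(st$c) else NA_real_,
      c_max = if (scalar_active) max(st$c) else NA_real_,
      scalar_time = st$scalar_time)
    if (k == eval_step) {
      snapshot <- list(mesh = st$mesh, c = st$c, time = t1,
                       scalar_time = st$scalar_time,
                       ostium = .ostium_at(motion, t1))
    }
    if (k %% steps_per_cycle == 0) {
      ke_at_phase <- c(ke_at_phase, st$ke)
      if (scalar_active) {
        os <- .ostium_at(motion, t1)
        per_cycle[[length(per_cycle) + 1L]] <- dplyr::mutate(
          regional_stasis(list(mesh = st$mesh, c = st$c), os, rr,
                          evaluation_phase = 0,
                          n_cycles = (k - scalar_start) %/% steps_per_cycle),
          cycle = (k - scalar_start) %/% steps_per_cycle)
      }
      if (verbose) {
        message(sprintf("cycle %d/%d done (t = %.3f s)",
                        k %/% steps_per_cycle, total_cycles, t1))
      }
    }
    remesh_due <- k %% config$remesh_interval_steps == 0
    if (remesh_due && k < n_steps) {
      st <- remesh_and_transfer(st, config = config)
      dom <- setup(st, t1, k)
      open_base <- grepl("^pv_inlet", st$mesh$boundary$label)
      mitral_edges <- st$mesh$boundary$label == "mitral"
    }
  }
  log <- dplyr::bind_rows(log)
  cyc <- tibble::tibble(cycle = seq_along(ke_at_phase), ke_end = ke_at_phase)
  if (nrow(cyc) > 1) cyc$ke_change <- c(NA, abs(diff(cyc$ke_end)))
  regional <- if (!is.null(snapshot) && !is.null(snapshot$ostium)) {
    regional_stasis(list(mesh = snapshot$mesh, c = snapshot$c),
                    snapshot$ostium, rr,
                    evaluation_phase = config$evaluation_phase,
                    n_cycles = scalar_cycles)
  } else NULL
  structure(list(state = st, log = log, cycle_summary = cyc,
                 snapshot = snapshot, regional = regional,
                 per_cycle_regional = dplyr::bind_rows(per_cycle),
                 config = config, props = props,
                 steps_per_cycle = steps_per_cycle,
                 rr_interval = rr),
            class = "flow_run")
}

#' Simulate the residence time of a moving chamber
#'
#' Initializes the flow for `init_cycles` cardiac cycles, then solves the
#' residence-time transport equation for `n_cycles` further cycles starting
#' from Tres = 0, and summarizes regional stasis at the evaluation phase
#' (end systole by default) of the final cycle.
#'
#' @param motion a `motion_field` with region labels (see [run_cycles()]).
#' @param props,config solver inputs.
#' @param n_cycles scalar (residence-time) cycles; default 6.
#' @param init_cycles flow initialization cycles; defaults to
#'   `config$init_cycles`.
#' @param ... passed to [run_cycles()].
#' @return a `flow_run` whose `regional` element holds the
#'   [regional_stasis()] summary and `per_cycle_regional` the cycle-by-cycle
#'   convergence trace.
#' @export
run_residence <- function(motion, props = fluid_properties(),
                          config = solver_config(), n_cycles = 6,
                          init_cycles = NULL, ...) {
  if (!is.null(init_cycles)) config$init_cycles <- as.integer(init_cycles)
  run_cycles(motion, props, config, n_cycles = config$init_cycles,
             scalar_cycles = n_cycles, ...)
}

#' @export
print.flow_run <- function(x, ...) {
  cat("<flow_run>", max(x$log$step), "steps,",
      nrow(x$cycle_summary), "cycles, RR", sprintf("%.3f s", x$rr_interval))
  if (!is.null(x$regional)) {
    cat(sprintf("; RT LA+LAA %.2f CC, LAA %.2f CC",
                x$regional$rt_la_with_laa, x$regional$rt_laa))
  }
  cat("\n")
  invisible(x)
}
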