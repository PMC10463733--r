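# Surface-based wall motion tracking: the phase-0 reference boundary is
# deformed by a non-rigid iterative closest point (ICP) scheme to match the
# segmentation of every other phase. The non-rigid model is a per-vertex
# displacement field with Laplacian smoothness regularization on the
# boundary graph; the regularization weight decreases over the iterations
# (coarse-to-fine). Rigid translations lie in the null space of the
# regularizer and are therefore recovered exactly.

#' Parameters for non-rigid ICP registration
#'
#' @param max_iterations outer correspondence/solve iterations (default 50).
#' @param tolerance mean point-to-target distance (mm) at which the
#'   registration is considered converged (default 0.1).
#' @param lambda_start,lambda_end Laplacian regularization weight of each
#'   incremental update at the first and last iteration; interpolated
#'   geometrically in between.
#' @param mu persistent Laplacian roughness penalty on the accumulated
#'   displacement field; discourages tangential vertex sliding (rigid
#'   translations are unpenalized) while leaving smooth local deformation
#'   free.
#' @param check if TRUE (default), error when the deformed boundary is
#'   self-intersecting or inverted.
#' @return a named list of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 50L, tolerance = 0.1,
                       lambda_start = 100, lambda_end = 1, mu = 1,
                       check = TRUE) {
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, lambda_start = lambda_start,
                 lambda_end = lambda_end, mu = mu, check = check),
            class = "icp_params")
}

# graph Laplacian of a closed polyline with n vertices (sparse)
.polyline_laplacian <- function(n) {
  i <- rep(seq_len(n), 3)
  j <- c(seq_len(n), c(2:n, 1L), c(n, 1:(n - 1)))
  x <- c(rep(2, n), rep(-1, 2 * n))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

.as_target_polyline <- function(target, phase = 1L, label = 1L) {
  if (inherits(target, "mask_series")) {
    return(mask_contour(target, phase = phase, label = label))
  }
  if (inherits(target, "surface_series")) {
    return(series_polygon(target, phase, "la")$vertices)
  }
  if (is.matrix(target) && ncol(target) == 2) return(target)
  stop("target must be a polygon matrix, mask_series or surface_series",
       call. = FALSE)
}

#' Non-rigid ICP registration of a closed boundary to a target
#'
#' Deforms `reference` (an n x 2 closed polygon, mm) to match `target`
#' (polygon or binary mask; a mask is contoured first). Each iteration
#' finds the closest point on the target for every deformed vertex and
#' solves a linear system balancing correspondence fit against Laplacian
#' smoothness of the displacement field.
#'
#' @param reference n x 2 matrix, closed counter-clockwise polygon.
#' @param target target boundary: polygon matrix, `mask_series`, or
#'   `surface_series`.
#' @param params an [icp_params()].
#' @param init optional n x 2 initial displacement (e.g. the previous
#'   phase's result when tracking a series).
#' @param phase,label phase index / chamber label used when `target` is a
#'   `mask_series`.
#' @return list with `displacement` (n x 2, mm), `residual_mean`,
#'   `residual_max` (mm), `converged`, and `iterations`. Warns (without
#'   failing) when `max_iterations` is reached above tolerance.
#' @export
register_nonrigid_icp <- function(reference, target, params = icp_params(),
                                  init = NULL, phase = 1L, label = 1L) {
  stopifnot(is.matrix(reference), ncol(reference) == 2)
  n <- nrow(reference)
  if (n < 4) stop("reference boundary is degenerate", call. = FALSE)
  if (polygon_area(reference) <= 0) {
    stop("reference must be closed and counter-clockwise oriented",
         call. = FALSE)
  }
  tgt <- .as_target_polyline(target, phase = phase, label = label)
  if (nrow(tgt) < 4) stop("target boundary is empty or degenerate",
                          call. = FALSE)
  L <- .polyline_laplacian(n)
  I <- Matrix::Diagonal(n)
  d <- if (is.null(init)) matrix(0, n, 2) else init
  # similarity (Procrustes) pre-alignment: recovers the rigid/scale bulk of
  # the motion exactly before the non-rigid stage refines locally
  for (it in seq_len(20L)) {
    cur <- reference + d
    cp <- closest_point_on_polyline(cur, tgt)
    X <- sweep(cur, 2, colMeans(cur))
    Y <- sweep(cp$points, 2, colMeans(cp$points))
    sv <- svd(crossprod(X, Y))
    R <- sv$v %*% diag(sign(c(1, det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    s <- sum(diag(R %*% crossprod(X, Y))) / sum(X^2)
    t_vec <- colMeans(cp$points) - s * colMeans(cur %*% t(R))
    new_pos <- s * cur %*% t(R) + matrix(t_vec, n, 2, byrow = TRUE)
    if (max(abs(new_pos - cur)) < 1e-10) break
    d <- d + (new_pos - cur)
  }
  lam <- exp(seq(log(params$lambda_start), log(params$lambda_end),
                 length.out = params$max_iterations))
  res_mean <- Inf
  it_used <- 0L
  # incremental solves: each iteration computes a Laplacian-smoothed update
  # towards the current correspondences, so fine-scale deformation (e.g. an
  # inflating appendage) accumulates over iterations while every step stays
  # locally smooth
  for (it in seq_len(params$max_iterations)) {
    it_used <- it
    cp <- closest_point_on_polyline(reference + d, tgt)
    res_mean <- mean(cp$dist)
    A <- I + (lam[it] + params$mu) * L
    r <- cp$points - (reference + d) - params$mu * as.matrix(L %*% d)
    step <- cbind(as.vector(Matrix::solve(A, r[, 1])),
                  as.vector(Matrix::solve(A, r[, 2])))
    d <- d + step
    if (res_mean <= params$tolerance && max(abs(step)) < 1e-9) break
  }
  converged <- res_mean <= params$tolerance
  if (!converged) {
    warning(sprintf(
      "non-rigid ICP did not reach tolerance %.3g mm (mean residual %.3g mm after %d iterations)",
      params$tolerance, res_mean, it_used), call. = FALSE)
  }
  deformed <- reference + d
  if (params$check) {
    if (polygon_area(deformed) <= 0) {
      stop("deformed boundary is inverted (signed area <= 0)", call. = FALSE)
    }
    if (!polygon_is_simple(deformed)) {
      stop("deformed boundary is self-intersecting", call. = FALSE)
    }
  }
  list(displacement = d,
       residual_mean = res_mean,
       residual_max = max(closest_point_on_polyline(deformed, tgt)$dist),
       converged = converged,
       iterations = it_used)
}

#' Track a boundary across a full cardiac cycle
#'
#' Registers the phase-1 reference boundary to the segmentation of every
#' other phase with [register_nonrigid_icp()], initializing each phase from
#' the previous phase's displacement (chaining). The result is a
#' `motion_field`: per-vertex displacements of the reference at every phase.
#'
#' @param reference n x 2 reference polygon (phase 1), or a
#'   `surface_series` from which the phase-1 LA polygon is taken.
#' @param targets per-phase segmentations covering all phases in cycle
#'   order: a `mask_series` (phase 1 is skipped as it corresponds to the
#'   reference) or a list of polygon matrices for phases 2..P.
#' @param params an [icp_params()].
#' @param rr_interval,phase_fractions cycle timing; inferred from `targets`
#'   when it is a `mask_series`.
#' @param label chamber label for mask targets.
#' @return an object of class `motion_field`: `reference` (vertices),
#'   `displacements` (list of n x 2 matrices, one per phase including the
#'   zero field of phase 1), `phase_fractions`, `rr_interval`, and a
#'   `residuals` tibble.
#' @export
track_series <- function(reference, targets, params = icp_params(),
                         rr_interval = NULL, phase_fractions = NULL,
                         label = 1L) {
  if (inherits(reference, "surface_series")) {
    if (is.null(rr_interval)) rr_interval <- reference$rr_interval
    reference <- series_polygon(reference, 1L, "la")$vertices
  }
  if (inherits(targets, "mask_series")) {
    np <- length(targets$masks)
    if (np < 2) stop("tracking needs at least 2 phases", call. = FALSE)
    if (is.null(rr_interval)) rr_interval <- targets$rr_interval
    if (is.null(phase_fractions)) phase_fractions <- targets$phase_fractions
    tgt_list <- lapply(2:np, function(k) mask_contour(targets, k, label))
  } else if (is.list(targets)) {
    if (length(targets) < 1) stop("tracking needs at least 2 phases",
                                  call. = FALSE)
    tgt_list <- targets
    np <- length(targets) + 1L
  } else {
    stop("targets must be a mask_series or a list of polygons", call. = FALSE)
  }
  if (is.null(phase_fractions)) phase_fractions <- (seq_len(np) - 1) / np
  if (is.null(rr_interval)) {
    stop("rr_interval must be provided when targets carry no timing",
         call. = FALSE)
  }
  n <- nrow(reference)
  disp <- vector("list", np)
  disp[[1]] <- matrix(0, n, 2)
  resid <- vector("list", np)
  resid[[1]] <- tibble::tibble(phase = 1L, residual_mean = 0,
                               residual_max = 0, converged = TRUE)
  prev <- NULL
  for (k in 2:np) {
    reg <- tryCatch(
      register_nonrigid_icp(reference, tgt_list[[k - 1]], params, init = prev),
      error = function(e) {
        stop("tracking failed at phase ", k, ": ", conditionMessage(e),
             call. = FALSE)
      })
    disp[[k]] <- reg$displacement
    prev <- reg$displacement
    resid[[k]] <- tibble::tibble(phase = k, residual_mean = reg$residual_mean,
                                 residual_max = reg$residual_max,
                                 converged = reg$converged)
  }
  structure(list(reference = reference, displacements = disp,
                 phase_fractions = phase_fractions,
                 rr_interval = rr_interval,
                 residuals = dplyr::bind_rows(resid),
                 dimension = 2L),
            class = "motion_field")
}

#' Exact motion field of a synthetic series
#'
#' The synthetic generator preserves vertex correspondence across phases, so
#' the true wall motion is available without registration: displacements are
#' simply the per-phase vertex differences from phase 1. Used as ground
#' truth for validating the tracker and as the default motion input of the
#' flow solver.
#'
#' @param series a 2D `surface_series`.
#' @param component `"la"` or `"lv"`.
#' @return a `motion_field` with zero residuals, carrying the component's
#'   per-edge region labels as `reference_labels`.
#' @export
motion_from_series <- function(series, component = c("la", "lv")) {
  component <- match.arg(component)
  stopifnot(inherits(series, "surface_series"))
  if (series$dimension != 2L) {
    stop("motion_from_series() supports the 2D desk mode", call. = FALSE)
  }
  ref <- series_polygon(series, 1L, component)
  np <- length(series$phases)
  idx <- series$component_vertices[[component]]
  disp <- lapply(seq_len(np), function(k) {
    series$phases[[k]][idx, , drop = FALSE] - ref$vertices
  })
  structure(list(reference = ref$vertices, displacements = disp,
                 phase_fractions = series$phase_fractions,
                 rr_interval = series$rr_interval,
                 residuals = tibble::tibble(phase = seq_len(np),
                                            residual_mean = 0,
                                            residual_max = 0,
                                            converged = TRUE),
                 dimension = 2L,
                 reference_labels = ref$label,
                 ostium = series$ostium,
                 depth_mm = series$depth_mm,
                 series = series,
                 component = component),
            class = "motion_field")
}

#' Periodic displacement splines of a motion field
#'
#' Builds one periodic cubic spline per vertex coordinate through the phase
#' displacements (with the wrap point at one full cycle), giving C1
#' velocities and exactly periodic motion.
#'
#' @param motion a `motion_field`.
#' @return a function `f(time, deriv = 0)` returning an n x dim matrix of
#'   displacements (mm, `deriv = 0`) or velocities (mm/s, `deriv = 1`) at
#'   an arbitrary time (s), periodic in the RR interval.
#' @export
motion_splines <- function(motion) {
  stopifnot(inherits(motion, "motion_field"))
  rr <- motion$rr_interval
  tt <- c(motion$phase_fractions, 1) * rr
  n <- nrow(motion$reference)
  dim_n <- ncol(motion$reference)
  np <- length(motion$displacements)
  funs <- vector("list", n * dim_n)
  for (v in seq_len(n)) {
    for (d in seq_len(dim_n)) {
      y <- vapply(seq_len(np), function(k) motion$displacements[[k]][v, d],
                  numeric(1))
      funs[[(v - 1) * dim_n + d]] <- stats::splinefun(tt, c(y, y[1]),
                                                      method = "periodic")
    }
  }
  function(time, deriv = 0) {
    tmod <- time %% rr
    out <- matrix(0, n, dim_n)
    for (v in seq_len(n)) {
      for (d in seq_len(dim_n)) {
        out[v, d] <- funs[[(v - 1) * dim_n + d]](tmod, deriv = deriv)
      }
    }
    out
  }
}

#' Wall velocity at an arbitrary time
#'
#' Time derivative of the periodic displacement splines. The cycle integral
#' of the velocity vanishes for every vertex (periodic motion), so each
#' point returns to its start after one cycle.
#'
#' @param motion a `motion_field`.
#' @param time time in seconds; must lie in `[0, rr_interval)` unless
#'   `wrap = TRUE`.
#' @param wrap allow times outside one cycle (wrapped periodically).
#' @return n x dim matrix of vertex velocities (mm/s).
#' @export
wall_velocity <- function(motion, time, wrap = FALSE) {
  stopifnot(inherits(motion, "motion_field"))
  if (!wrap && (time < 0 || time >= motion$rr_interval)) {
    stop("time outside the cardiac cycle; use wrap = TRUE to wrap",
         call. = FALSE)
  }
  motion_splines(motion)(time, deriv = 1)
}

#' @export
print.motion_field <- function(x, ...) {
  cat("<motion_field>", nrow(x$reference), "vertices,",
      length(x$displacements), "phases, RR",
      sprintf("%.3f s, max residual %.3g mm\n", x$rr_interval,
              max(x$residuals$residual_mean)))
  invisible(x)
}
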