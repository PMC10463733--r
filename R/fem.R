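# P1 finite-element kernels on triangle meshes. All assembly is vectorized
# over triangles; matrices are sparse (Matrix package). Coordinates here are
# in metres (the flow solver's internal unit).

# per-triangle geometry: areas and P1 shape-function gradients
.tri_geom <- function(nodes, tri) {
  x1 <- nodes[tri[, 1], 1]; y1 <- nodes[tri[, 1], 2]
  x2 <- nodes[tri[, 2], 1]; y2 <- nodes[tri[, 2], 2]
  x3 <- nodes[tri[, 3], 1]; y3 <- nodes[tri[, 3], 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  A <- det / 2
  b <- cbind(y2 - y3, y3 - y1, y1 - y2) / det   # d phi_i / dx
  c <- cbind(x3 - x2, x1 - x3, x2 - x1) / det   # d phi_i / dy
  list(A = A, bx = b, by = c)
}

# lumped mass vector (integral of each basis function)
.fem_mass_lumped <- function(g, tri, n) {
  m <- numeric(n)
  for (k in 1:3) {
    m <- m + as.numeric(tapply(g$A / 3, factor(tri[, k], levels = seq_len(n)),
                               sum, default = 0))
  }
  m[is.na(m)] <- 0
  m
}

# stiffness matrix: integral grad phi_i . grad phi_j
.fem_stiffness <- function(g, tri, n) {
  ii <- jj <- xx <- vector("list", 9)
  idx <- 1
  for (a in 1:3) for (b in 1:3) {
    ii[[idx]] <- tri[, a]
    jj[[idx]] <- tri[, b]
    xx[[idx]] <- g$A * (g$bx[, a] * g$bx[, b] + g$by[, a] * g$by[, b])
    idx <- idx + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# convection matrix for element-mean advecting field a (T x 2):
# integral phi_i (a . grad phi_j), plus streamline (SUPG-type) diffusion
# tau (a.grad phi_i)(a.grad phi_j) with tau = h/(2|a|), which upwinds the
# scheme at high cell Peclet number.
.fem_convection <- function(g, tri, n, a_elem, supg = 1) {
  agx <- matrix(0, length(g$A), 3)
  for (k in 1:3) agx[, k] <- a_elem[, 1] * g$bx[, k] + a_elem[, 2] * g$by[, k]
  anorm <- sqrt(rowSums(a_elem^2))
  h <- sqrt(2 * abs(g$A))
  tau <- supg * h / (2 * anorm + 1e-30)
  ii <- jj <- xx <- vector("list", 9)
  idx <- 1
  for (i in 1:3) for (j in 1:3) {
    ii[[idx]] <- tri[, i]
    jj[[idx]] <- tri[, j]
    xx[[idx]] <- g$A * (agx[, j] / 3 + tau * agx[, i] * agx[, j])
    idx <- idx + 1
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = c(n, n))
}

# nodal divergence functional of a P1 field u (N x 2):
# r_i = integral grad phi_i . u  (element-mean u)
.fem_div_rhs <- function(g, tri, n, u) {
  ue_x <- (u[tri[, 1], 1] + u[tri[, 2], 1] + u[tri[, 3], 1]) / 3
  ue_y <- (u[tri[, 1], 2] + u[tri[, 2], 2] + u[tri[, 3], 2]) / 3
  r <- numeric(n)
  for (k in 1:3) {
    contrib <- g$A * (g$bx[, k] * ue_x + g$by[, k] * ue_y)
    r <- r + as.numeric(tapply(contrib, factor(tri[, k], levels = seq_len(n)),
                               sum, default = 0))
  }
  r[is.na(r)] <- 0
  r
}

# nodal gradient functional of a P1 scalar p: G_i = integral phi_i grad p
.fem_grad_rhs <- function(g, tri, n, p) {
  px <- g$bx[, 1] * p[tri[, 1]] + g$bx[, 2] * p[tri[, 2]] +
        g$bx[, 3] * p[tri[, 3]]
  py <- g$by[, 1] * p[tri[, 1]] + g$by[, 2] * p[tri[, 2]] +
        g$by[, 3] * p[tri[, 3]]
  gx <- gy <- numeric(n)
  for (k in 1:3) {
    f <- factor(tri[, k], levels = seq_len(n))
    gx <- gx + as.numeric(tapply(g$A / 3 * px, f, sum, default = 0))
    gy <- gy + as.numeric(tapply(g$A / 3 * py, f, sum, default = 0))
  }
  gx[is.na(gx)] <- 0; gy[is.na(gy)] <- 0
  cbind(gx, gy)
}

# per-triangle divergence of a P1 field
.fem_div_elem <- function(g, tri, u) {
  (g$bx[, 1] * u[tri[, 1], 1] + g$bx[, 2] * u[tri[, 2], 1] +
   g$bx[, 3] * u[tri[, 3], 1] +
   g$by[, 1] * u[tri[, 1], 2] + g$by[, 2] * u[tri[, 2], 2] +
   g$by[, 3] * u[tri[, 3], 2])
}

# boundary functional: r_i = integral_bnd phi_i (v . n) over the listed
# edges; edges are (a, b) node pairs ordered CCW along the boundary so the
# outward normal is (dy, -dx). v is nodal (N x 2).
.fem_boundary_flux_rhs <- function(nodes, edges, n, v) {
  a <- edges[, 1]; b <- edges[, 2]
  dx <- nodes[b, 1] - nodes[a, 1]
  dy <- nodes[b, 2] - nodes[a, 2]
  vn_a <- v[a, 1] * dy - v[a, 2] * dx   # (v . n) * len at node a
  vn_b <- v[b, 1] * dy - v[b, 2] * dx
  r <- numeric(n)
  # trapezoidal edge quadrature: int phi_a (v.n) = len/6 (2 vn_a + vn_b)
  r_a <- (2 * vn_a + vn_b) / 6
  r_b <- (vn_a + 2 * vn_b) / 6
  r <- r + as.numeric(tapply(c(r_a, r_b), factor(c(a, b), levels = seq_len(n)),
                             sum, default = 0))
  r[is.na(r)] <- 0
  r
}

# gradient operator matrices: (Gx p)_i = integral phi_i dp/dx, likewise Gy.
# Used to build the consistent projection Laplacian G^T M^-1 G.
.fem_grad_ops <- function(g, tri, n) {
  ii <- jj <- xg <- yg <- vector("list", 9)
  idx <- 1
  for (i in 1:3) for (j in 1:3) {
    ii[[idx]] <- tri[, i]
    jj[[idx]] <- tri[, j]
    xg[[idx]] <- g$A / 3 * g$bx[, j]
    yg[[idx]] <- g$A / 3 * g$by[, j]
    idx <- idx + 1
  }
  list(Gx = Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                 x = unlist(xg), dims = c(n, n)),
       Gy = Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                                 x = unlist(yg), dims = c(n, n)))
}

# impose Dirichlet rows on a sparse system (row replacement)
.apply_dirichlet <- function(A, rhs, idx, vals) {
  if (length(idx) == 0) return(list(A = A, rhs = rhs))
  n <- nrow(A)
  D <- Matrix::Diagonal(n, x = as.numeric(!(seq_len(n) %in% idx)))
  A2 <- D %*% A + Matrix::sparseMatrix(i = idx, j = idx, x = 1, dims = c(n, n))
  rhs[idx] <- vals
  list(A = A2, rhs = rhs)
}
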