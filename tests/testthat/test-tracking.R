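test_that("registration is exact on identity and recovers rigid motion", {
  ref <- series_polygon(default_series(), 1, "la")$vertices
  # identity target: zero displacement to machine precision
  r0 <- register_nonrigid_icp(ref, ref)
  expect_lt(max(abs(r0$displacement)), 1e-9)
  expect_true(r0$converged)
  # known translation recovered within 1%
  tr <- sweep(ref, 2, c(3, -2), "+")
  r1 <- register_nonrigid_icp(ref, tr)
  expect_lt(abs(mean(r1$displacement[, 1]) - 3), 0.03)
  expect_lt(abs(mean(r1$displacement[, 2]) + 2), 0.02)
  # rotation: residual to the rotated target < 1% of the chamber size
  ctr <- colMeans(ref)
  th <- 10 * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  rot <- sweep(sweep(ref, 2, ctr) %*% t(R), 2, ctr, "+")
  r2 <- register_nonrigid_icp(ref, rot)
  expect_lt(r2$residual_mean / diff(range(ref[, 1])), 0.01)
  # uniform scaling: deformed volume ratio within 2% of s^2
  sc <- sweep(sweep(ref, 2, ctr) * 1.10, 2, ctr, "+")
  r3 <- register_nonrigid_icp(ref, sc)
  ratio <- polygon_area(ref + r3$displacement) / polygon_area(ref)
  expect_lt(abs(ratio / 1.1^2 - 1), 0.02)
})

test_that("registration rejects degenerate inputs", {
  ref <- series_polygon(default_series(), 1, "la")$vertices
  expect_error(register_nonrigid_icp(ref[1:3, ], ref), "degenerate")
  expect_error(register_nonrigid_icp(ref[rev(seq_len(nrow(ref))), ], ref),
               "counter-clockwise")
  expect_error(register_nonrigid_icp(ref, ref[1:2, , drop = FALSE]),
               "degenerate")
})

test_that("tracking a voxelized series recovers the volume curve to 3%", {
  series <- default_series()
  masks <- default_masks(0.5)
  mf <- suppressWarnings(track_series(series, masks))
  expect_identical(length(mf$displacements), 20L)
  vols <- vapply(seq_along(mf$displacements), function(k) {
    polygon_area(mf$reference + mf$displacements[[k]]) *
      series$depth_mm / 1000
  }, numeric(1))
  gt <- series$ground_truth$v_la + series$ground_truth$v_laa
  expect_lt(max(abs(vols - gt) / gt), 0.03)
  # two identical phases give zero relative displacement
  ref <- series_polygon(series, 1, "la")$vertices
  mf2 <- track_series(ref, list(ref, ref), rr_interval = 1)
  expect_lt(max(abs(mf2$displacements[[2]] - mf2$displacements[[3]])), 1e-6)
  # single-phase input errors
  expect_error(track_series(series, structure(list(masks = masks$masks[1]),
                                              class = "mask_series")),
               "at least 2 phases")
})

test_that("wall velocity differentiates periodic motion correctly", {
  # single moving vertex x(t) = A sin(2 pi t / T), 20 phases
  A <- 5; T <- 1
  ph <- (0:19) / 20
  base <- cbind(c(0, 10, 10, 0, 0, 10, 5), c(0, 0, 10, 10, 5, 5, 7))
  disp <- lapply(ph, function(u) {
    d <- matrix(0, nrow(base), 2)
    d[1, 1] <- A * sin(2 * pi * u)
    d
  })
  m <- structure(list(reference = base, displacements = disp,
                      phase_fractions = ph, rr_interval = T,
                      dimension = 2L), class = "motion_field")
  v0 <- wall_velocity(m, 0)
  expect_lt(abs(v0[1, 1] / (2 * pi * A / T) - 1), 0.02)
  # stationary vertices have zero velocity at all times
  expect_lt(max(abs(v0[-1, ])), 1e-9)
  # cycle integral of velocity returns each vertex to its start
  f <- motion_splines(m)
  tt <- seq(0, T, length.out = 2001)
  dt <- diff(tt)[1]
  vx <- vapply(tt[-1], function(t) f(t, deriv = 1)[1, 1], numeric(1))
  expect_lt(abs(sum(vx) * dt), 1e-6)
  expect_lt(max(abs(f(T) - f(0))), 1e-9)
  # out-of-cycle times require the wrap flag
  expect_error(wall_velocity(m, 1.5), "wrap")
  expect_silent(wall_velocity(m, 1.5, wrap = TRUE))
})
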