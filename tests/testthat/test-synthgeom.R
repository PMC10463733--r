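test_that("chamber spec validation names the violated invariant", {
  expect_s3_class(chamber_spec(), "chamber_spec")
  expect_error(chamber_spec(la_ef = 1.2), "la_ef")
  expect_error(chamber_spec(la_ef = 0), "la_ef")
  expect_error(chamber_spec(lv_esv = 200, lv_edv = 150), "lv_esv")
  expect_error(chamber_spec(la_max_volume = -5), "la_max_volume")
  expect_error(chamber_spec(phase_count = 3), "phase_count")
  expect_error(chamber_spec(heart_rate = 0), "heart_rate")
})

test_that("volume waveforms are periodic, C1 and hit their extremes", {
  u <- seq(0, 1, by = 1 / 400)
  v_lv <- lv_volume_waveform(u, edv = 150, esv = 50)
  expect_equal(max(v_lv), 150)
  expect_equal(min(v_lv), 50)
  expect_equal(v_lv[1], v_lv[length(v_lv)])  # periodic wrap
  v_la <- atrial_volume_waveform(u, vmax = 80, ef = 0.5)
  expect_equal(max(v_la), 80)
  expect_equal(min(v_la), 40)
  # derivative vanishes at the joins (cosine segments)
  expect_equal(lv_volume_waveform(0.35, 150, 50, deriv = TRUE), 0,
               tolerance = 1e-12)
  expect_equal(atrial_volume_waveform(0, 80, 0.5, deriv = TRUE), 0,
               tolerance = 1e-12)
})

test_that("generated series meets the spec volumes, EF and periodicity", {
  series <- default_series()
  expect_equal(length(series$phases), 20L)
  gt <- series$ground_truth
  # EF definition forces min = max (1 - EF)
  expect_equal(min(gt$v_la), 40, tolerance = 0.01)
  expect_equal(max(gt$v_la), 80, tolerance = 0.01)
  # computed (discretized) volumes track the analytic curve to < 1%
  d <- compute_descriptors(series)
  expect_lt(abs(d$la_max_vol / 80 - 1), 0.01)
  expect_lt(abs(d$la_min_vol / 40 - 1), 0.01)
  expect_lt(abs(d$la_ef / 50 - 1), 0.01)
  expect_lt(abs(d$laa_ef / 72 - 1), 0.01)
  # every phase boundary is closed, simple, outward oriented
  for (k in c(1, 8, 15)) {
    p <- series_polygon(series, k, "la")$vertices
    expect_gt(polygon_area(p), 0)
    expect_true(polygon_is_simple(p))
  }
  # motion is periodic: phase 0 and wrapped phase 1.0 coincide by shared
  # parameterization; the spline displacement at t = RR returns to zero
  m <- motion_from_series(series, "la")
  f <- motion_splines(m)
  expect_lt(max(abs(f(series$rr_interval))), 1e-9)
  # required opening regions exist
  expect_true("mitral" %in% series$region)
  expect_true("aortic" %in% series$region)
  expect_true(any(grepl("^pv_inlet", series$region)))
})

test_that("generation is deterministic and AF-like specs round-trip", {
  s1 <- generate_chamber_series(chamber_spec(la_max_volume = 80, la_ef = 0.5))
  s2 <- generate_chamber_series(chamber_spec(la_max_volume = 80, la_ef = 0.5))
  expect_identical(s1$phases, s2$phases)
  af <- generate_chamber_series(chamber_spec(la_max_volume = 133,
                                             la_ef = 0.43))
  d <- compute_descriptors(af)
  expect_lt(abs(d$la_ef / 43 - 1), 0.01)
})

test_that("3D mode recovers EF within 1% and volumes near-analytically", {
  s3 <- generate_chamber_series(chamber_spec(dimension = 3))
  d3 <- compute_descriptors(s3)
  expect_lt(abs(d3$la_ef / 53 - 1), 0.01)
  expect_lt(abs(d3$lv_ef / (100 * (1 - 47 / 145)) - 1), 0.01)
  expect_lt(abs(d3$la_max_vol / 87 - 1), 0.02)
})

test_that("cohort generation is reproducible and means converge (3 SE)", {
  cs <- cohort_spec(n_control = 2, n_af = 3, seed = 11)
  c1 <- generate_cohort(cs)
  c2 <- generate_cohort(cs)
  expect_identical(c1$la_ef, c2$la_ef)
  expect_identical(nrow(c1), 5L)
  expect_setequal(unique(c1$group), c("control", "af"))
  # empty cohort
  expect_identical(nrow(generate_cohort(cohort_spec(0, 0))), 0L)
  # law of large numbers at n = 2000: sample mean within 3 SE
  big <- generate_cohort(cohort_spec(n_control = 2000, n_af = 0, seed = 42))
  for (f in c("la_ef", "bsa", "la_max_idx")) {
    ms <- cohort_default_distributions()$control[[f]]
    se <- ms[2] / sqrt(2000)
    expect_lt(abs(mean(big[[f]]) - ms[1]), 3 * se)
  }
  # impossible distributions error
  bad <- cohort_default_distributions()
  bad$control$la_ef <- c(1.5, 0.01)
  expect_error(validate_cohort_spec(
    cohort_spec(parameter_distributions = bad)), "la_ef")
})

test_that("voxelization matches analytic and mesh volumes", {
  # unit cube (10 mm sides -> 1 ml) at 0.5 mm voxels
  cube <- list(
    vertices = 10 * rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                          c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)),
    triangles = rbind(c(1, 3, 2), c(1, 4, 3), c(5, 6, 7), c(5, 7, 8),
                      c(1, 2, 6), c(1, 6, 5), c(2, 3, 7), c(2, 7, 6),
                      c(3, 4, 8), c(3, 8, 7), c(4, 1, 5), c(4, 5, 8)))
  vx <- voxelize(cube, 0.5)
  expect_lt(abs(mask_volume(vx) / 1 - 1), 0.05)
  # 2D series mask volume vs analytic volume at 0.5 mm
  series <- default_series()
  vx2 <- default_masks(0.5)
  gt <- series$ground_truth$v_la[1] + series$ground_truth$v_laa[1]
  expect_lt(abs(mask_volume(vx2, 1, 1) / gt - 1), 0.05)
  # mask -> contour -> polygon round trip volume within 5%
  pg <- mask_contour(vx2, 1, 1)
  v_poly <- mesh_volume(pg, depth_mm = series$depth_mm, check = FALSE)
  expect_lt(abs(v_poly / gt - 1), 0.05)
  # invalid voxel sizes
  expect_error(voxelize(series, 0), "voxel_size")
  expect_error(voxelize(series, -1), "voxel_size")
})

test_that("surface series round-trips through the VTK writer", {
  series <- default_series()
  dir <- withr::local_tempdir()
  write_surface_series(series, dir)
  back <- read_surface_series(dir)
  expect_equal(back$phases[[1]], series$phases[[1]], tolerance = 1e-6)
  expect_identical(back$facets, series$facets)
  expect_identical(back$region, series$region)
  expect_equal(back$rr_interval, series$rr_interval)
  d0 <- compute_descriptors(series)
  db <- compute_descriptors(back, bsa = d0$bsa)
  expect_equal(db$la_ef, d0$la_ef, tolerance = 1e-4)
})

test_that("solver config round-trips through YAML", {
  cfg <- solver_config(dt = 1e-3, desk_scale = 10, idw_neighbors = 4)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_solver_config(cfg, path)
  back <- read_solver_config(path)
  expect_equal(back$dt, 1e-3)
  expect_equal(back$idw_neighbors, 4L)
  expect_equal(back$desk_scale, 10)
})
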