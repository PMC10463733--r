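test_that("mesh_volume matches analytic shapes and flags bad orientation", {
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  expect_equal(mesh_volume(sq, depth_mm = 10), 1)       # 1 ml cube-equivalent
  expect_error(mesh_volume(sq[4:1, ], depth_mm = 10), "orientation")
  bow <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))        # self-intersecting
  expect_error(mesh_volume(bow, depth_mm = 10), "self-intersecting")
  expect_error(mesh_volume(sq), "depth_mm")
  # icosphere r = 10 mm with >= 1280 facets: within 1% of 4/3 pi r^3,
  # converging under refinement
  err <- vapply(2:4, function(s) {
    ico <- icosphere(10, s)
    abs(mesh_volume(ico) * 1000 / (4 * pi * 1000 / 3) - 1)
  }, numeric(1))
  expect_gte(nrow(icosphere(10, 3)$triangles), 1280)
  expect_lt(err[2], 0.01)
  expect_true(all(diff(err) < 0))
  # reversed orientation and open surface error
  ico <- icosphere(5, 2)
  expect_error(mesh_volume(list(vertices = ico$vertices,
                                triangles = ico$triangles[, c(1, 3, 2)])),
               "orientation")
  expect_error(mesh_volume(list(vertices = ico$vertices,
                                triangles = ico$triangles[-1, ])),
               "not closed")
})

test_that("ejection fraction follows its definition and bounds", {
  expect_equal(ejection_fraction(100, 50), 50)
  expect_equal(ejection_fraction(41, 19), 100 * (41 - 19) / 41,
               tolerance = 1e-12)  # ~53.66, consistent with a 53% group mean
  expect_equal(ejection_fraction(70, 70), 0)
  expect_error(ejection_fraction(50, 60), "exceeds")
  expect_error(ejection_fraction(0, 0), "v_max")
})

test_that("retention ratio reproduces the printed group ratios", {
  expect_equal(round(retention_ratio(41 * 2.13, 98), 1), 0.9)
  expect_equal(round(retention_ratio(66 * 2.02, 106), 1), 1.3)
  expect_equal(retention_ratio(87, 87), 1)
  expect_error(retention_ratio(80, 0), "lv_sv")
  expect_error(retention_ratio(80, -5), "lv_sv")
})

test_that("BSA indexing is plain division with input checks", {
  expect_equal(index_by_bsa(87.33, 2.13), 41, tolerance = 1e-3)
  expect_equal(index_by_bsa(0, 1.9), 0)
  expect_equal(index_by_bsa(42, 1), 42)
  expect_error(index_by_bsa(42, 0), "bsa")
})

test_that("flow rates recover the analytic derivative of a cosine curve", {
  n <- 20; T <- 1; A <- 30; V0 <- 100
  v <- V0 + A * cos(2 * pi * (0:(n - 1)) / n)
  fr <- flow_rates(v, T)
  expect_lt(abs(fr$peak_mitral_flow / (2 * pi * A / T) - 1), 0.02)
  expect_lt(abs(fr$peak_aortic_flow / (2 * pi * A / T) - 1), 0.02)
  # constant volume -> no flow
  fr0 <- flow_rates(rep(100, 8), 1)
  expect_equal(fr0$peak_mitral_flow, 0)
  expect_equal(fr0$peak_aortic_flow, 0)
  expect_error(flow_rates(c(1, 2, 3), 1), "4 phases")
  expect_error(flow_rates(v, 0), "rr_interval")
})

test_that("ostium split partitions volume additively in 2D and 3D", {
  series <- default_series()
  sp <- split_laa(series, phase = 1)
  # additivity within 0.5%
  expect_lt(abs((sp$v_la_body + sp$v_laa) / sp$v_total - 1), 0.005)
  # appendage volume matches generator ground truth within 2%
  expect_lt(abs(sp$v_laa / series$ground_truth$v_laa[1] - 1), 0.02)
  # plane beyond the appendage tip
  pg <- series_polygon(series, 1, "la")$vertices
  expect_error(split_laa(pg, point = c(min(pg[, 1]) - 5, 0),
                         normal = c(-1, 0), depth_mm = 20), "empty LAA")
  # 3D split on the revolved geometry
  s3 <- generate_chamber_series(chamber_spec(dimension = 3))
  sp3 <- split_laa(s3, phase = 1)
  expect_lt(abs((sp3$v_la_body + sp3$v_laa) / sp3$v_total - 1), 0.005)
  expect_lt(abs(sp3$v_laa / s3$ground_truth$v_laa[1] - 1), 0.02)
})

test_that("EF and retention ratio are invariant to uniform scaling", {
  series <- default_series()
  d <- compute_descriptors(series)
  scaled <- series
  s <- 1.7
  scaled$phases <- lapply(series$phases, function(v) v * s)
  scaled$ostium <- lapply(series$ostium, function(o) {
    list(point = o$point * s, normal = o$normal)
  })
  d2 <- compute_descriptors(scaled)
  expect_equal(d2$la_ef, d$la_ef, tolerance = 1e-9)
  expect_equal(d2$la_retention_ratio, d$la_retention_ratio, tolerance = 1e-9)
  expect_equal(d2$la_max_vol, d$la_max_vol * s^2, tolerance = 1e-9)
})

test_that("descriptor table carries clinical report headers", {
  d <- compute_descriptors(default_series())
  tab <- descriptor_table(d)
  expect_true("LA retention ratio (-)" %in% names(tab))
  expect_true("LA Max Volume,Idx (ml/m^2)" %in% names(tab))
  expect_equal(tab[["LV Stroke Volume (ml)"]], d$lv_sv)
  expect_equal(d$lv_sv, d$lv_edv - d$lv_esv)
})
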