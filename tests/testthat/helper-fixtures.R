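# Shared fixtures: labelled rectangle polygons for channel/box benchmarks and
# a memoized default chamber series (generation is deterministic, so caching
# across test files is safe).

rect_polygon <- function(L, H, nx, ny,
                         left = "inlet", right = "outlet") {
  bot <- cbind(seq(0, L, length.out = nx + 1)[-(nx + 1)], 0)
  rgt <- cbind(L, seq(0, H, length.out = ny + 1)[-(ny + 1)])
  top <- cbind(seq(L, 0, length.out = nx + 1)[-(nx + 1)], H)
  lft <- cbind(0, seq(H, 0, length.out = ny + 1)[-(ny + 1)])
  list(v = rbind(bot, rgt, top, lft),
       lab = c(rep("wall", nx), rep(right, ny), rep("wall", nx),
               rep(left, ny)))
}

.fixture_env <- new.env(parent = emptyenv())

default_series <- function() {
  if (is.null(.fixture_env$series)) {
    .fixture_env$series <- generate_chamber_series(
      chamber_spec(la_max_volume = 80, la_ef = 0.50))
  }
  .fixture_env$series
}

default_masks <- function(voxel = 0.5) {
  key <- paste0("mask", voxel)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- voxelize(default_series(), voxel, component = "la")
  }
  .fixture_env[[key]]
}
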