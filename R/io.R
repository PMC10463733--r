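# On-disk interchange: legacy-VTK surface time series with a JSON sidecar,
# optional NIfTI masks (via RNifti), and YAML solver configuration.

#' Write a surface series as a VTK time series with a JSON sidecar
#'
#' One legacy ASCII VTK polydata file per phase (`phase_00.vtk`, ...) with
#' the region label as integer cell data, plus `series.json` carrying the
#' timing, the label dictionary, the depth convention, the ostium planes
#' and the analytic volume curves.
#'
#' @param series a `surface_series`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_surface_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- sort(unique(series$region))
  label_id <- stats::setNames(seq_along(labels) - 1L, labels)
  for (k in seq_along(series$phases)) {
    v <- series$phases[[k]]
    if (ncol(v) == 2) v <- cbind(v, 0)
    f <- file.path(dir, sprintf("phase_%02d.vtk", k - 1L))
    con <- file(f, "w")
    writeLines(c("# vtk DataFile Version 3.0",
                 "chamber surface", "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d float", nrow(v))), con)
    utils::write.table(format(v, digits = 10, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    fc <- series$facets
    if (ncol(fc) == 2) {
      writeLines(sprintf("LINES %d %d", nrow(fc), 3 * nrow(fc)), con)
      utils::write.table(cbind(2L, fc - 1L), con, row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    } else {
      writeLines(sprintf("POLYGONS %d %d", nrow(fc), 4 * nrow(fc)), con)
      utils::write.table(cbind(3L, fc - 1L), con, row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    }
    writeLines(c(sprintf("CELL_DATA %d", nrow(fc)),
                 "SCALARS region int 1", "LOOKUP_TABLE default"), con)
    writeLines(as.character(label_id[series$region]), con)
    close(con)
  }
  side <- list(
    dimension = series$dimension,
    phase_fractions = series$phase_fractions,
    rr_interval = series$rr_interval,
    depth_mm = series$depth_mm,
    labels = as.list(label_id),
    component = series$component,
    ostium = series$ostium,
    ground_truth = series$ground_truth
  )
  jsonlite::write_json(side, file.path(dir, "series.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a surface series written by [write_surface_series()]
#'
#' @param dir directory containing `phase_*.vtk` and `series.json`.
#' @return a `surface_series` (without the generating spec).
#' @export
read_surface_series <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "series.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^phase_\\d+\\.vtk$",
                           full.names = TRUE))
  if (length(files) == 0) stop("no phase_*.vtk files in ", dir, call. = FALSE)
  phases <- vector("list", length(files))
  facets <- NULL
  region_id <- NULL
  for (k in seq_along(files)) {
    ln <- readLines(files[k])
    np <- as.integer(sub("POINTS (\\d+) float", "\\1",
                         grep("^POINTS", ln, value = TRUE)[1]))
    i0 <- grep("^POINTS", ln)[1]
    pts <- utils::read.table(text = ln[(i0 + 1):(i0 + np)])
    v <- as.matrix(pts)
    if (side$dimension == 2) v <- v[, 1:2, drop = FALSE]
    phases[[k]] <- unname(v)
    if (k == 1L) {
      ic <- grep("^(LINES|POLYGONS)", ln)[1]
      nf <- as.integer(strsplit(ln[ic], " ")[[1]][2])
      fc <- utils::read.table(text = ln[(ic + 1):(ic + nf)])
      facets <- unname(as.matrix(fc[, -1, drop = FALSE]) + 1L)
      ir <- grep("^LOOKUP_TABLE", ln)[1]
      region_id <- as.integer(ln[(ir + 1):(ir + nf)])
    }
  }
  labels <- names(side$labels)[match(region_id, unlist(side$labels))]
  comp <- side$component
  n_la <- max(which(comp == 1L))
  ostium <- side$ostium
  if (is.data.frame(ostium)) {
    ostium <- lapply(seq_len(nrow(ostium)), function(i) {
      list(point = unlist(ostium$point[i]), normal = unlist(ostium$normal[i]))
    })
  }
  structure(list(
    dimension = as.integer(side$dimension),
    phases = phases,
    facets = facets,
    region = labels,
    component = comp,
    component_vertices = list(la = sort(unique(as.vector(facets[comp == 1L, ]))),
                              lv = sort(unique(as.vector(facets[comp == 2L, ])))),
    phase_fractions = side$phase_fractions,
    rr_interval = side$rr_interval,
    depth_mm = side$depth_mm,
    spec = NULL,
    ostium = ostium,
    ground_truth = tibble::as_tibble(side$ground_truth)
  ), class = "surface_series")
}

#' Write a mask series as NIfTI volumes
#'
#' Requires the suggested RNifti package. 2D masks are written as
#' single-slice volumes with the voxel size in the header.
#'
#' @param mask a `mask_series`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_mask_series <- function(mask, dir) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("writing NIfTI masks requires the RNifti package", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (k in seq_along(mask$masks)) {
    m <- mask$masks[[k]]
    if (length(dim(m)) == 2) dim(m) <- c(dim(m), 1L)
    img <- RNifti::asNifti(m, pixdim = rep(mask$voxel_size, 3))
    RNifti::writeNifti(img, file.path(dir, sprintf("mask_%02d.nii.gz", k - 1L)))
  }
  invisible(dir)
}

#' Read/write a solver configuration as YAML
#'
#' @param config a [solver_config()].
#' @param path YAML file path.
#' @return `write_solver_config()` returns `path` invisibly;
#'   `read_solver_config()` returns a `solver_config`.
#' @export
write_solver_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_solver_config
#' @export
read_solver_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(solver_config, vals[!vapply(vals, is.null, logical(1))])
}
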