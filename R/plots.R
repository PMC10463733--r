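# ggplot2 displays for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a chamber geometry series
#'
#' Overlays the closed chamber boundaries of selected phases, coloured by
#' phase, with region labels distinguishable by linetype.
#'
#' @param object a `surface_series` (2D).
#' @param phases phase indices to draw (default: 4 spread over the cycle).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.surface_series <- function(object, phases = NULL, ...) {
  stopifnot(object$dimension == 2L)
  np <- length(object$phases)
  if (is.null(phases)) phases <- unique(round(seq(1, np, length.out = 4)))
  df <- purrr::map_dfr(phases, function(k) {
    v <- object$phases[[k]]
    a <- object$facets[, 1]
    tibble::tibble(x = v[a, 1], y = v[a, 2],
                   xend = v[object$facets[, 2], 1],
                   yend = v[object$facets[, 2], 2],
                   region = object$region,
                   phase = sprintf("%.0f%% RR",
                                   100 * object$phase_fractions[k]))
  })
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       colour = .data$phase,
                                       linetype = .data$region != "la_body" &
                                         .data$region != "lv")) +
    ggplot2::coord_equal() +
    ggplot2::guides(linetype = "none") +
    ggplot2::labs(x = "x (mm)", y = "y (mm)", colour = "phase",
                  title = "Synthetic chamber boundaries over the cycle")
}

#' Plot the per-step log of a flow run
#'
#' Kinetic energy and (when present) the mean residence time against time,
#' with cycle boundaries marked.
#'
#' @param object a `flow_run`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.flow_run <- function(object, ...) {
  lg <- object$log
  df <- dplyr::bind_rows(
    tibble::tibble(time = lg$time, value = lg$ke,
                   quantity = "kinetic energy (J/m)"),
    tibble::tibble(time = lg$time, value = lg$c_mean,
                   quantity = "mean residence time (s)"))
  df <- df[is.finite(df$value), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::geom_vline(
      xintercept = object$rr_interval * seq_len(nrow(object$cycle_summary)),
      linetype = 3, colour = "grey60") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Flow run: per-step diagnostics")
}

#' Regional stasis boxplot by group
#'
#' Residence time by region (LA including the appendage, LA without it,
#' LAA alone) and group, with subject-level points overlaid.
#'
#' @param table cohort tibble with `group` and the `rt_*` columns.
#' @return a ggplot.
#' @export
plot_stasis_boxplot <- function(table) {
  df <- tidyr::pivot_longer(
    table[, c("group", "rt_la_with_laa", "rt_la_without_laa", "rt_laa")],
    -"group", names_to = "region", values_to = "rt")
  df$region <- factor(df$region,
                      levels = c("rt_la_with_laa", "rt_la_without_laa",
                                 "rt_laa"),
                      labels = c("LA with LAA", "LA without LAA", "LAA"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$rt,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6,
                          position = ggplot2::position_dodge(0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.12, dodge.width = 0.8), size = 1.2) +
    ggplot2::labs(x = NULL, y = "residence time (cardiac cycles)",
                  title = "Regional blood residence time by group")
}

#' Regression panel of residence time against descriptors
#'
#' One facet per predictor: observations, the OLS fit and its 95%
#' confidence band, annotated with R^2 and the slope p-value.
#'
#' @param table cohort tibble.
#' @param predictors descriptor column names to regress on.
#' @param response response column (default `rt_la_with_laa`).
#' @return a ggplot.
#' @export
plot_regression_panel <- function(table,
                                  predictors = c("la_max_vol_idx", "la_ef",
                                                 "la_retention_ratio",
                                                 "lv_sv"),
                                  response = "rt_la_with_laa") {
  pieces <- purrr::map(predictors, function(p) {
    r <- univariate_regression(table[[p]], table[[response]])
    xs <- seq(min(table[[p]]), max(table[[p]]), length.out = 50)
    band <- r$ci_band(xs)
    band$predictor <- p
    pts <- tibble::tibble(x = table[[p]], y = table[[response]],
                          predictor = p)
    lab <- tibble::tibble(predictor = p,
                          label = sprintf("R² = %.2f, p = %.3g",
                                          r$r_squared, r$p_value))
    list(band = band, pts = pts, lab = lab)
  })
  band <- dplyr::bind_rows(purrr::map(pieces, "band"))
  pts <- dplyr::bind_rows(purrr::map(pieces, "pts"))
  lab <- dplyr::bind_rows(purrr::map(pieces, "lab"))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$x, ymin = .data$lwr,
                                      ymax = .data$upr),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$x, y = .data$fit),
                       inherit.aes = FALSE) +
    ggplot2::geom_point() +
    ggplot2::geom_text(data = lab,
                       ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~predictor, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "residence time (cardiac cycles)",
                  title = "Univariate associations with atrial stasis")
}
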