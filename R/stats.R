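# Cohort statistics: two-sample t-tests for group comparisons, univariate
# OLS of residence time against cardiac descriptors with confidence bands
# and leave-one-out leverage reporting, and mean +/- SD table emitters.
# Model fitting goes through stats::t.test / stats::lm; this layer wraps
# them in the shapes the analysis needs and adds tidy()/glance() methods.

#' Two-sample t-test between groups
#'
#' Pooled-variance two-sample t-test by default (Welch available), with a
#' 5% significance flag.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param variant `"pooled"` (equal variances, default) or `"welch"`.
#' @param conf_level confidence level (default 0.95; significance is
#'   flagged at `1 - conf_level`).
#' @return object of class `stasis_ttest`: tidy with [generics::tidy()].
#' @examples
#' two_sample_ttest(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))$statistic
#' @export
two_sample_ttest <- function(a, b, variant = c("pooled", "welch"),
                             conf_level = 0.95) {
  variant <- match.arg(variant)
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each sample needs at least 2 observations", call. = FALSE)
  }
  ht <- tryCatch(
    stats::t.test(a, b, var.equal = variant == "pooled",
                  conf.level = conf_level),
    error = function(e) {
      # zero-variance samples: the limit of the pooled statistic
      d <- mean(a) - mean(b)
      list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
           p.value = if (d == 0) 1 else 0,
           parameter = c(df = length(a) + length(b) - 2),
           conf.int = c(d, d))
    })
  structure(list(
    mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
    mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
    statistic = unname(ht$statistic), p_value = ht$p.value,
    df = unname(ht$parameter), conf_int = unname(ht$conf.int),
    variant = variant,
    significant = ht$p.value < (1 - conf_level)
  ), class = "stasis_ttest")
}

#' @export
print.stasis_ttest <- function(x, ...) {
  cat(sprintf(
    "<stasis_ttest %s> %.3g +/- %.3g (n=%d) vs %.3g +/- %.3g (n=%d): t = %.3f, p = %.4g%s\n",
    x$variant, x$mean_a, x$sd_a, x$n_a, x$mean_b, x$sd_b, x$n_b,
    x$statistic, x$p_value, if (x$significant) " *" else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.stasis_ttest <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_a - x$mean_b,
    mean_a = x$mean_a, sd_a = x$sd_a, n_a = x$n_a,
    mean_b = x$mean_b, sd_b = x$sd_b, n_b = x$n_b,
    statistic = x$statistic, p.value = x$p_value, df = x$df,
    conf.low = x$conf_int[1], conf.high = x$conf_int[2],
    variant = x$variant, significant = x$significant)
}

#' Univariate regression of residence time on a descriptor
#'
#' Ordinary least squares `y ~ x` with R^2, the two-sided slope p-value,
#' a 95% confidence band for the mean response evaluable at any x, and a
#' leave-one-out leverage report: the slope p-value after deleting each
#' observation in turn, flagging points whose removal flips significance.
#'
#' @param x predictor values (n >= 3, not constant).
#' @param y response values (residence times).
#' @param conf_level confidence level of the band (default 0.95).
#' @return object of class `stasis_regression` with elements `fit` (the
#'   `lm`), `slope`, `intercept`, `r_squared`, `p_value`, `n`,
#'   `ci_band(x)` (function returning a tibble `fit`, `lwr`, `upr`), and
#'   `leverage` (leave-one-out tibble). Supports [generics::tidy()] and
#'   [generics::glance()].
#' @examples
#' r <- univariate_regression(1:10, 2 * (1:10) + 1)
#' c(r$slope, r$intercept, r$r_squared)
#' @export
univariate_regression <- function(x, y, conf_level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("regression needs at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("predictor is constant", call. = FALSE)
  df <- data.frame(x = x, y = y)
  fit <- stats::lm(y ~ x, data = df)
  sm <- summary(fit)
  alpha <- 1 - conf_level
  loo <- purrr::map_dfr(seq_len(n), function(i) {
    f <- stats::lm(y ~ x, data = df[-i, ])
    s <- summary(f)
    tibble::tibble(dropped = i, x = x[i], y = y[i],
                   slope = stats::coef(f)[["x"]],
                   p_value = s$coefficients["x", "Pr(>|t|)"])
  })
  p_full <- sm$coefficients["x", "Pr(>|t|)"]
  loo$flips_significance <- (p_full < alpha) != (loo$p_value < alpha)
  structure(list(
    fit = fit,
    slope = stats::coef(fit)[["x"]],
    intercept = stats::coef(fit)[["(Intercept)"]],
    slope_se = sm$coefficients["x", "Std. Error"],
    r_squared = sm$r.squared,
    p_value = p_full,
    n = n,
    conf_level = conf_level,
    significant = p_full < alpha,
    ci_band = function(x_new) {
      pr <- stats::predict(fit, newdata = data.frame(x = x_new),
                           interval = "confidence", level = conf_level)
      tibble::tibble(x = x_new, fit = pr[, "fit"], lwr = pr[, "lwr"],
                     upr = pr[, "upr"])
    },
    leverage = loo
  ), class = "stasis_regression")
}

#' @export
print.stasis_regression <- function(x, ...) {
  cat(sprintf(
    "<stasis_regression> slope %.4g (p = %.3g), R^2 = %.3f, n = %d%s\n",
    x$slope, x$p_value, x$r_squared, x$n,
    if (any(x$leverage$flips_significance))
      "; significance driven by single point(s)" else ""))
  invisible(x)
}

#' @export
tidy.stasis_regression <- function(x, ...) {
  co <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(co), estimate = co[, 1],
                 std.error = co[, 2], statistic = co[, 3], p.value = co[, 4])
}

#' @export
glance.stasis_regression <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n,
                 significant = x$significant,
                 n_leverage_flips = sum(x$leverage$flips_significance))
}

#' Group comparison table (mean +/- SD and t-test per field)
#'
#' Summarizes each numeric descriptor of a cohort table by group as
#' mean +/- SD and compares the groups with [two_sample_ttest()], flagging
#' p < 0.05.
#'
#' @param table cohort tibble with a `group` column (`"control"`/`"af"`)
#'   and numeric descriptor columns.
#' @param fields columns to summarize; defaults to all numeric columns.
#' @param variant t-test variant.
#' @return tibble: `field`, `control` (formatted), `af`, group means/SDs,
#'   `p_value`, `significant`.
#' @export
group_summary <- function(table, fields = NULL,
                          variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (!"group" %in% names(table)) stop("table needs a 'group' column",
                                       call. = FALSE)
  ga <- dplyr::filter(table, .data$group == "control")
  gb <- dplyr::filter(table, .data$group == "af")
  if (nrow(ga) == 0 || nrow(gb) == 0) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (is.null(fields)) {
    fields <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  purrr::map_dfr(fields, function(f) {
    if (!f %in% names(table)) stop("missing field '", f, "'", call. = FALSE)
    xa <- ga[[f]]; xb <- gb[[f]]
    bad <- c(ga$subject_id[!is.finite(xa)], gb$subject_id[!is.finite(xb)])
    if (length(bad) > 0) {
      stop("missing value of '", f, "' for subject ", bad[1], call. = FALSE)
    }
    tt <- two_sample_ttest(xa, xb, variant = variant)
    tibble::tibble(
      field = f,
      control = sprintf("%.3g ± %.2g", tt$mean_a, tt$sd_a),
      af = sprintf("%.3g ± %.2g", tt$mean_b, tt$sd_b),
      mean_control = tt$mean_a, sd_control = tt$sd_a, n_control = tt$n_a,
      mean_af = tt$mean_b, sd_af = tt$sd_b, n_af = tt$n_b,
      p_value = tt$p_value, significant = tt$significant)
  })
}

#' Residence time by appendage shape (subgroup table)
#'
#' Mean +/- SD of the regional residence times by appendage shape label
#' within each group, with a pooled t-test where both shape subgroups have
#' at least two members and descriptive statistics only otherwise.
#'
#' @param table cohort tibble with `group`, `laa_shape_label`, and the
#'   regional residence-time columns.
#' @param fields residence-time columns to report.
#' @return tibble with one row per group x field: subgroup summaries, `n`
#'   per subgroup, and `p_value` (NA when a subgroup has n < 2).
#' @export
shape_subgroup_analysis <- function(table,
                                    fields = c("rt_la_with_laa",
                                               "rt_la_without_laa",
                                               "rt_laa")) {
  if (!all(c("group", "laa_shape_label") %in% names(table))) {
    stop("table needs 'group' and 'laa_shape_label' columns", call. = FALSE)
  }
  fields <- intersect(fields, names(table))
  purrr::map_dfr(unique(table$group), function(g) {
    sub <- dplyr::filter(table, .data$group == g)
    cw <- sub[sub$laa_shape_label == "chicken_wing", , drop = FALSE]
    ncw <- sub[sub$laa_shape_label != "chicken_wing", , drop = FALSE]
    purrr::map_dfr(fields, function(f) {
      p <- if (nrow(cw) >= 2 && nrow(ncw) >= 2) {
        two_sample_ttest(cw[[f]], ncw[[f]])$p_value
      } else NA_real_
      tibble::tibble(
        group = g, field = f,
        mean_cw = mean(cw[[f]]), sd_cw = stats::sd(cw[[f]]),
        n_cw = nrow(cw),
        mean_non_cw = mean(ncw[[f]]), sd_non_cw = stats::sd(ncw[[f]]),
        n_non_cw = nrow(ncw),
        p_value = p)
    })
  })
}
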