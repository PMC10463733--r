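#' Draw a synthetic two-group cohort of chamber specifications
#'
#' Samples subject-level chamber parameters from the per-group normal
#' distributions of a [cohort_spec()]. Indexed volumes (ml/m^2) and BSA are
#' drawn jointly and multiplied into absolute volumes; LV end-systolic
#' volume is derived from the drawn end-diastolic volume and ejection
#' fraction. Draws violating a chamber invariant (e.g. an ejection fraction
#' outside (0, 1)) are rejected and redrawn, up to `max_redraws` per
#' subject, after which an error is raised. With a fixed seed the cohort is
#' fully reproducible.
#'
#' @param cohort a [cohort_spec()].
#' @return a tibble with one row per subject: `subject_id`, `group`
#'   (`"control"`/`"af"`), `sex`, the drawn parameters, and a list-column
#'   `spec` of [chamber_spec()] objects.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_control = 2, n_af = 3, seed = 7))
#' coh$group
#' @export
generate_cohort <- function(cohort) {
  validate_cohort_spec(cohort)
  n_total <- cohort$n_control + cohort$n_af
  if (n_total == 0) {
    return(tibble::tibble(subject_id = character(), group = character(),
                          sex = character(), spec = list()))
  }
  set.seed(cohort$seed)
  rows <- vector("list", n_total)
  i <- 0L
  for (g in c("control", "af")) {
    n_g <- if (g == "control") cohort$n_control else cohort$n_af
    pd <- cohort$parameter_distributions[[g]]
    for (s in seq_len(n_g)) {
      i <- i + 1L
      draw <- NULL
      for (attempt in seq_len(cohort$max_redraws)) {
        d <- lapply(pd, function(ms) stats::rnorm(1, ms[1], ms[2]))
        ok <- d$bsa > 0 && d$heart_rate > 0 &&
          d$la_max_idx > 0 && d$laa_max_idx > 0 && d$lv_edv_idx > 0 &&
          d$la_ef > 0.01 && d$la_ef < 0.99 &&
          d$laa_ef > 0.01 && d$laa_ef < 0.99 &&
          d$lv_ef > 0.01 && d$lv_ef < 0.99
        if (ok) { draw <- d; break }
      }
      if (is.null(draw)) {
        stop("could not draw a valid chamber spec for group '", g,
             "' within ", cohort$max_redraws, " redraws; ",
             "check the configured distributions", call. = FALSE)
      }
      shape <- if (stats::runif(1) < cohort$p_chicken_wing[[g]]) {
        "chicken_wing"
      } else {
        "non_chicken_wing"
      }
      sex <- if (stats::runif(1) < cohort$p_female[[g]]) "f" else "m"
      spec <- do.call(chamber_spec, c(list(
        la_max_volume = draw$la_max_idx * draw$bsa,
        la_ef = draw$la_ef,
        laa_max_volume = draw$laa_max_idx * draw$bsa,
        laa_ef = draw$laa_ef,
        lv_edv = draw$lv_edv_idx * draw$bsa,
        lv_esv = draw$lv_edv_idx * draw$bsa * (1 - draw$lv_ef),
        heart_rate = draw$heart_rate,
        bsa = draw$bsa,
        laa_shape_label = shape,
        sex = sex
      ), cohort$chamber_args))
      rows[[i]] <- tibble::tibble(
        subject_id = sprintf("%s_%02d", g, s),
        group = g, sex = sex,
        laa_shape_label = shape,
        bsa = draw$bsa, heart_rate = draw$heart_rate,
        la_max_idx = draw$la_max_idx, la_ef = draw$la_ef,
        laa_max_idx = draw$laa_max_idx, laa_ef = draw$laa_ef,
        lv_edv_idx = draw$lv_edv_idx, lv_ef = draw$lv_ef,
        spec = list(spec)
      )
    }
  }
  dplyr::bind_rows(rows)
}
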