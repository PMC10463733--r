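#' Specification of a synthetic heart-chamber geometry
#'
#' A `chamber_spec` fixes the size, function and timing of one synthetic
#' subject: maximum left-atrial (LA) and appendage (LAA) volumes and their
#' ejection fractions, left-ventricular (LV) end-diastolic and end-systolic
#' volumes, heart rate and body surface area. The synthetic generator
#' ([generate_chamber_series()]) turns a spec into a time series of closed
#' chamber boundaries over one cardiac cycle.
#'
#' Volumes are in millilitres; `la_max_volume` is the LA body volume
#' *excluding* the appendage (LA and LAA are specified separately, split at
#' the ostium). Ejection fractions are dimensionless in (0, 1).
#'
#' @param la_max_volume maximum LA body volume (ml).
#' @param la_ef LA ejection fraction, in (0, 1).
#' @param laa_max_volume maximum LAA volume (ml).
#' @param laa_ef LAA ejection fraction, in (0, 1).
#' @param lv_edv,lv_esv LV end-diastolic / end-systolic volume (ml),
#'   `lv_esv < lv_edv`.
#' @param heart_rate beats per minute; the RR interval is `60 / heart_rate` s.
#' @param bsa body surface area (m^2), used only for descriptor indexing.
#' @param laa_shape_label `"chicken_wing"` or `"non_chicken_wing"`; carried
#'   as a categorical label, does not alter the generated topology.
#' @param phase_count number of frames per cardiac cycle (default 20,
#'   i.e. one frame per 5% of the RR interval).
#' @param dimension 2 (planar chambers, the default desk-scale mode) or 3.
#' @param sex `"f"` or `"m"`; carried through to cohort tables.
#' @param depth_mm out-of-plane depth (mm) used to express planar areas as
#'   volumes in 2D mode.
#' @param neck_length_mm,neck_base_width_mm,neck_ostium_width_mm LAA neck
#'   geometry: length, width where it leaves the LA body, and width at the
#'   ostium (the narrowest point, where the appendage is split off). The
#'   ostium width is clamped automatically if the drawn LAA volume is too
#'   small to accommodate it.
#' @param n_pv_inlets number of pulmonary-vein inflow openings (1-6).
#'
#' @return an object of class `chamber_spec` (a named list).
#' @seealso [generate_chamber_series()], [generate_cohort()]
#' @examples
#' spec <- chamber_spec(la_max_volume = 80, la_ef = 0.5)
#' spec$heart_rate
#' @export
chamber_spec <- function(la_max_volume = 87,
                         la_ef = 0.53,
                         laa_max_volume = 6.8,
                         laa_ef = 0.72,
                         lv_edv = 145,
                         lv_esv = 47,
                         heart_rate = 67,
                         bsa = 2.13,
                         laa_shape_label = c("chicken_wing", "non_chicken_wing"),
                         phase_count = 20L,
                         dimension = 2L,
                         sex = c("m", "f"),
                         depth_mm = 20,
                         neck_length_mm = 8,
                         neck_base_width_mm = 12,
                         neck_ostium_width_mm = 7,
                         n_pv_inlets = 4L) {
  laa_shape_label <- match.arg(laa_shape_label)
  sex <- match.arg(sex)
  spec <- structure(list(
    la_max_volume = la_max_volume, la_ef = la_ef,
    laa_max_volume = laa_max_volume, laa_ef = laa_ef,
    lv_edv = lv_edv, lv_esv = lv_esv,
    heart_rate = heart_rate, bsa = bsa,
    laa_shape_label = laa_shape_label,
    phase_count = as.integer(phase_count),
    dimension = as.integer(dimension),
    sex = sex,
    depth_mm = depth_mm,
    neck_length_mm = neck_length_mm,
    neck_base_width_mm = neck_base_width_mm,
    neck_ostium_width_mm = neck_ostium_width_mm,
    n_pv_inlets = as.integer(n_pv_inlets)
  ), class = "chamber_spec")
  validate_chamber_spec(spec)
  spec
}

#' Validate a chamber specification
#'
#' Errors with a message naming the first violated invariant; returns the
#' spec invisibly when valid.
#'
#' @param spec a [chamber_spec()].
#' @return the spec, invisibly.
#' @export
validate_chamber_spec <- function(spec) {
  stopifnot(inherits(spec, "chamber_spec"))
  chk <- function(ok, what) {
    if (!isTRUE(ok)) stop("invalid chamber_spec: ", what, call. = FALSE)
  }
  num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (f in c("la_max_volume", "laa_max_volume", "lv_edv", "lv_esv")) {
    chk(num(spec[[f]]) && spec[[f]] > 0, paste0(f, " must be > 0"))
  }
  chk(num(spec$la_ef) && spec$la_ef > 0 && spec$la_ef < 1,
      "la_ef must lie strictly in (0, 1)")
  chk(num(spec$laa_ef) && spec$laa_ef > 0 && spec$laa_ef < 1,
      "laa_ef must lie strictly in (0, 1)")
  chk(spec$lv_esv < spec$lv_edv, "lv_esv must be smaller than lv_edv")
  chk(num(spec$heart_rate) && spec$heart_rate > 0,
      "heart_rate must be > 0 (RR interval = 60 / heart_rate)")
  chk(num(spec$bsa) && spec$bsa > 0, "bsa must be > 0")
  chk(spec$phase_count >= 4, "phase_count must be at least 4")
  chk(spec$dimension %in% c(2L, 3L), "dimension must be 2 or 3")
  chk(num(spec$depth_mm) && spec$depth_mm > 0, "depth_mm must be > 0")
  chk(spec$n_pv_inlets >= 1 && spec$n_pv_inlets <= 6,
      "n_pv_inlets must be between 1 and 6")
  invisible(spec)
}

#' Specification of a synthetic two-group cohort
#'
#' Describes per-group normal distributions (mean, sd) for each chamber
#' parameter, from which [generate_cohort()] draws subject-level
#' [chamber_spec()]s. Volumes are parameterized as body-surface-area-indexed
#' values (ml/m^2) together with BSA, mirroring how group summaries are
#' reported clinically; absolute volumes are derived per draw.
#'
#' @param n_control,n_af group sizes.
#' @param parameter_distributions a named list with elements `control` and
#'   `af`, each a named list of `c(mean, sd)` pairs for the fields
#'   `bsa`, `heart_rate`, `la_max_idx`, `la_ef`, `laa_max_idx`, `laa_ef`,
#'   `lv_edv_idx`, `lv_ef`. Defaults to [cohort_default_distributions()].
#' @param p_chicken_wing named numeric: probability of the chicken-wing
#'   appendage label per group.
#' @param p_female named numeric: probability of female sex per group.
#' @param seed integer seed controlling the draws.
#' @param max_redraws maximum redraws per subject when a draw violates a
#'   chamber invariant (default 100, after which an error is raised).
#' @param ... further arguments passed to every [chamber_spec()]
#'   (e.g. `phase_count`, `dimension`).
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 8L, n_af = 21L,
                        parameter_distributions = cohort_default_distributions(),
                        p_chicken_wing = c(control = 7 / 8, af = 16 / 21),
                        p_female = c(control = 3 / 8, af = 6 / 21),
                        seed = 1L, max_redraws = 100L, ...) {
  spec <- structure(list(
    n_control = as.integer(n_control), n_af = as.integer(n_af),
    parameter_distributions = parameter_distributions,
    p_chicken_wing = p_chicken_wing, p_female = p_female,
    seed = as.integer(seed), max_redraws = as.integer(max_redraws),
    chamber_args = list(...)
  ), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

#' Default cohort parameter distributions
#'
#' Group means and standard deviations emulating a small clinical cohort of
#' controls and paroxysmal-AF patients: controls have smaller indexed atrial
#' volumes and higher atrial ejection fractions, while ventricular size and
#' function are comparable between groups.
#'
#' @return a named list with `control` and `af` sublists of `c(mean, sd)`.
#' @export
cohort_default_distributions <- function() {
  list(
    control = list(
      bsa = c(2.13, 0.28), heart_rate = c(67, 7),
      la_max_idx = c(41, 7), la_ef = c(0.53, 0.07),
      laa_max_idx = c(3.2, 1.3), laa_ef = c(0.72, 0.07),
      lv_edv_idx = c(68, 18), lv_ef = c(0.69, 0.06)
    ),
    af = list(
      bsa = c(2.02, 0.17), heart_rate = c(62, 8),
      la_max_idx = c(66, 15), la_ef = c(0.43, 0.09),
      laa_max_idx = c(6, 2.7), laa_ef = c(0.62, 0.12),
      lv_edv_idx = c(78, 11), lv_ef = c(0.67, 0.05)
    )
  )
}

#' @rdname cohort_spec
#' @param cohort a `cohort_spec` to validate.
#' @export
validate_cohort_spec <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  chk <- function(ok, what) {
    if (!isTRUE(ok)) stop("invalid cohort_spec: ", what, call. = FALSE)
  }
  chk(cohort$n_control >= 0 && cohort$n_af >= 0, "group sizes must be >= 0")
  pd <- cohort$parameter_distributions
  chk(is.list(pd) && all(c("control", "af") %in% names(pd)),
      "parameter_distributions must have 'control' and 'af' entries")
  fields <- c("bsa", "heart_rate", "la_max_idx", "la_ef", "laa_max_idx",
              "laa_ef", "lv_edv_idx", "lv_ef")
  for (g in c("control", "af")) {
    chk(all(fields %in% names(pd[[g]])),
        paste0("missing distribution fields for group '", g, "'"))
    for (f in fields) {
      ms <- pd[[g]][[f]]
      chk(length(ms) == 2 && all(is.finite(ms)) && ms[2] >= 0,
          paste0(g, "$", f, " must be c(mean, sd) with sd >= 0"))
    }
    for (f in c("la_ef", "laa_ef", "lv_ef")) {
      chk(pd[[g]][[f]][1] > 0 && pd[[g]][[f]][1] < 1,
          paste0(g, "$", f, " mean must lie in (0, 1)"))
    }
    for (f in c("bsa", "heart_rate", "la_max_idx", "laa_max_idx", "lv_edv_idx")) {
      chk(pd[[g]][[f]][1] > 0, paste0(g, "$", f, " mean must be > 0"))
    }
  }
  chk(cohort$max_redraws >= 1, "max_redraws must be >= 1")
  invisible(cohort)
}

#' @export
print.chamber_spec <- function(x, ...) {
  cat("<chamber_spec>", x$dimension, "D,",
      sprintf("LA %.1f ml (EF %.0f%%), LAA %.2f ml (EF %.0f%%), LV %.0f/%.0f ml, HR %.0f bpm\n",
              x$la_max_volume, 100 * x$la_ef, x$laa_max_volume, 100 * x$laa_ef,
              x$lv_edv, x$lv_esv, x$heart_rate))
  invisible(x)
}
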