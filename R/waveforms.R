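# Periodic chamber volume waveforms built from half-cosine segments.
#
# Phase 0 is pinned to LV end diastole (maximum LV volume). Ventricular
# systole ends (minimum LV volume, i.e. end systole) at 35% RR. The LA acts
# as a reservoir during ventricular systole (filling from the pulmonary
# veins while the mitral valve is closed) and empties during diastole, with
# a late active-contraction lobe starting at 85% RR. Each segment is a
# half-cosine ramp, so the derivative vanishes at every joint and the curve
# is C1 and periodic by construction. The timings are package defaults
# representing normal sinus physiology; only the extreme volumes are
# subject-specific.

# half-cosine ramp 0 -> 1 on s in [0, 1]
.ramp <- function(s) (1 - cos(pi * s)) / 2
.dramp <- function(s) pi * sin(pi * s) / 2

# Timing constants (fractions of RR)
.WF <- list(
  lv_es = 0.35,       # end systole
  lv_fill_end = 0.55, # end of early (E-wave) filling
  lv_diastasis_end = 0.80,
  e_frac = 0.70,      # fraction of stroke volume in early filling
  d_frac = 0.05,      # fraction in diastasis
  a_frac = 0.25,      # fraction in atrial kick
  la_peak = 0.35,     # LA maximum (end ventricular systole)
  la_passive_end = 0.70,
  la_plateau_end = 0.85,
  la_passive_frac = 0.60, # fraction of LA delta emptied passively
  la_plateau_frac = 0.05
)

#' Left-ventricular volume waveform
#'
#' Periodic LV volume over one cardiac cycle: systolic ejection to 35% RR,
#' early diastolic filling, diastasis, and an atrial-kick lobe from 80% RR.
#'
#' @param u phase as a fraction of the RR interval (any real; wrapped).
#' @param edv,esv end-diastolic and end-systolic volumes (ml).
#' @param deriv if TRUE return dV/du (ml per RR fraction) instead of V.
#' @return volume (ml) or its phase derivative.
#' @keywords internal
lv_volume_waveform <- function(u, edv, esv, deriv = FALSE) {
  u <- u %% 1
  sv <- edv - esv
  w <- .WF
  seg_starts <- c(0, w$lv_es, w$lv_fill_end, w$lv_diastasis_end, 1)
  base <- c(edv, esv, esv + w$e_frac * sv, esv + (w$e_frac + w$d_frac) * sv)
  amp <- c(-sv, w$e_frac * sv, w$d_frac * sv, w$a_frac * sv)
  k <- findInterval(u, seg_starts, rightmost.closed = TRUE)
  k[k > 4] <- 4L
  s <- (u - seg_starts[k]) / (seg_starts[k + 1] - seg_starts[k])
  if (deriv) {
    amp[k] * .dramp(s) / (seg_starts[k + 1] - seg_starts[k])
  } else {
    base[k] + amp[k] * .ramp(s)
  }
}

#' Atrial volume waveform (LA body or LAA)
#'
#' Periodic reservoir/conduit curve: minimum at phase 0 (end diastole, after
#' atrial contraction), filling to the maximum at end ventricular systole
#' (35% RR), passive emptying, a short plateau (diastasis), and active
#' contraction from 85% RR back to the minimum.
#'
#' @inheritParams lv_volume_waveform
#' @param vmax maximum volume (ml).
#' @param ef ejection fraction in (0, 1); the minimum is `vmax * (1 - ef)`.
#' @keywords internal
atrial_volume_waveform <- function(u, vmax, ef, deriv = FALSE) {
  u <- u %% 1
  vmin <- vmax * (1 - ef)
  dv <- vmax - vmin
  w <- .WF
  seg_starts <- c(0, w$la_peak, w$la_passive_end, w$la_plateau_end, 1)
  base <- c(vmin, vmax, vmax - w$la_passive_frac * dv,
            vmin + (1 - w$la_passive_frac - w$la_plateau_frac) * dv)
  amp <- c(dv, -w$la_passive_frac * dv, -w$la_plateau_frac * dv,
           -(1 - w$la_passive_frac - w$la_plateau_frac) * dv)
  k <- findInterval(u, seg_starts, rightmost.closed = TRUE)
  k[k > 4] <- 4L
  s <- (u - seg_starts[k]) / (seg_starts[k + 1] - seg_starts[k])
  if (deriv) {
    amp[k] * .dramp(s) / (seg_starts[k + 1] - seg_starts[k])
  } else {
    base[k] + amp[k] * .ramp(s)
  }
}

#' Phase of end systole
#'
#' Fraction of the RR interval at which the LV volume is minimal in the
#' synthetic waveforms (used as the default stasis evaluation phase).
#'
#' @return a scalar fraction of RR.
#' @export
end_systole_phase <- function() .WF$lv_es
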