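#' Apoptosis (caspase cascade) state
#'
#' Two-stage protease amplifier: a cellular damage signal activates
#' procaspase 9 to caspase 9, which both activates further procaspase 9
#' (autocatalysis) and converts procaspase 3 to caspase 3, the proximal cause
#' of cell death.  Crossing the caspase 3 threshold irreversibly commits the
#' cohort; the population engine then removes committed cells at a fixed
#' death rate.  With zero damage input the off state (no active caspases) is
#' stable: basal procaspase turnover alone never triggers the cascade.
#'
#' @param anti_apoptotic_scale Multiplier on the commitment threshold,
#'   the lumped effect of anti-apoptotic protein expression (default 1).
#' @return Object of class `apoptosis_state` with fields `procaspase9`,
#'   `caspase9`, `procaspase3`, `caspase3`, `committed`, `arrest_clock`.
#' @export
apoptosis_state <- function(anti_apoptotic_scale = 1) {
  stopifnot(anti_apoptotic_scale > 0)
  d <- .cyclosim_defaults
  structure(list(
    procaspase9 = d$casp_pro_synth / d$casp_pro_decay,
    caspase9 = 0,
    procaspase3 = d$casp_pro_synth / d$casp_pro_decay,
    caspase3 = 0,
    committed = FALSE,
    arrest_clock = 0,
    threshold = d$casp3_threshold * anti_apoptotic_scale
  ), class = "apoptosis_state")
}

#' Advance the caspase cascade
#'
#' Caspase 9 activation = basal damage-driven term + autocatalytic term;
#' caspase 3 is formed by caspase 9 catalysis of procaspase 3; all species
#' decay first order and procaspases are resynthesised.  `committed` is set,
#' irreversibly, when caspase 3 exceeds the threshold.
#'
#' @param state An [apoptosis_state()].
#' @param damage_signal Damage input (a.u., >= 0).
#' @param dt Step in hours (> 0); internally sub-stepped.
#' @return Updated `apoptosis_state`.
#' @export
update_apoptosis <- function(state, damage_signal = 0, dt) {
  stopifnot(dt > 0, damage_signal >= 0)
  d <- .cyclosim_defaults
  nsub <- max(1L, ceiling(dt / 0.05))
  h <- dt / nsub
  p9 <- state$procaspase9; c9 <- state$caspase9
  p3 <- state$procaspase3; c3 <- state$caspase3
  for (i in seq_len(nsub)) {
    act9 <- d$casp9_damage_act * damage_signal + d$casp9_auto_act * c9
    dp9 <- d$casp_pro_synth - d$casp_pro_decay * p9 - act9 * p9
    dc9 <- act9 * p9 - d$casp9_decay * c9
    cat3 <- d$casp3_cat * c9
    dp3 <- d$casp_pro_synth - d$casp_pro_decay * p3 - cat3 * p3
    dc3 <- cat3 * p3 - d$casp3_decay * c3
    p9 <- max(p9 + h * dp9, 0); c9 <- max(c9 + h * dc9, 0)
    p3 <- max(p3 + h * dp3, 0); c3 <- max(c3 + h * dc3, 0)
  }
  state$procaspase9 <- p9; state$caspase9 <- c9
  state$procaspase3 <- p3; state$caspase3 <- c3
  if (c3 > state$threshold) state$committed <- TRUE
  state
}

#' Damage signal from prolonged mitotic arrest
#'
#' Cohorts arrested at a checkpoint beyond the profile's tolerance
#' accumulate a damage signal proportional to the excess arrest time, which
#' feeds [update_apoptosis()].
#'
#' @param arrest_clock Hours of continuous arrest.
#' @param arrest_tolerance_h Tolerated arrest duration (profile parameter).
#' @return Damage signal (a.u., >= 0).
#' @export
arrest_damage_signal <- function(arrest_clock, arrest_tolerance_h) {
  .cyclosim_defaults$arrest_damage_rate *
    max(0, arrest_clock - arrest_tolerance_h)
}
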