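#' MAPK / EGF signalling state
#'
#' The EGF -> receptor -> RAS -> RAF -> MEK -> ERK cascade is represented by
#' normalised tier activities in \[0, 1\].  Because receptor occupancy and the
#' kinase tiers relax much faster than the cell-cycle processes they drive,
#' each tier is treated as quasi-steady in its upstream input: a basal
#' activity plus an input-proportional component, scaled by any tier-specific
#' inhibition.  Mutant RAS is pinned at its EGF-saturated activity regardless
#' of ligand or upstream inhibition, which is the operational definition of
#' constitutive activation used throughout.
#'
#' @param egf_conc EGF concentration (a.u.; saturating >> `egf_km`).
#' @return Object of class `mapk_state` with fields `egf_conc`,
#'   `receptor_occupancy`, `ras_active`, `raf_active`, `mek_active`,
#'   `erk_active`.
#' @export
mapk_state <- function(egf_conc = 0) {
  update_mapk(structure(list(egf_conc = 0, receptor_occupancy = 0,
                             ras_active = 0, raf_active = 0,
                             mek_active = 0, erk_active = 0),
                        class = "mapk_state"),
              egf_conc = egf_conc)
}

#' Update the MAPK cascade
#'
#' Recomputes the quasi-steady tier activities for the given EGF input, RAS
#' genotype and per-tier inhibitions.  `dt` is accepted for interface
#' symmetry with the other signalling modules but the update is exact at any
#' step because the cascade is quasi-steady.
#'
#' @param state A [mapk_state()].
#' @param egf_conc EGF concentration (>= 0).
#' @param ras_status `"wild"` or `"mutant"`.
#' @param inhibitions Numeric vector of length 5 in \[0,1\]: fractional
#'   inhibition of receptor, RAS, RAF, MEK and ERK (config hooks for the five
#'   upstream drug classes; all default 0).
#' @param dt Time step in hours (unused by the quasi-steady update).
#' @return Updated `mapk_state`.
#' @export
update_mapk <- function(state, egf_conc = state$egf_conc,
                        ras_status = c("wild", "mutant"),
                        inhibitions = rep(0, 5), dt = NULL) {
  ras_status <- match.arg(ras_status)
  stopifnot(length(inhibitions) == 5, all(inhibitions >= 0),
            all(inhibitions <= 1))
  if (!is.finite(egf_conc) || egf_conc < 0) {
    stop("egf_conc must be finite and >= 0", call. = FALSE)
  }
  b <- .cyclosim_defaults$mapk_basal
  tier <- function(input, inh) b + (1 - b) * input * (1 - inh)
  occ <- egf_conc / (egf_conc + .cyclosim_defaults$egf_km) *
    (1 - inhibitions[1])
  ras <- if (ras_status == "mutant") {
    # EGF-saturated wild-type output: occ -> 1, no inhibition upstream
    tier(1, 0)
  } else {
    tier(occ, inhibitions[2])
  }
  raf <- tier(ras, inhibitions[3])
  mek <- tier(raf, inhibitions[4])
  erk <- tier(mek, inhibitions[5])
  state$egf_conc <- egf_conc
  state$receptor_occupancy <- occ
  state$ras_active <- ras
  state$raf_active <- raf
  state$mek_active <- mek
  state$erk_active <- erk
  state
}

#' Cyclin D synthesis rate from ERK activity
#'
#' Saturating (Hill) function of ERK activity with a non-zero basal term, so
#' cells cycle slowly even without ligand, scaled by the profile's cyclin D
#' over-expression fold.
#'
#' @param state A [mapk_state()].
#' @param overexpression_fold Multiplier >= 0 (profile
#'   `cyclin_d_overexpression_fold`).
#' @return Synthesis rate in a.u./h.
#' @export
cyclin_d_production <- function(state, overexpression_fold = 1) {
  stopifnot(overexpression_fold >= 0)
  d <- .cyclosim_defaults
  erk <- state$erk_active
  drive <- erk^d$erk_cyclin_hill /
    (erk^d$erk_cyclin_hill + d$erk_cyclin_km^d$erk_cyclin_hill)
  (d$cyclin_d_prod_basal +
     (d$cyclin_d_prod_max - d$cyclin_d_prod_basal) * drive) *
    overexpression_fold
}
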