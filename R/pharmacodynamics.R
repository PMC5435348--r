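#' Drug model (mechanism class + Hill parameters)
#'
#' Every drug acts through a standard Hill concentration-effect law,
#' `effect = emax * C^n / (ec50^n + C^n)`, mapped onto the model by its
#' mechanism class:
#' \describe{
#'   \item{`non_cycle_specific_kill`}{kill rate (per hour) applied to every
#'     compartment except the five M states (transcription is inactive in
#'     mitosis); actinomycin D class.}
#'   \item{`s_phase_kill`}{kill rate (per hour) applied to the 30 S
#'     compartments only; gemcitabine class.}
#'   \item{`mitotic_arrest`}{fractional microtubule stabilisation (<= 1)
#'     slowing kinetochore attachment turnover; paclitaxel class.}
#'   \item{`cdk46_inhibition`}{fractional cdk4/6 inhibition (<= 1); the
#'     palbociclib class acting on the G1-S checkpoint.}
#'   \item{`aka_inhibition`, `akb_inhibition`}{fractional aurora kinase A/B
#'     inhibition (config-only hooks).}
#'   \item{`mapk_receptor_inhibition` ... `mapk_erk_inhibition`}{fractional
#'     inhibition of one MAPK tier (config-only hooks).}
#' }
#'
#' @param name Drug name (used to match schedule segments).
#' @param mechanism One of the classes above.
#' @param ec50 Half-effect concentration (nM, > 0).
#' @param hill_n Hill coefficient (> 0).
#' @param emax Maximal effect: a per-hour kill rate for the kill mechanisms,
#'   a fraction <= 1 for the inhibition/arrest mechanisms.
#' @return Object of class `drug_model`.
#' @export
drug_model <- function(name, mechanism = c("non_cycle_specific_kill",
                                           "s_phase_kill",
                                           "mitotic_arrest",
                                           "cdk46_inhibition",
                                           "aka_inhibition",
                                           "akb_inhibition",
                                           "mapk_receptor_inhibition",
                                           "mapk_ras_inhibition",
                                           "mapk_raf_inhibition",
                                           "mapk_mek_inhibition",
                                           "mapk_erk_inhibition"),
                       ec50, hill_n, emax) {
  mechanism <- match.arg(mechanism)
  stopifnot(ec50 > 0, hill_n > 0, emax >= 0)
  fractional <- !mechanism %in% c("non_cycle_specific_kill", "s_phase_kill")
  if (fractional && emax > 1) {
    stop("fractional-effect mechanisms require emax <= 1", call. = FALSE)
  }
  structure(list(name = as.character(name), mechanism = mechanism,
                 ec50 = ec50, hill_n = hill_n, emax = emax),
            class = "drug_model")
}

#' Built-in drug parameterizations
#'
#' Hill parameters for the four study drugs.  The source database for the
#' original parameter set is not public, so these values are calibration
#' constants fixed once against the reported simulation behaviour:
#' palbociclib 30-300 nM spans partial-to-strong G1 restriction and is
#' non-cytotoxic; 30 nM gemcitabine produces comparable single-agent effects
#' in the normal and malignant lines; 10 nM paclitaxel gives essentially
#' complete mitotic arrest over 24 h; actinomycin D around 30-100 nM gives
#' strong non-cycle-specific kill.
#'
#' @param name One of `"palbociclib"`, `"gemcitabine"`, `"paclitaxel"`,
#'   `"actinomycin_d"`.
#' @return A [drug_model()].
#' @export
builtin_drug <- function(name = c("palbociclib", "gemcitabine", "paclitaxel",
                                  "actinomycin_d")) {
  name <- match.arg(name)
  switch(name,
    palbociclib = drug_model("palbociclib", "cdk46_inhibition",
                             ec50 = 10, hill_n = 2, emax = 0.66),
    gemcitabine = drug_model("gemcitabine", "s_phase_kill",
                             ec50 = 30, hill_n = 2, emax = 0.40),
    paclitaxel = drug_model("paclitaxel", "mitotic_arrest",
                            ec50 = 2.5, hill_n = 2, emax = 1),
    actinomycin_d = drug_model("actinomycin_d", "non_cycle_specific_kill",
                               ec50 = 40, hill_n = 1.5, emax = 0.07)
  )
}

#' Hill concentration-effect law
#'
#' @param conc Concentration (>= 0, same units as `drug$ec50`).
#' @param drug A [drug_model()].
#' @return Effect in the drug's mechanism units (kill rate per hour or
#'   fractional inhibition); 0 at zero concentration, `emax/2` at the EC50,
#'   saturating at `emax`.
#' @export
hill_effect <- function(conc, drug) {
  stopifnot(all(conc >= 0))
  cn <- conc^drug$hill_n
  drug$emax * cn / (drug$ec50^drug$hill_n + cn)
}

#' Piecewise-constant drug exposure schedule
#'
#' @param segments Data frame with columns `drug`, `concentration`,
#'   `t_start`, `t_end` (hours).  Segments of different drugs may overlap
#'   (combinations) or be offset (delays); washout is implied at each
#'   segment end.
#' @return Object of class `exposure_schedule`.
#' @export
exposure_schedule <- function(segments = data.frame(drug = character(0),
                                                    concentration = numeric(0),
                                                    t_start = numeric(0),
                                                    t_end = numeric(0))) {
  stopifnot(is.data.frame(segments),
            all(c("drug", "concentration", "t_start", "t_end") %in%
                  names(segments)))
  if (nrow(segments) > 0) {
    stopifnot(all(segments$t_start < segments$t_end),
              all(segments$concentration >= 0))
  }
  segments$drug <- as.character(segments$drug)
  structure(list(segments = segments), class = "exposure_schedule")
}

#' One-drug, one-window schedule helper
#' @param drug_name Drug name.
#' @param concentration Concentration.
#' @param t_start,t_end Exposure window (hours).
#' @return An [exposure_schedule()].
#' @export
single_exposure <- function(drug_name, concentration, t_start = 0,
                            t_end = 24) {
  exposure_schedule(data.frame(drug = drug_name,
                               concentration = concentration,
                               t_start = t_start, t_end = t_end))
}

#' Concentrations in force at time t
#' @param schedule An [exposure_schedule()].
#' @param t Time (hours).
#' @return Named numeric vector of concentrations (one entry per drug with an
#'   active segment; concentrations of the same drug in overlapping segments
#'   add).
#' @export
exposure_at <- function(schedule, t) {
  seg <- schedule$segments
  act <- seg[seg$t_start <= t & t < seg$t_end, , drop = FALSE]
  if (nrow(act) == 0) return(stats::setNames(numeric(0), character(0)))
  tapply_named <- tapply(act$concentration, act$drug, sum)
  stats::setNames(as.numeric(tapply_named), names(tapply_named))
}

#' Event times of a schedule (segment starts/ends)
#' @param schedule An [exposure_schedule()].
#' @return Sorted unique times.
#' @export
schedule_breaks <- function(schedule) {
  sort(unique(c(schedule$segments$t_start, schedule$segments$t_end)))
}

#' Map active drug concentrations to model perturbations
#'
#' Evaluates each drug's Hill effect at its current concentration and routes
#' it to the corresponding model input: global (non-M) kill rate, S-phase
#' kill rate, microtubule stabilisation, cdk4/6 inhibition, aurora kinase
#' inhibitions and MAPK tier inhibitions.  Fractional effects of multiple
#' drugs with the same mechanism combine independently
#' (`1 - prod(1 - e_i)`); kill rates add.
#'
#' @param schedule An [exposure_schedule()].
#' @param t Time (hours).
#' @param drugs Named list of [drug_model()] objects (names must cover every
#'   drug appearing in the schedule).
#' @return List with `global_kill_rate`, `s_phase_kill_rate`,
#'   `sac` (a [sac_drug_effects()]), `palbociclib_inhibition`,
#'   `mapk_inhibitions` (length-5 vector).
#' @export
exposure_to_context <- function(schedule, t, drugs) {
  conc <- exposure_at(schedule, t)
  unknown <- setdiff(names(conc), names(drugs))
  if (length(unknown) > 0) {
    stop("no drug model for: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- list(global_kill_rate = 0, s_phase_kill_rate = 0,
              microtubule_stabilization = 0, aka_inhibition = 0,
              akb_inhibition = 0, palbociclib_inhibition = 0,
              mapk_inhibitions = rep(0, 5))
  frac_combine <- function(a, b) 1 - (1 - a) * (1 - b)
  mapk_idx <- c(mapk_receptor_inhibition = 1, mapk_ras_inhibition = 2,
                mapk_raf_inhibition = 3, mapk_mek_inhibition = 4,
                mapk_erk_inhibition = 5)
  for (nm in names(conc)) {
    dr <- drugs[[nm]]
    e <- hill_effect(conc[[nm]], dr)
    switch(dr$mechanism,
      non_cycle_specific_kill = out$global_kill_rate <-
        out$global_kill_rate + e,
      s_phase_kill = out$s_phase_kill_rate <- out$s_phase_kill_rate + e,
      mitotic_arrest = out$microtubule_stabilization <-
        frac_combine(out$microtubule_stabilization, e),
      cdk46_inhibition = out$palbociclib_inhibition <-
        frac_combine(out$palbociclib_inhibition, e),
      aka_inhibition = out$aka_inhibition <-
        frac_combine(out$aka_inhibition, e),
      akb_inhibition = out$akb_inhibition <-
        frac_combine(out$akb_inhibition, e),
      {
        i <- mapk_idx[[dr$mechanism]]
        out$mapk_inhibitions[i] <- frac_combine(out$mapk_inhibitions[i], e)
      }
    )
  }
  out$sac <- sac_drug_effects(out$microtubule_stabilization,
                              out$aka_inhibition, out$akb_inhibition)
  out
}

#' Cytotoxicity (percent reduction from the pre-treatment count)
#'
#' `100 * (1 - n_end / n_start)`; negative values mean net growth over the
#' window and are reported as such.
#'
#' @param n_start Cell count at treatment start (> 0).
#' @param n_end Cell count at window end.
#' @return Percent.
#' @export
cytotoxicity <- function(n_start, n_end) {
  if (any(n_start <= 0)) stop("n_start must be > 0", call. = FALSE)
  100 * (1 - n_end / n_start)
}

#' Viability as percent of untreated control
#' @param n_treated Treated live count.
#' @param n_control Untreated control live count at the matched time (> 0).
#' @return Percent.
#' @export
viability_percent_of_control <- function(n_treated, n_control) {
  if (any(n_control <= 0)) stop("control count must be > 0", call. = FALSE)
  100 * n_treated / n_control
}

#' Bliss-independence excess
#'
#' Interaction score in percentage points: observed combined effect minus the
#' Bliss-independence expectation `EA + EB - EA*EB/100`, where effects are
#' `100 - viability%`.  Negative scores indicate antagonism.
#'
#' @param effect_ab Observed combined effect (percent).
#' @param effect_a,effect_b Monotherapy effects (percent).
#' @return Score in percentage points.
#' @export
bliss_excess <- function(effect_ab, effect_a, effect_b) {
  expected <- effect_a + effect_b - effect_a * effect_b / 100
  effect_ab - expected
}
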