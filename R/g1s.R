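#' G1-S checkpoint state
#'
#' Continuous variables of the restriction-point axis: cyclin D activates
#' cdk4, cyclin E activates cdk2, the combined kinase activity phosphorylates
#' RB, phosphorylated RB releases E2F, and E2F drives both cyclin E synthesis
#' (a positive feedback that gives the checkpoint its switch-like response)
#' and myc, whose product with free E2F sets the G1 to S transition
#' permissiveness.  p21/p27 (p53-driven under damage input) inhibit cdk2.
#'
#' The drug-free configuration is monostable at the released (cycling) state;
#' strong cdk4 inhibition collapses the feedback loop and the permissiveness
#' falls to near zero, reversibly.
#'
#' @param cyclin_d,cyclin_e Initial cyclin levels (a.u.).
#' @param p21_p27_level Initial CDK-inhibitor level (a.u.).
#' @param rb_phosphorylated_fraction,e2f_free_fraction,myc_activity Initial
#'   fractions/activities in \[0,1\].
#' @return Object of class `g1s_state`.
#' @export
g1s_state <- function(cyclin_d = 0.7, cyclin_e = 1.5,
                      p21_p27_level = 0,
                      rb_phosphorylated_fraction = 0.7,
                      e2f_free_fraction = 0.7,
                      myc_activity = 0.7) {
  s <- structure(list(
    cyclin_d = cyclin_d, cyclin_e = cyclin_e,
    cdk4_activity = 0, cdk2_activity = 0,
    rb_phosphorylated_fraction = rb_phosphorylated_fraction,
    e2f_free_fraction = e2f_free_fraction,
    p21_p27_level = p21_p27_level,
    myc_activity = myc_activity
  ), class = "g1s_state")
  s$cdk4_activity <- cdk4_from_cyclin_d(cyclin_d, 0)
  s$cdk2_activity <- cdk2_from_cyclin_e(cyclin_e, p21_p27_level)
  s
}

cdk4_from_cyclin_d <- function(cyclin_d, palbociclib_inhibition) {
  d <- .cyclosim_defaults
  cyclin_d / (cyclin_d + d$cdk4_km) * (1 - palbociclib_inhibition)
}

cdk2_from_cyclin_e <- function(cyclin_e, p21_p27) {
  d <- .cyclosim_defaults
  cyclin_e / (cyclin_e + d$cdk2_km) * d$p21_km / (d$p21_km + p21_p27)
}

# exact update of x' = a - b x over dt (b > 0)
.relax <- function(x, a, b, dt) {
  xs <- a / b
  xs + (x - xs) * exp(-b * dt)
}

#' Advance the G1-S checkpoint state by one time step
#'
#' Cyclins integrate synthesis minus first-order decay (cyclin E synthesis is
#' E2F-driven), kinase activities follow their cyclins through saturating
#' kinetics (cdk4 scaled by `1 - palbociclib_inhibition`, cdk2 inhibited by
#' p21/p27), RB phosphorylation relaxes toward a steep Hill function of total
#' kinase activity, and free E2F and myc follow RB phosphorylation.  An
#' RB-null genotype pins free E2F at 1; a mutant p53 genotype silences the
#' damage-driven p21/p27 branch.
#'
#' @param state A [g1s_state()].
#' @param cyclin_d_production Synthesis rate from [cyclin_d_production()]
#'   (a.u./h, >= 0).
#' @param palbociclib_inhibition Fractional cdk4/6 inhibition in \[0,1\].
#' @param p21_p27_input p53-driven production rate of p21/p27 (a.u./h;
#'   0 unless a DNA-damage input is configured).
#' @param dt Step in hours (> 0).
#' @param rb_status `"positive"` or `"null"`.
#' @param p53_status `"wild"` or `"mutant"`.
#' @return Updated `g1s_state`.
#' @export
update_g1s <- function(state, cyclin_d_production, palbociclib_inhibition = 0,
                       p21_p27_input = 0, dt = 0.05,
                       rb_status = c("positive", "null"),
                       p53_status = c("wild", "mutant")) {
  rb_status <- match.arg(rb_status)
  p53_status <- match.arg(p53_status)
  stopifnot(dt > 0)
  if (cyclin_d_production < 0 || p21_p27_input < 0 ||
      palbociclib_inhibition < 0 || palbociclib_inhibition > 1) {
    stop("negative inputs or inhibition outside [0, 1]", call. = FALSE)
  }
  d <- .cyclosim_defaults
  if (p53_status == "mutant") p21_p27_input <- 0
  state$p21_p27_level <- .relax(state$p21_p27_level,
                                d$p21_damage_prod * p21_p27_input,
                                d$p21_decay, dt)
  state$cyclin_d <- .relax(state$cyclin_d, cyclin_d_production,
                           d$cyclin_d_decay, dt)
  state$cyclin_e <- .relax(state$cyclin_e,
                           d$cyclin_e_basal_prod +
                             d$cyclin_e_e2f_prod * state$e2f_free_fraction,
                           d$cyclin_e_decay, dt)
  state$cdk4_activity <- cdk4_from_cyclin_d(state$cyclin_d,
                                            palbociclib_inhibition)
  state$cdk2_activity <- cdk2_from_cyclin_e(state$cyclin_e,
                                            state$p21_p27_level)
  k <- state$cdk4_activity + state$cdk2_activity
  rb_target <- k^d$rb_hill / (k^d$rb_hill + d$rb_km^d$rb_hill)
  state$rb_phosphorylated_fraction <-
    .relax(state$rb_phosphorylated_fraction, rb_target / d$rb_tau,
           1 / d$rb_tau, dt)
  state$e2f_free_fraction <- if (rb_status == "null") 1 else
    state$rb_phosphorylated_fraction
  state$myc_activity <- .relax(state$myc_activity,
                               state$e2f_free_fraction / d$myc_tau,
                               1 / d$myc_tau, dt)
  state
}

#' G1 to S transition permissiveness
#'
#' Saturating increasing (Hill) function of the product of free E2F and myc
#' activity, returned to the population engine as the multiplier on the final
#' G1 compartment's outflow into S.
#'
#' @param state A [g1s_state()].
#' @return Multiplier in \[0, 1\].
#' @export
g1s_permissiveness <- function(state) {
  d <- .cyclosim_defaults
  x <- state$e2f_free_fraction * state$myc_activity
  x^d$perm_hill / (x^d$perm_hill + d$perm_km^d$perm_hill)
}

#' Signalling-dependent G1 duration
#'
#' G1 progression is driven by protein accumulation, which follows the
#' ERK/cyclin D growth signal: the G1 progression rate (the reciprocal mean
#' dwell) is a basal rate plus a term proportional to a saturating function
#' of the cyclin D level.  The two rate constants are calibration constants
#' fixed so the normal profile's drug-free doubling time spans its
#' basal-to-saturating EGF range.
#'
#' @param state A [g1s_state()].
#' @return Mean G1 duration in hours.
#' @export
g1_duration <- function(state) {
  d <- .cyclosim_defaults
  cd <- state$cyclin_d
  drive <- cd^d$g1_drive_hill / (cd^d$g1_drive_hill +
                                   d$g1_drive_km^d$g1_drive_hill)
  1 / (d$g1_rate_basal + d$g1_rate_span * drive)
}

#' Steady G1-S / MAPK signalling under constant conditions
#'
#' Iterates the MAPK and G1-S updates to convergence for fixed EGF, genotype
#' and drug inhibition, returning the equilibrated states.  Used for
#' asynchronous steady-state initialisation and analytic growth-rate
#' calculations.
#'
#' @param profile A [cell_line_profile()].
#' @param egf_conc EGF concentration.
#' @param palbociclib_inhibition Fractional cdk4/6 inhibition.
#' @param p21_p27_input Damage-driven p21/p27 production.
#' @param from Optional starting `g1s_state` (defaults to the cycling state).
#' @return List with elements `mapk`, `g1s`, `permissiveness`,
#'   `g1_duration_h`.
#' @export
g1s_steady <- function(profile, egf_conc = 0, palbociclib_inhibition = 0,
                       p21_p27_input = 0, from = NULL) {
  mapk <- update_mapk(mapk_state(), egf_conc = egf_conc,
                      ras_status = profile$ras_status)
  prod <- cyclin_d_production(mapk, profile$cyclin_d_overexpression_fold)
  g1s <- if (is.null(from)) g1s_state() else from
  dt <- 0.25
  for (i in seq_len(2000)) {
    prev <- unlist(g1s[c("cyclin_d", "cyclin_e", "e2f_free_fraction",
                         "myc_activity", "p21_p27_level")])
    g1s <- update_g1s(g1s, prod, palbociclib_inhibition, p21_p27_input, dt,
                      rb_status = profile$rb_status,
                      p53_status = profile$p53_status)
    cur <- unlist(g1s[c("cyclin_d", "cyclin_e", "e2f_free_fraction",
                        "myc_activity", "p21_p27_level")])
    if (max(abs(cur - prev)) < 1e-10) break
  }
  list(mapk = mapk, g1s = g1s,
       permissiveness = g1s_permissiveness(g1s),
       g1_duration_h = g1_duration(g1s))
}
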