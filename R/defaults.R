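# Central store of kinetic rate constants and calibrated defaults.
#
# The published account of this model prints its structure but not its rate
# constants, and the printed simulation outcomes (doubling-time range under
# EGF, checkpoint selectivity, combination antagonism) are therefore
# calibration targets: the values below were fixed once so that the default
# configuration reproduces them, and are not intended to be tuned per run.
# All concentrations of intracellular species are in arbitrary units (a.u.);
# drug concentrations are nM; times are hours; rates are per hour.

.cyclosim_defaults <- new.env(parent = emptyenv())

local({
  d <- .cyclosim_defaults

  ## --- MAPK / EGF cascade (quasi-steady tiers, normalised activities 0..1)
  d$mapk_basal <- 0.02          # basal activity of each tier at zero input
  d$egf_km <- 1                 # EGF receptor half-occupancy concentration (a.u.)
  d$erk_cyclin_km <- 0.25       # ERK half-max for cyclin D synthesis drive
  d$erk_cyclin_hill <- 2
  d$cyclin_d_prod_basal <- 0.1  # a.u./h, EGF-independent cyclin D synthesis
  d$cyclin_d_prod_max <- 1.0    # a.u./h at saturating ERK

  ## --- G1-S checkpoint
  d$cyclin_d_decay <- 0.25      # /h
  d$cdk4_km <- 1                # cyclin D half-max for cdk4 activation
  d$cyclin_e_basal_prod <- 0.05 # a.u./h
  d$cyclin_e_e2f_prod <- 0.95   # a.u./h at full free E2F
  d$cyclin_e_decay <- 0.5       # /h
  d$cdk2_km <- 1                # cyclin E half-max for cdk2 activation
  d$p21_km <- 0.5               # p21/p27 level halving cdk2 activity
  d$p21_decay <- 0.5            # /h
  d$p21_damage_prod <- 1        # a.u./h per unit p53 damage input (config hook)
  d$rb_km <- 0.8                # kinase activity half-max for RB phosphorylation
  d$rb_hill <- 4
  d$rb_tau <- 0.3               # h, RB phosphorylation relaxation time
  d$myc_tau <- 0.3              # h, myc relaxation toward free E2F
  d$perm_km <- 0.3              # E2F*myc half-max for G1->S permissiveness
  d$perm_hill <- 4

  ## --- EGF-modulated G1 dwell
  ## G1 progression rate = g1_rate_basal + g1_rate_span * drive(cyclin D);
  ## mean dwell is the reciprocal.  The drive is kept far from saturation
  ## (large km) so its dynamic range spans the basal-to-saturating cyclin D
  ## range; the two rate constants are calibrated so the normal profile's
  ## drug-free doubling time runs from ~25 h (basal EGF) to ~13 h
  ## (saturating EGF).
  d$g1_drive_km <- 20           # cyclin D half-max for the progression drive
  d$g1_drive_hill <- 2
  d$g1_rate_basal <- 0.03695205 # /h  (calibrated)
  d$g1_rate_span <- 34.636371   # /h  (calibrated)
  d$miapaca2_s_extension_h <- 12.544032 # h (calibrated: MiaPaca-2 drug-free Td ~26 h)

  ## --- Spindle assembly checkpoint
  d$sac_attach_rate <- 25       # /h unattached -> monotelic
  d$sac_second_rate <- 25       # /h monotelic -> (amphitelic | syntelic)
  d$sac_syntelic_frac <- 0.5    # geometry: second attachment to same pole
  d$sac_correction_rate <- 25   # /h syntelic -> monotelic (aurora kinase B)
  d$sac_wait_prod <- 50         # a.u./h at full production
  d$sac_wait_decay <- 25        # /h ("rapid decay" once tension complete)
  d$sac_wait_km <- 0.45         # non-amphitelic-fraction switch midpoint:
                                # above the standing fraction contributed by
                                # freshly entering (still-attaching) cells,
                                # below a drug-perturbed ensemble
  d$sac_wait_hill <- 6
  d$sac_threshold <- 0.5        # wait-signal level gating anaphase
  d$sac_slip_base <- 0.001      # /h slippage scale at aka_fold = 1
  d$sac_slip_aka <- 10          # slippage amplification per aka_fold unit
  d$sac_slip_ramp_h <- 6        # h, arrest-clock ramp time constant
  d$sac_slip_ramp_cap <- 2      # ramp saturates at this multiple
  d$n_kinetochore_pairs <- 46

  ## --- Apoptosis (caspase cascade)
  d$casp_pro_synth <- 0.5       # a.u./h procaspase synthesis (9 and 3)
  d$casp_pro_decay <- 0.1       # /h (procaspase pool ~5 a.u. at rest)
  d$casp9_damage_act <- 0.05    # /h per unit damage signal
  d$casp9_auto_act <- 0.1       # /h per unit caspase 9 (autocatalysis)
  d$casp9_decay <- 0.7          # /h (> auto_act * p9_rest keeps the off state)
  d$casp3_cat <- 1.0            # /h per unit caspase 9
  d$casp3_decay <- 0.5          # /h
  d$casp3_threshold <- 0.3      # commitment threshold (a.u.)
  d$arrest_damage_rate <- 0.5   # damage signal per hour of over-tolerance arrest
  d$apoptosis_death_rate <- 0.3 # /h removal of committed cohorts

  ## --- Numerics
  d$dt_max <- 0.05              # h, cap on the population integrator step
  d$rate_dt_cap <- 0.25         # max (rate * dt) allowed for the RK4 step
})

default_constants <- function() as.list(.cyclosim_defaults)
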