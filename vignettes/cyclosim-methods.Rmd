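---
title: "Modelling cyclotherapy: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cyclotherapy: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclosim)
```

This vignette documents the model behind `cyclosim`, the assumptions and
numerical choices it rests on, and the design decisions taken where the
biology under-determines the mathematics. It states no empirical result
that the package's test suite and acceptance script do not themselves
compute.

## The population model

A cell population is a vector of deterministic, real-valued counts over
63 cytokinetic states: 15 G1, 30 S, 10 G2 and 5 M compartments in a
chain, plus G0, a terminally differentiated/senescent pool and a damaged
(metabolically active, non-replicating) pool. The mean-field choice —
expected counts rather than stochastic agents — reflects the intended
scale of cultured populations of 10^5–10^7 cells, where demographic noise
is negligible; what the model deliberately omits is cell-to-cell
parameter variability, so a compartment is a *cohort* of identical cells.

Each compartment i empties at a first-order rate k_i, so a phase of
duration D modelled with n stages has per-stage rate n/D and an
Erlang(n)-distributed transit time with coefficient of variation
1/sqrt(n). This is the standard "linear chain" device: with 15–30 stages
per phase the transit-time distribution is narrow enough that the
population behaves nearly like a deterministic-delay model while
remaining a set of ODEs. The consequence to be aware of is a small,
systematic difference between the stage-structured growth rate (the root
of `R * prod(k_i/(k_i + lambda)) = 1`, with `R` the effective number of
cycling daughters per division) and the textbook closed form
`Td = Tc*log(2)/log(2(1-loss)(1-diff))`; for this compartment structure
the two agree to well under 1%, and the test suite holds the simulated
doubling time to the closed form within 2%.

At division, two daughters per telophase exit are partitioned **in this
order**: the spontaneous cell-loss factor first, then the
differentiating fraction, then the quiescent split. The order matters
because the composed fractions do not commute; the chosen order treats
spontaneous post-division death as acting on all daughters, and
lineage-exit decisions as made by surviving daughters. G0 re-entry is
off by default (`g0_return_rate = 0`): no stimulus model is included, so
quiescence is an absorbing annotation unless a return rate is
configured.

The book-keeping identity — live + G0 + differentiated + damaged +
cumulative dead − cumulative births is constant — is enforced by
construction (all fluxes are routed, none is dropped) and asserted in
the tests to 1e-6 relative.

### Asynchronous initialisation

"Asynchronous steady" starts place the cycling population on the stable
exponentially-growing stage distribution, computed by solving the
stage-structured Euler–Lotka equation for the growth rate and recursing
the stable stage weights. The quiescent fraction of the initial count is
placed in G0 (matching how quiescent fractions are tabulated for cell
lines), and the differentiated pool is seeded at its balanced-growth
share so that every output — including the total live count — grows
exponentially from t = 0 rather than after a transient.

## Signalling modules

All intracellular species are in arbitrary units; only their calibrated
input–output behaviour is meaningful. One signalling state is shared per
population: cohorts differ in cell-cycle position, not in signalling,
which is the coarsest faithful reading of a model whose drug inputs are
piecewise constant in time and uniform across the dish.

**EGF/MAPK.** Receptor occupancy is quasi-steady in EGF
(half-occupancy at 1 a.u.; "saturating" in the scenarios is 100).
Each tier (RAS, RAF, MEK, ERK) is a basal activity plus an
input-proportional term, scaled by an optional tier inhibition — five
drug-class hooks that no built-in scenario uses. Mutant RAS is pinned at
the EGF-saturated wild-type output regardless of ligand and upstream
inhibition; this *defines* constitutive activation, and the test suite
asserts the equality of the mutant and EGF-saturated wild-type
equilibria exactly. Receptor internalisation and ERK pulsatility are out
of scope: the cascade exists to set one number, the cyclin D synthesis
rate.

**G1-S checkpoint.** Cyclins integrate synthesis minus first-order
decay; cdk4 follows cyclin D saturably and is scaled by
`1 − palbociclib_inhibition`; cdk2 follows cyclin E and is inhibited by
p21/p27; RB phosphorylation relaxes (τ = 0.3 h) toward a steep Hill
function (n = 4) of total kinase activity; free E2F equals the
RB-phosphorylated fraction (RB-null pins it at 1); myc tracks E2F; and
the G1→S permissiveness is a Hill function (n = 4) of E2F·myc. Because
E2F drives cyclin E synthesis, the module is a positive-feedback switch:
drug-free it is monostable at the released state, while strong cdk4
inhibition collapses the loop and the permissiveness falls by many
orders of magnitude — reversibly, within roughly one G1 transit of
washout. The p53 → p21/p27 branch is structurally present but receives
zero input by default: DNA damage is not modelled in this release, so
mutant p53 has no dynamical consequence and the genotype is carried for
fidelity only.

G1 *progression* (protein accumulation) is distinct from the G1→S
*gate*: the per-stage G1 rate is `g1_rate_basal + g1_rate_span *
drive(cyclin D)`, with the drive a shallow Hill function of cyclin D
kept far from saturation so that its dynamic range spans the
basal-to-saturating cyclin D range. The two rate constants are the
model's principal growth calibration: they are solved (once, exactly,
via the Euler–Lotka equation) so that the normal profile's drug-free
doubling time is 25 h at basal EGF and 13 h at saturating EGF. cdk4/6
inhibition therefore acts only on the gate, not on intra-G1 progression
— a cdk4/6-inhibited cell still grows, it just cannot commit to S.

**Spindle assembly checkpoint.** Kinetochore pairs are a mean-field
ensemble over four attachment classes. Microtubule-stabilising drugs do
three things at once: slow attachment turnover, divert the second
attachment toward the tensionless syntelic configuration (the captured
fraction rises linearly with stabilisation from the 50/50 random-pole
default), and slow aurora-kinase-B error correction, which requires
depolymerisation of the faulty fibre. Jointly these make the expected
time to full bipolar attachment diverge as stabilisation approaches 1 —
this, not a hard block, is what sustains a many-hour arrest, and it
restores within minutes of washout.

The population engine advances one ensemble for the mitotic cohort with
a *dilution* term: freshly entering prometaphase cells are all-unattached
and pull the ensemble average toward the unattached corner at a rate
equal to the mitotic influx over the prometaphase+metaphase mass. The
wait signal is produced through a steep switch in the non-amphitelic
fraction (midpoint 0.45, above the standing entrant fraction; Hill 6),
divided by the aurora-kinase-A fold, and degraded fast (τ ≈ 2.4 min) so
the "rapid decay" regime holds. Anaphase is licensed when the signal is
below threshold; while blocked, cells slip directly to G1 at a rate that
grows with arrest duration and with AK-A fold (unit base at fold 1, ×10
amplification per extra fold — the calibrated representation of
AK-A-induced leakiness). A slipping cell exits as *one* G1 cell: mitotic
slippage is exit without division. An optional aneuploidy penalty on
slipped lineages exists but defaults to off, as post-slippage fate is
not part of the present scope. The mean-field backend is cross-checked
against a seeded per-kinetochore Gillespie oracle (46 pairs per cell) to
within 5% on the time to attachment completion.

**Apoptosis.** Procaspase 9 → caspase 9 → caspase 3 with caspase-9
autocatalysis. The off state is strictly stable (autocatalytic gain at
the resting procaspase pool is below the caspase-9 decay rate), so zero
damage input never commits at any step size; sustained damage commits
within hours, and commitment is a latched flag — removing the signal
does not rescue the cohort. The one damage input wired by default is
mitotic arrest: cohorts blocked longer than the profile's
`arrest_tolerance_h` (default 24 h, the upper end of the commonly cited
8–24 h checkpoint-tolerance window) accumulate damage at 0.5 a.u. per
excess hour. The 24 h default is a calibration requirement as much as a
biological one: normal cells must survive a 24 h paclitaxel block and
resume cycling on washout. S-phase and non-cycle-specific drug lethality
deliberately bypass the cascade and act as direct kill rates — the
simplest faithful reading of "cycle-specific cytotoxicity"; a maintainer
wanting all death routed through the cascade can feed the drug effects
into `update_apoptosis()`'s damage input instead.

## Pharmacodynamics and built-in drugs

Every mechanism uses the Hill law. The reference parameter source for
the original four drugs is not publicly available, so the built-in
EC50/n/Emax values are calibration constants, fixed once so the default
configuration reproduces the documented comparative behaviours, and not
meant to be tuned per run:

| drug | mechanism | EC50 (nM) | n | Emax |
|---|---|---|---|---|
| palbociclib | cdk4/6 inhibition | 10 | 2 | 0.66 (fraction) |
| gemcitabine | S-phase kill | 30 | 2 | 0.40 /h |
| paclitaxel | mitotic arrest | 2.5 | 2 | 1.0 (fraction) |
| actinomycin D | non-cycle-specific kill, spares M | 40 | 1.5 | 0.07 /h |

Two of these deserve comment. Palbociclib's fractional Emax below 1 is a
structural necessity, not a potency statement: with complete achievable
cdk4 inhibition, saturating concentrations collapse the G1-S switch in
*both* lines and the malignant line loses its S-phase population over
48 h, contradicting the checkpoint-override phenotype the malignant
genotype is supposed to confer at every tested concentration. Partial
maximal inhibition keeps the high-cyclin-D (mutant RAS) state above the
switch threshold at any concentration while the low-cyclin-D normal
state collapses already at 30 nM. Actinomycin D's small maximal kill
rate reflects that its role in the study scenarios is a *background*
non-cycle-specific pressure against which mitotic shielding is measured.

Washout is instantaneous: drug effect drops to zero at a segment end,
with no intracellular persistence (no pharmacokinetics of any kind are
modelled — concentrations are specified directly as exposure profiles).

## Cell-line profiles and the doubling-time reconciliation

The malignant built-in (`miapaca2`) carries the tabulated cytokinetics
(Tc 19.5 h, loss factor 0.03, no quiescence or differentiation) and the
checkpoint genotype: mutant p53, mutant RAS, 3-fold aurora kinase A.
The normal built-in (`arpe19_like_normal`) has Tc 19.8 h, loss 0.05,
15% quiescent, 20% differentiating, all checkpoints intact. The
selectivity scenarios instead use `normalized_counterpart(miapaca2)` —
the hypothetical normal line with *identical* cytokinetic parameters and
functional checkpoints — because matched cytokinetics isolate the
checkpoint contribution to selectivity.

A tabulated tension must be resolved explicitly: a 19.5 h cycle with a
0.03 loss factor implies a ~20.4 h doubling time under any standard
growth formula, yet the measured mean doubling time is ~26 h.
`validate_profile()` surfaces this as a warning rather than silently
altering tabulated values, and the profile carries one calibration knob,
`s_phase_extension_h` (12.54 h for the malignant built-in), that slows
the line down to its measured doubling time. The extension is placed in
S phase, framed as oncogene-induced replication stress. Placement was a
genuinely open design choice and the alternatives fail on comparative
grounds: an extension appended to G2 (an "inter-division gap") creates a
large drug-insensitive sanctuary that *inverts* the gemcitabine
selectivity ordering under strong kill, and a basal G1 extension drops
the malignant steady-state S fraction below the normal one, with the
same inversion. Only the S-phase placement is simultaneously consistent
with the slow measured growth, the malignant line's larger S-phase
occupancy, and its gemcitabine hypersensitivity — and it is the one
placement with a mechanistic story, since RAS-driven replication stress
genuinely lengthens S phase. The counterpart constructor zeroes the
extension along with the genotype fields: the hypothetical normal line
is defined by its EGF-responsive growth (25 h ↔ 13 h), which a 12.5 h
replication handicap would break.

One consequence is worth stating plainly: the malignant line's
steady-state distribution is S-dominated (roughly 84% of cycling cells
in S at basal EGF, against ~29% for the counterpart). This is an extreme
value biologically, and it is the price of honouring both tabulated
numbers with a single dwell parameter.

Drug scenarios run at basal EGF (0) by default: the normal line's basal
doubling time (25 h) matches the measured ~26 h culture value, so basal
EGF is the standard-culture condition; at saturating EGF the counterpart
would outgrow the malignant line two-fold and the S-phase comparisons
would invert.

## Scenario read-outs

Three read-out conventions were open and are fixed as follows. The
palbociclib+gemcitabine delay scan measures viability percent-of-control
at a fixed horizon of 72 h after the palbociclib start (palbociclib
48 h, gemcitabine 24 h from its delayed start). The simultaneous
actinomycin D + paclitaxel surface uses a 24 h co-exposure read out at
48 h — one day after washout — because the mitotic shielding that
produces the antagonism only re-expresses as a countable difference
once the protected, arrested cells have resumed growth; at the 24 h
point itself the same protection is present but numerically about a
third smaller. The delayed variant runs paclitaxel 0–24 h (washout) with
actinomycin D at 30 nM from 12 h to 36 h, read at 36 h.

## Numerics

The population step is classical RK4 on the (linear, within a step)
compartment system, with coefficients frozen over each step and
refreshed from the signalling modules every step. The step size is the
minimum of the user cap (0.05 h) and `0.25 / max transition rate`, and
is aligned to schedule-segment boundaries so washouts are sharp; at the
fastest configured G1 rates this gives steps near 0.012 h. Negative
counts signal a step-size violation and abort the run rather than being
clamped (a tolerance of 1e-8 relative absorbs roundoff). Halving the
step changes a 96 h drug-free total by well under 0.5% (tested). The
SAC ensemble and the caspase cascade are sub-stepped explicitly inside
each population step; the G1-S relaxations use exact exponential
updates, so they are unconditionally stable. Ties in `delay_scan`'s
argmax resolve to the earliest delay (R's `which.max`), which is also
the clinically conservative choice.

Problem sizes used throughout the tests and the acceptance script —
96–120 h horizons for growth fits, a 25-point delay scan, 5×5
combination surfaces, 1 000–1 500 cells in the stochastic SAC oracle —
were chosen so each check runs in seconds to a couple of minutes on one
CPU while leaving the measured quantities' sampling error far below the
tolerances being asserted.

## What the built-in scenarios do and do not show

All quantitative behaviour of this package is the behaviour of *the
model*: growth curves, arrest kinetics, selectivity ratios and
antagonism scores are simulation outputs under calibrated constants, not
measurements. The synthetic populations emulate exponential-phase,
well-mixed, checkpoint-differentiated cell cultures with piecewise-
constant drug exposure. They do not emulate: cell-to-cell parameter
variability (every cohort is kinetically identical), pharmacokinetics,
DNA-damage signalling (the p53 branch is inert), the G2-M checkpoint,
resistance evolution, or spatial structure. A passing suite therefore
shows that the implementation honours its model contract and its
calibrated reference behaviours — not that the model predicts any
particular laboratory result.

## Known limitations

- The G1-S switch's collapse threshold is sharp; behaviour very close to
  the switch boundary (e.g. palbociclib Emax above ~0.7) changes
  qualitatively, which is physiological for a bistable checkpoint but
  means potency extrapolation beyond the calibrated range is unsafe.
- The shared-signalling approximation cannot represent drug schedules
  fast enough that cohorts at different cycle positions would see
  materially different intracellular states.
- The SAC dilution ensemble summarises the mitotic cohort by one average
  attachment state; strongly bimodal mitotic populations (a fresh wave
  entering during a deep arrest) are represented only approximately.
- Cytotoxicity can be negative (net growth) by definition; it is a
  count-reduction measure, not a death count.
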