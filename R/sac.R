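#' Kinetochore ensemble state
#'
#' Mean-field description of the spindle assembly checkpoint for a cohort of
#' mitotic cells: the fractions of sister-chromatid pairs that are
#' unattached, monotelically attached (one kinetochore to one pole),
#' syntelically attached (both sisters to the same pole, no tension) or
#' amphitelically attached (sisters to opposite poles, under tension), plus
#' the diffusible "wait" signal that blocks the metaphase-anaphase
#' transition.  All kinetochores start unattached and emitting the wait
#' signal; microtubules attach at random, aurora kinase B removes tensionless
#' (syntelic) attachments, and once essentially all pairs are amphitelic the
#' wait signal decays rapidly and anaphase is licensed.
#'
#' @param n_pairs Number of sister-chromatid pairs (46 for human cells).
#' @param frac_unattached,frac_monotelic,frac_syntelic,frac_amphitelic Initial
#'   attachment fractions; must sum to 1.
#' @param wait_signal Initial wait-signal level (a.u.).
#' @return Object of class `kinetochore_ensemble`.
#' @export
kinetochore_ensemble <- function(n_pairs = .cyclosim_defaults$n_kinetochore_pairs,
                                 frac_unattached = 1, frac_monotelic = 0,
                                 frac_syntelic = 0, frac_amphitelic = 0,
                                 wait_signal = 2) {
  f <- c(frac_unattached, frac_monotelic, frac_syntelic, frac_amphitelic)
  if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-9) {
    stop("attachment fractions must be non-negative and sum to 1",
         call. = FALSE)
  }
  stopifnot(wait_signal >= 0, n_pairs >= 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 frac_unattached = frac_unattached,
                 frac_monotelic = frac_monotelic,
                 frac_syntelic = frac_syntelic,
                 frac_amphitelic = frac_amphitelic,
                 wait_signal = wait_signal),
            class = "kinetochore_ensemble")
}

#' Drug effects acting on the spindle assembly checkpoint
#'
#' @param microtubule_stabilization Fraction in \[0,1\]; paclitaxel-class
#'   stabilisation that slows attachment turnover and error correction.
#' @param aka_inhibition Fractional aurora kinase A inhibition (adds delay to
#'   early mitosis; config-only hook).
#' @param akb_inhibition Fractional aurora kinase B inhibition (slows removal
#'   of syntelic attachments).
#' @return Object of class `sac_drug_effects`.
#' @export
sac_drug_effects <- function(microtubule_stabilization = 0,
                             aka_inhibition = 0, akb_inhibition = 0) {
  v <- c(microtubule_stabilization, aka_inhibition, akb_inhibition)
  stopifnot(all(v >= 0), all(v <= 1))
  structure(list(microtubule_stabilization = microtubule_stabilization,
                 aka_inhibition = aka_inhibition,
                 akb_inhibition = akb_inhibition),
            class = "sac_drug_effects")
}

# Microtubule stabilisation (paclitaxel class) suppresses spindle dynamics:
# attachment turnover slows, the second attachment is increasingly captured
# by the near pole (syntelic, tensionless), and aurora-kinase-B error
# correction — which requires depolymerisation of the faulty fibre — slows
# in proportion.  Together these make the expected time to full amphitelic
# attachment diverge as stabilisation approaches 1, which is what sustains
# a mitotic arrest over many hours.
sac_rates <- function(drugs) {
  d <- .cyclosim_defaults
  slow <- 1 - drugs$microtubule_stabilization
  list(attach = d$sac_attach_rate * slow,
       second = d$sac_second_rate * slow,
       syn_frac = d$sac_syntelic_frac +
         (1 - d$sac_syntelic_frac) * drugs$microtubule_stabilization,
       correct = d$sac_correction_rate * slow * (1 - drugs$akb_inhibition))
}

#' Advance kinetochore attachment dynamics
#'
#' Mean-field kinetics: unattached pairs gain a first attachment (monotelic);
#' the second attachment lands amphitelically or syntelically (random pole
#' geometry, 50/50 by default); syntelic attachments are removed back to
#' monotelic by aurora kinase B (inactive on tensed amphitelic pairs, so
#' amphitelic is absorbing).  Microtubule stabilisation slows attachment and
#' correction alike; aurora kinase B inhibition slows only correction.
#' An optional `reset_rate` mixes in freshly entering (all-unattached) cells,
#' which is how the population engine represents continuous mitotic influx.
#'
#' @param ens A [kinetochore_ensemble()].
#' @param drugs A [sac_drug_effects()].
#' @param dt Step in hours (> 0); internally sub-stepped for stability.
#' @param reset_rate Per-hour dilution by newly entering unattached cells.
#' @return Updated ensemble.
#' @export
update_attachments <- function(ens, drugs = sac_drug_effects(), dt,
                               reset_rate = 0) {
  stopifnot(dt > 0, reset_rate >= 0)
  r <- sac_rates(drugs)
  maxrate <- max(r$attach, r$second, r$correct, reset_rate, 1e-12)
  nsub <- max(1L, ceiling(maxrate * dt / 0.1))
  h <- dt / nsub
  f <- c(ens$frac_unattached, ens$frac_monotelic, ens$frac_syntelic,
         ens$frac_amphitelic)
  for (i in seq_len(nsub)) {
    df <- c(-r$attach * f[1],
            r$attach * f[1] - r$second * f[2] + r$correct * f[3],
            r$second * r$syn_frac * f[2] - r$correct * f[3],
            r$second * (1 - r$syn_frac) * f[2])
    df <- df + reset_rate * (c(1, 0, 0, 0) - f)
    f <- f + h * df
  }
  if (any(f < -1e-9) || abs(sum(f) - 1) > 1e-6) {
    stop("attachment fractions left the simplex; step size too large",
         call. = FALSE)
  }
  f <- pmax(f, 0); f <- f / sum(f)
  ens$frac_unattached <- f[1]; ens$frac_monotelic <- f[2]
  ens$frac_syntelic <- f[3]; ens$frac_amphitelic <- f[4]
  ens
}

#' Advance the wait signal
#'
#' The wait signal is produced while any pairs lack tension, through a steep
#' (bistable-like) switch in the non-amphitelic fraction, and is degraded
#' first order, so it collapses rapidly once attachment is essentially
#' complete.  Aurora kinase A over-expression divides the production term
#' (unit effect at fold 1), the modelled mechanism of checkpoint weakening.
#'
#' @param ens A [kinetochore_ensemble()].
#' @param aka_fold Aurora kinase A fold-change (>= 1 typical).
#' @param dt Step in hours (> 0).
#' @return Updated ensemble.
#' @export
update_wait_signal <- function(ens, aka_fold = 1, dt) {
  stopifnot(dt > 0, aka_fold > 0)
  d <- .cyclosim_defaults
  u <- 1 - ens$frac_amphitelic
  s <- u^d$sac_wait_hill / (u^d$sac_wait_hill + d$sac_wait_km^d$sac_wait_hill)
  prod <- d$sac_wait_prod * s / aka_fold
  ens$wait_signal <- .relax(ens$wait_signal, prod, d$sac_wait_decay, dt)
  ens
}

#' Metaphase exit signal
#'
#' Anaphase is allowed when the wait signal is below threshold.  While
#' blocked, a slippage rate lets cells leak out of the arrest directly into
#' G1 without completing division; the rate grows with aurora kinase A
#' over-expression and with time under arrest.
#'
#' @param ens A [kinetochore_ensemble()].
#' @param threshold Wait-signal threshold (> 0).
#' @param aka_fold Aurora kinase A fold-change.
#' @param arrest_clock Hours of continuous arrest so far.
#' @return List with `anaphase_allowed` (logical) and `slippage_rate`
#'   (per hour; 0 when anaphase is allowed).
#' @export
m_exit_signal <- function(ens, threshold = .cyclosim_defaults$sac_threshold,
                          aka_fold = 1, arrest_clock = 0) {
  stopifnot(threshold > 0)
  d <- .cyclosim_defaults
  allowed <- ens$wait_signal < threshold
  slip <- if (allowed) 0 else {
    ramp <- min(arrest_clock / d$sac_slip_ramp_h, d$sac_slip_ramp_cap)
    d$sac_slip_base * (1 + d$sac_slip_aka * (aka_fold - 1)) * ramp
  }
  list(anaphase_allowed = allowed, slippage_rate = slip)
}

#' Stochastic per-kinetochore oracle for attachment completion
#'
#' Simulates `n_cells` independent cells, each with `n_pairs` kinetochore
#' pairs undergoing the per-pair Markov attachment process at the same rates
#' as the mean-field model (unattached -> monotelic -> amphitelic/syntelic,
#' syntelic corrected back to monotelic), by exact Gillespie simulation per
#' pair.  Returns the population trajectory of the amphitelic fraction and
#' the per-cell times to full (all pairs amphitelic) attachment.  Used as an
#' independent cross-check of the mean-field backend in the test suite.
#'
#' @param n_cells Number of cells.
#' @param n_pairs Kinetochore pairs per cell.
#' @param drugs A [sac_drug_effects()].
#' @param t_max Simulation horizon in hours.
#' @param seed Optional integer seed.
#' @return List with `time_to_all_amphitelic` (numeric, per cell, `NA` if not
#'   reached by `t_max`) and a function `frac_amphitelic(t)` giving the
#'   population amphitelic fraction at time `t`.
#' @export
sac_stochastic_oracle <- function(n_cells = 1000,
                                  n_pairs = .cyclosim_defaults$n_kinetochore_pairs,
                                  drugs = sac_drug_effects(), t_max = 2,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  r <- sac_rates(drugs)
  npair_tot <- n_cells * n_pairs
  # per-pair Markov chain; simulate all pairs' jump processes vectorised:
  # states 1=unattached 2=monotelic 3=syntelic 4=amphitelic (absorbing)
  amph_time <- numeric(npair_tot)  # time each pair first becomes amphitelic
  state <- rep.int(1L, npair_tot)
  tnow <- numeric(npair_tot)
  active <- which(state != 4L)
  while (length(active) > 0) {
    s <- state[active]
    rate <- c(r$attach, r$second, r$correct)[s]
    tnow[active] <- tnow[active] + stats::rexp(length(active), rate)
    mono <- active[s == 2L]
    if (length(mono) > 0) {
      to_syn <- stats::runif(length(mono)) < r$syn_frac
      state[mono] <- ifelse(to_syn, 3L, 4L)
    }
    state[active[s == 1L]] <- 2L
    state[active[s == 3L]] <- 2L
    done <- active[state[active] == 4L]
    amph_time[done] <- tnow[done]
    over <- active[tnow[active] > t_max]
    amph_time[over] <- NA_real_
    state[over] <- 4L  # retire (censored)
    active <- which(state != 4L)
  }
  per_cell <- matrix(amph_time, nrow = n_pairs)
  t_all <- apply(per_cell, 2, function(x) if (anyNA(x)) NA_real_ else max(x))
  frac_fun <- function(t) {
    vapply(t, function(tt) mean(!is.na(amph_time) & amph_time <= tt),
           numeric(1))
  }
  list(time_to_all_amphitelic = t_all, frac_amphitelic = frac_fun)
}
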