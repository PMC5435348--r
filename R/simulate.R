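#' Simulate a cell population under a drug exposure schedule
#'
#' The main driver: advances an asynchronous population of cohorts through
#' the 63-compartment cycle structure while co-integrating the shared
#' signalling modules — EGF/MAPK (quasi-steady), the G1-S checkpoint ODEs
#' (setting the G1 dwell and the G1->S permissiveness), the spindle-assembly
#' checkpoint ensemble (gating metaphase exit, with slippage), and the
#' apoptosis cascade driven by prolonged mitotic arrest.  Drug exposure is
#' piecewise constant; Hill-mapped drug effects are re-evaluated at each
#' schedule segment boundary and signalling relaxes continuously across
#' them.
#'
#' The population step is classical RK4 with an adaptive step bounded by
#' `dt` and by the fastest transition rate; the spindle-checkpoint ensemble
#' is sub-stepped internally.  Integration points are aligned to segment
#' boundaries so washouts are sharp.
#'
#' @param profile A [cell_line_profile()].
#' @param drugs Named list of [drug_model()] objects.
#' @param schedule An [exposure_schedule()].
#' @param egf_conc EGF concentration (constant; a.u., saturating = 100).
#' @param horizon Simulation end time (hours).
#' @param n0 Initial cell count.
#' @param init_mode `"asynchronous-steady"` (default) or `"synchronous-G1"`.
#' @param dt Maximum integrator step in hours.
#' @param record_every Output sampling interval in hours.
#' @return Object of class `simulation_result`: list with `timeseries` (wide
#'   data frame: `time_h`, the 63 compartment columns, `cumulative_dead`,
#'   `births`, `cumulative_slipped`, `total_live`), `phases` (long data frame `time_h`, `phase`,
#'   `fraction`), `final_state`, and the run configuration.
#' @export
simulate_population <- function(profile,
                                drugs = list(),
                                schedule = exposure_schedule(),
                                egf_conc = 0,
                                horizon = 96,
                                n0 = 1000,
                                init_mode = c("asynchronous-steady",
                                              "synchronous-G1"),
                                dt = .cyclosim_defaults$dt_max,
                                record_every = 0.5) {
  init_mode <- match.arg(init_mode)
  errs <- profile_violations(profile)
  if (length(errs) > 0) stop("invalid profile: ",
                             paste(errs, collapse = "; "), call. = FALSE)
  stopifnot(horizon > 0, dt > 0, record_every > 0)
  if (length(drugs) > 0 && is.null(names(drugs))) {
    names(drugs) <- vapply(drugs, `[[`, character(1), "name")
  }
  d <- .cyclosim_defaults

  state <- initialize_population(profile, n0, init_mode, egf_conc)
  sig <- g1s_steady(profile, egf_conc = egf_conc)
  g1s <- sig$g1s
  ens <- kinetochore_ensemble(frac_unattached = 0.02, frac_monotelic = 0.02,
                              frac_syntelic = 0.01, frac_amphitelic = 0.95,
                              wait_signal = 0)
  apop <- apoptosis_state()
  arrest_clock <- 0

  breaks <- schedule_breaks(schedule)
  events <- sort(unique(c(0, breaks[breaks > 0 & breaks < horizon], horizon)))
  rec_times <- seq(0, horizon, by = record_every)
  if (rec_times[length(rec_times)] < horizon) {
    rec_times <- c(rec_times, horizon)
  }

  nrec <- length(rec_times)
  rec_counts <- matrix(NA_real_, nrow = nrec, ncol = 63,
                       dimnames = list(NULL, compartment_labels()))
  rec_dead <- rec_births <- rec_slip <- rec_time <- numeric(nrec)
  irec <- 1L
  record <- function(st) {
    rec_counts[irec, ] <<- st$counts
    rec_dead[irec] <<- st$cumulative_dead
    rec_births[irec] <<- st$births
    rec_slip[irec] <<- st$slipped
    rec_time[irec] <<- st$time
    irec <<- irec + 1L
  }
  record(state)
  next_rec <- 2L

  t <- 0
  for (iseg in seq_len(length(events) - 1)) {
    seg_end <- events[iseg + 1]
    pd <- exposure_to_context(schedule, events[iseg], drugs)
    mapk <- update_mapk(mapk_state(), egf_conc = egf_conc,
                        ras_status = profile$ras_status,
                        inhibitions = pd$mapk_inhibitions)
    cd_prod <- cyclin_d_production(mapk,
                                   profile$cyclin_d_overexpression_fold)
    while (t < seg_end - 1e-12) {
      # step size from the currently fastest process
      ctx_probe <- transition_context(
        profile, g1_duration_h = g1_duration(g1s),
        g1s_permissiveness = g1s_permissiveness(g1s),
        s_phase_kill_rate = pd$s_phase_kill_rate,
        global_kill_rate = pd$global_kill_rate)
      maxrate <- max(stage_rates(ctx_probe), pd$global_kill_rate +
                       pd$s_phase_kill_rate, 1e-6)
      h <- min(dt, d$rate_dt_cap / maxrate, seg_end - t)
      if (next_rec <= nrec) h <- min(h, max(rec_times[next_rec] - t, 1e-9))

      g1s <- update_g1s(g1s, cd_prod, pd$palbociclib_inhibition,
                        p21_p27_input = 0, dt = h,
                        rb_status = profile$rb_status,
                        p53_status = profile$p53_status)
      m_in <- 5 / ctx_probe$m_duration_h * state$counts[[.idx$prophase]]
      m_mass <- state$counts[[.idx$prometaphase]] +
        state$counts[[.idx$metaphase]]
      reset <- if (m_mass > 1e-12 * max(total_live(state), 1)) {
        min(m_in / m_mass, 50)
      } else 10
      ens <- update_attachments(ens, pd$sac, h, reset_rate = reset)
      ens <- update_wait_signal(ens, aka_fold = profile$aka_fold, dt = h)
      mex <- m_exit_signal(ens, threshold = d$sac_threshold,
                           aka_fold = profile$aka_fold,
                           arrest_clock = arrest_clock)
      arrest_clock <- if (mex$anaphase_allowed) 0 else arrest_clock + h
      dmg <- arrest_damage_signal(arrest_clock, profile$arrest_tolerance_h)
      apop <- update_apoptosis(apop, dmg, h)
      apop_kill <- if (apop$committed) d$apoptosis_death_rate else 0

      ctx <- transition_context(
        profile, g1_duration_h = g1_duration(g1s),
        g1s_permissiveness = g1s_permissiveness(g1s),
        s_phase_kill_rate = pd$s_phase_kill_rate,
        global_kill_rate = pd$global_kill_rate,
        m_exit = mex, apoptosis_kill_rate = apop_kill)
      state <- advance(state, ctx, h)
      t <- state$time
      while (next_rec <= nrec && t >= rec_times[next_rec] - 1e-9) {
        record(state)
        next_rec <- next_rec + 1L
      }
    }
  }

  ts <- data.frame(time_h = rec_time[seq_len(irec - 1)],
                   rec_counts[seq_len(irec - 1), , drop = FALSE],
                   cumulative_dead = rec_dead[seq_len(irec - 1)],
                   births = rec_births[seq_len(irec - 1)],
                   cumulative_slipped = rec_slip[seq_len(irec - 1)],
                   check.names = FALSE)
  ts$total_live <- rowSums(rec_counts[seq_len(irec - 1), , drop = FALSE])
  phase_of <- c(rep("G1", 15), rep("S", 30), rep("G2", 10), rep("M", 5),
                "G0", "differentiated", "damaged")
  phs <- do.call(rbind, lapply(seq_len(nrow(ts)), function(i) {
    tot <- ts$total_live[i]
    fr <- tapply(as.numeric(rec_counts[i, ]), phase_of, sum)[
      c("G1", "S", "G2", "M", "G0", "differentiated", "damaged")]
    data.frame(time_h = ts$time_h[i], phase = names(fr),
               fraction = as.numeric(fr) / tot, row.names = NULL)
  }))
  structure(list(timeseries = ts, phases = phs, final_state = state,
                 profile = profile, drugs = drugs, schedule = schedule,
                 egf_conc = egf_conc, horizon = horizon, dt = dt,
                 n0 = n0, init_mode = init_mode),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  ts <- x$timeseries
  cat(sprintf("<simulation_result> %s, %d drugs, %.4g -> %.4g live cells over %.3g h\n",
              x$profile$name, length(x$drugs), ts$total_live[1],
              ts$total_live[nrow(ts)], x$horizon))
  invisible(x)
}
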