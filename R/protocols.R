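#' Standard study profile pair
#'
#' The malignant line is the built-in MiaPaca-2 parameterization; the normal
#' control is its checkpoint-proficient counterpart (identical cytokinetic
#' parameters, functional checkpoints), the construction used throughout the
#' selectivity scenarios.
#'
#' @return List with elements `malignant` and `normal`.
#' @export
study_profile_pair <- function() {
  mal <- builtin_profile("miapaca2")
  list(malignant = mal, normal = normalized_counterpart(mal))
}

scenario_names <- c("egf_titration", "palbociclib_monotherapy",
                    "gemcitabine_monotherapy", "palbo_gem_surface",
                    "palbo_gem_delay_scan", "paclitaxel_arrest",
                    "actd_monotherapy", "actd_paclitaxel_surface",
                    "actd_paclitaxel_delayed")

#' Run a named study scenario
#'
#' Reproduces the package's reference experiments end-to-end and returns the
#' underlying tables plus headline metrics.  Scenarios:
#' \describe{
#'   \item{egf_titration}{drug-free growth of both profiles across an EGF
#'     range (96 h); doubling times per concentration.}
#'   \item{palbociclib_monotherapy}{48 h at 30/100/300 nM; growth curves,
#'     added-death fractions and S-phase depletion for both profiles.}
#'   \item{gemcitabine_monotherapy}{24 h across a concentration grid;
#'     cytotoxicity for both profiles.}
#'   \item{palbo_gem_surface}{palbociclib (48 h) + gemcitabine (24 h,
#'     simultaneous start) dose-response surface, viability at 72 h.}
#'   \item{palbo_gem_delay_scan}{both drugs 30 nM; gemcitabine delayed
#'     0-24 h after palbociclib; viability %-of-control at 72 h and the
#'     normal:malignant selectivity ratio.}
#'   \item{paclitaxel_arrest}{10 nM for 24 h with washout; phase
#'     distributions at 12/24/27 h for both profiles.}
#'   \item{actd_monotherapy}{24 h actinomycin D grid; cytotoxicity.}
#'   \item{actd_paclitaxel_surface}{24 h simultaneous combination exposure
#'     read out at 48 h (one day after washout, when the protection of
#'     mitotically shielded cells has re-expressed as regrowth), with Bliss
#'     scores for both profiles.}
#'   \item{actd_paclitaxel_delayed}{paclitaxel 0-24 h (with washout),
#'     actinomycin D added 12 h after the paclitaxel start (12-36 h);
#'     viability %-of-control at 36 h.}
#' }
#'
#' @param name Scenario name (see above).
#' @param overrides Named list overriding scenario defaults (e.g.
#'   `list(concentrations = c(10, 30))`); unknown keys are an error.
#' @return A list (class `scenario_result`) of tables and a `metrics` list of
#'   headline numbers.
#' @export
run_scenario <- function(name = scenario_names, overrides = list()) {
  name <- match.arg(name)
  pair <- study_profile_pair()
  defaults <- switch(name,
    egf_titration = list(egf = c(0, 0.5, 1, 2, 5, 100), horizon = 96,
                         fit_window = c(24, 96)),
    palbociclib_monotherapy = list(concentrations = c(30, 100, 300),
                                   duration = 48, horizon = 48),
    gemcitabine_monotherapy = list(concentrations = c(3, 10, 30, 100, 300),
                                   duration = 24, horizon = 24),
    palbo_gem_surface = list(palbo_grid = c(0, 30, 100, 300),
                             gem_grid = c(0, 3, 10, 30, 100),
                             palbo_duration = 48, gem_duration = 24,
                             horizon = 72),
    palbo_gem_delay_scan = list(conc = 30, delays = 0:24,
                                palbo_duration = 48, gem_duration = 24,
                                horizon = 72),
    paclitaxel_arrest = list(conc = 10, duration = 24, horizon = 27,
                             snapshot_times = c(12, 24, 27)),
    actd_monotherapy = list(concentrations = c(3, 10, 30, 100),
                            duration = 24, horizon = 24),
    actd_paclitaxel_surface = list(actd_grid = c(0, 3, 10, 30, 100),
                                   pac_grid = c(0, 1, 3, 10, 30),
                                   duration = 24, horizon = 48),
    actd_paclitaxel_delayed = list(pac_conc = 10, actd_conc = 30,
                                   delay = 12, pac_duration = 24,
                                   actd_duration = 24, horizon = 36)
  )
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown override keys for scenario '", name, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  p <- utils::modifyList(defaults, overrides)
  out <- switch(name,
    egf_titration = scenario_egf(pair, p),
    palbociclib_monotherapy = scenario_palbo(pair, p),
    gemcitabine_monotherapy = scenario_mono_kill(pair, p, "gemcitabine"),
    palbo_gem_surface = scenario_palbo_gem_surface(pair, p),
    palbo_gem_delay_scan = scenario_palbo_gem_delay(pair, p),
    paclitaxel_arrest = scenario_paclitaxel(pair, p),
    actd_monotherapy = scenario_mono_kill(pair, p, "actinomycin_d"),
    actd_paclitaxel_surface = scenario_actd_pac_surface(pair, p),
    actd_paclitaxel_delayed = scenario_actd_pac_delayed(pair, p)
  )
  structure(c(out, list(scenario = name, params = p)),
            class = "scenario_result")
}

scenario_egf <- function(pair, p) {
  runs <- expand.grid(profile = c("normal", "malignant"), egf = p$egf,
                      stringsAsFactors = FALSE)
  curves <- list(); td <- numeric(nrow(runs))
  for (i in seq_len(nrow(runs))) {
    res <- simulate_population(pair[[runs$profile[i]]],
                               egf_conc = runs$egf[i],
                               horizon = p$horizon, record_every = 1)
    ts <- res$timeseries[, c("time_h", "total_live")]
    ts$profile <- runs$profile[i]; ts$egf <- runs$egf[i]
    curves[[i]] <- ts
    td[i] <- doubling_time(res, p$fit_window)
  }
  runs$doubling_time_h <- td
  mal <- runs$doubling_time_h[runs$profile == "malignant"]
  list(growth_curves = do.call(rbind, curves),
       doubling_times = runs,
       metrics = list(
         normal_td_basal_h = runs$doubling_time_h[
           runs$profile == "normal" & runs$egf == min(p$egf)],
         normal_td_saturating_h = runs$doubling_time_h[
           runs$profile == "normal" & runs$egf == max(p$egf)],
         malignant_td_range_rel = diff(range(mal)) / mean(mal)))
}

scenario_palbo <- function(pair, p) {
  palbo <- builtin_drug("palbociclib")
  rows <- list(); curves <- list()
  for (nm in c("normal", "malignant")) {
    ctrl <- simulate_population(pair[[nm]], horizon = p$horizon,
                                record_every = 1)
    ctrl_ts <- ctrl$timeseries
    ctrl_dead_frac <- (ctrl_ts$cumulative_dead[nrow(ctrl_ts)] -
                         ctrl_ts$cumulative_dead[1]) / ctrl_ts$total_live[1]
    s0 <- phase_distribution(ctrl$final_state)[["S"]]
    for (conc in p$concentrations) {
      res <- simulate_population(
        pair[[nm]], list(palbociclib = palbo),
        single_exposure("palbociclib", conc, 0, p$duration),
        horizon = p$horizon, record_every = 1)
      ts <- res$timeseries
      dead_frac <- (ts$cumulative_dead[nrow(ts)] - ts$cumulative_dead[1]) /
        ts$total_live[1]
      rows[[length(rows) + 1]] <- data.frame(
        profile = nm, concentration = conc,
        viability_pct = viability_percent_of_control(
          ts$total_live[nrow(ts)], ctrl_ts$total_live[nrow(ctrl_ts)]),
        added_death_pct = 100 * (dead_frac - ctrl_dead_frac),
        s_fraction = phase_distribution(res$final_state)[["S"]],
        s_fraction_control = s0)
      cv <- ts[, c("time_h", "total_live")]
      cv$profile <- nm; cv$concentration <- conc
      curves[[length(curves) + 1]] <- cv
    }
  }
  tab <- do.call(rbind, rows)
  dep <- tab$s_fraction_control - tab$s_fraction
  list(growth_curves = do.call(rbind, curves), response = tab,
       metrics = list(
         max_added_death_pct = max(tab$added_death_pct),
         s_depletion_normal = dep[tab$profile == "normal"],
         s_depletion_malignant = dep[tab$profile == "malignant"]))
}

scenario_mono_kill <- function(pair, p, drug_name) {
  dr <- builtin_drug(drug_name)
  rows <- list()
  for (nm in c("normal", "malignant")) {
    start <- simulate_population(pair[[nm]], horizon = 1e-6,
                                 record_every = 1)  # t = 0 count
    n0 <- start$timeseries$total_live[1]
    for (conc in p$concentrations) {
      res <- simulate_population(
        pair[[nm]], stats::setNames(list(dr), dr$name),
        single_exposure(dr$name, conc, 0, p$duration),
        horizon = p$horizon, record_every = 1)
      ts <- res$timeseries
      rows[[length(rows) + 1]] <- data.frame(
        profile = nm, concentration = conc,
        cytotox_pct = cytotoxicity(n0, ts$total_live[nrow(ts)]))
    }
  }
  tab <- do.call(rbind, rows)
  cyto <- function(nm) tab$cytotox_pct[tab$profile == nm]
  list(response = tab,
       metrics = list(cytotox_normal = cyto("normal"),
                      cytotox_malignant = cyto("malignant"),
                      max_abs_difference = max(abs(cyto("malignant") -
                                                     cyto("normal")))))
}

scenario_palbo_gem_surface <- function(pair, p) {
  palbo <- builtin_drug("palbociclib"); gem <- builtin_drug("gemcitabine")
  tmpl <- function(concA, concB) {
    seg <- data.frame(drug = character(0), concentration = numeric(0),
                      t_start = numeric(0), t_end = numeric(0))
    if (concA > 0) seg <- rbind(seg, data.frame(
      drug = "palbociclib", concentration = concA, t_start = 0,
      t_end = p$palbo_duration))
    if (concB > 0) seg <- rbind(seg, data.frame(
      drug = "gemcitabine", concentration = concB, t_start = 0,
      t_end = p$gem_duration))
    exposure_schedule(seg)
  }
  surfaces <- lapply(pair[c("normal", "malignant")], function(pr)
    combination_surface(pr, palbo, gem, p$palbo_grid, p$gem_grid,
                        schedule_template = tmpl, horizon = p$horizon))
  list(surface_normal = surfaces$normal,
       surface_malignant = surfaces$malignant,
       metrics = list(
         min_bliss_normal = min(surfaces$normal$bliss_score_pct),
         min_bliss_malignant = min(surfaces$malignant$bliss_score_pct)))
}

scenario_palbo_gem_delay <- function(pair, p) {
  sc <- delay_scan(pair, builtin_drug("palbociclib"),
                   builtin_drug("gemcitabine"),
                   concA = p$conc, concB = p$conc, delays = p$delays,
                   durationA = p$palbo_duration,
                   durationB = p$gem_duration, horizon = p$horizon)
  best <- attr(sc, "best_delay_h")
  list(scan = sc,
       metrics = list(best_delay_h = best,
                      best_ratio = sc$selectivity_ratio[
                        sc$delay_h == best]))
}

scenario_paclitaxel <- function(pair, p) {
  pac <- builtin_drug("paclitaxel")
  phases <- list(); metrics <- list()
  for (nm in c("normal", "malignant")) {
    base <- simulate_population(pair[[nm]], horizon = 1e-6,
                                record_every = 1)
    ref <- phase_distribution(base$final_state)
    res <- simulate_population(
      pair[[nm]], list(paclitaxel = pac),
      single_exposure("paclitaxel", p$conc, 0, p$duration),
      horizon = p$horizon, record_every = 0.5)
    snap <- res$phases[res$phases$time_h %in% p$snapshot_times, ]
    snap$profile <- nm
    ref_df <- data.frame(time_h = NA_real_, phase = names(ref),
                         fraction = as.numeric(ref), profile = nm)
    phases[[nm]] <- snap
    phases[[paste0(nm, "_ref")]] <- ref_df
    g1 <- function(t) sum(snap$fraction[snap$time_h == t &
                                          snap$phase == "G1"])
    m <- function(t) sum(snap$fraction[snap$time_h == t &
                                         snap$phase == "M"])
    metrics[[paste0("m_fraction_12h_", nm)]] <- m(12)
    metrics[[paste0("m_fraction_24h_", nm)]] <- m(24)
    metrics[[paste0("g1_fraction_24h_", nm)]] <- g1(24)
    metrics[[paste0("g1_fraction_27h_", nm)]] <- g1(27)
    metrics[[paste0("m_fraction_ref_", nm)]] <- ref[["M"]]
    metrics[[paste0("g1_fraction_ref_", nm)]] <- ref[["G1"]]
  }
  list(phase_snapshots = do.call(rbind, phases), metrics = metrics)
}

scenario_actd_pac_surface <- function(pair, p) {
  actd <- builtin_drug("actinomycin_d"); pac <- builtin_drug("paclitaxel")
  surfaces <- lapply(pair[c("normal", "malignant")], function(pr)
    combination_surface(pr, actd, pac, p$actd_grid, p$pac_grid,
                        horizon = p$horizon))
  list(surface_normal = surfaces$normal,
       surface_malignant = surfaces$malignant,
       metrics = list(
         bliss_highest_normal = surface_score_at(surfaces$normal),
         bliss_highest_malignant = surface_score_at(surfaces$malignant)))
}

scenario_actd_pac_delayed <- function(pair, p) {
  actd <- builtin_drug("actinomycin_d"); pac <- builtin_drug("paclitaxel")
  drugs <- list(actinomycin_d = actd, paclitaxel = pac)
  sch <- exposure_schedule(data.frame(
    drug = c("paclitaxel", "actinomycin_d"),
    concentration = c(p$pac_conc, p$actd_conc),
    t_start = c(0, p$delay),
    t_end = c(p$pac_duration, p$delay + p$actd_duration)))
  viab <- vapply(c(normal = "normal", malignant = "malignant"),
                 function(nm) {
    ctrl <- simulate_population(pair[[nm]], horizon = p$horizon,
                                record_every = 1)
    trt <- simulate_population(pair[[nm]], drugs, sch, horizon = p$horizon,
                               record_every = 1)
    viability_percent_of_control(
      trt$timeseries$total_live[nrow(trt$timeseries)],
      ctrl$timeseries$total_live[nrow(ctrl$timeseries)])
  }, numeric(1))
  list(metrics = list(viability_normal_pct = viab[["normal"]],
                      viability_malignant_pct = viab[["malignant"]]))
}
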