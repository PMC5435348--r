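#' Dose-response surface for a two-drug combination
#'
#' Runs the full population simulation at every point of the concentration
#' grid (monotherapy rows/columns are obtained by including concentration 0
#' in the grids), computes the effect `100 - viability%` against the shared
#' untreated control at the horizon, and scores each point as the observed
#' combined effect minus the Bliss-independence expectation from the
#' monotherapies (percentage points; negative = antagonism).
#'
#' @param profile A [cell_line_profile()].
#' @param drugA,drugB [drug_model()] objects.
#' @param conc_gridA,conc_gridB Concentration grids (should include 0 so the
#'   monotherapy effects needed for the Bliss expectation are available).
#' @param schedule_template Function `(concA, concB)` returning an
#'   [exposure_schedule()]; defaults to simultaneous 0-24 h exposure of both
#'   drugs.
#' @param horizon Time (hours) at which viability is read; defaults to the
#'   latest segment end across the grid.
#' @param egf_conc,n0,record_every Passed to [simulate_population()].
#' @return Object of class `dose_response_surface`: data frame with columns
#'   `concA`, `concB`, `profile`, `viability_pct`, `effect_pct`,
#'   `bliss_score_pct`, with the drugs and horizon as attributes.
#' @export
combination_surface <- function(profile, drugA, drugB,
                                conc_gridA, conc_gridB,
                                schedule_template = NULL,
                                horizon = NULL,
                                egf_conc = 0, n0 = 1000,
                                record_every = 1) {
  stopifnot(length(conc_gridA) > 0, length(conc_gridB) > 0)
  if (is.null(schedule_template)) {
    schedule_template <- function(concA, concB) {
      seg <- data.frame(drug = character(0), concentration = numeric(0),
                        t_start = numeric(0), t_end = numeric(0))
      if (concA > 0) seg <- rbind(seg, data.frame(drug = drugA$name,
                                                  concentration = concA,
                                                  t_start = 0, t_end = 24))
      if (concB > 0) seg <- rbind(seg, data.frame(drug = drugB$name,
                                                  concentration = concB,
                                                  t_start = 0, t_end = 24))
      exposure_schedule(seg)
    }
  }
  grid <- expand.grid(concA = sort(unique(conc_gridA)),
                      concB = sort(unique(conc_gridB)))
  if (is.null(horizon)) {
    horizon <- max(vapply(seq_len(nrow(grid)), function(i) {
      seg <- schedule_template(grid$concA[i], grid$concB[i])$segments
      if (nrow(seg) == 0) 24 else max(seg$t_end)
    }, numeric(1)))
  }
  drugs <- stats::setNames(list(drugA, drugB), c(drugA$name, drugB$name))
  end_count <- function(concA, concB) {
    res <- tryCatch(
      simulate_population(profile, drugs,
                          schedule_template(concA, concB),
                          egf_conc = egf_conc, horizon = horizon, n0 = n0,
                          record_every = record_every),
      error = function(e) stop(sprintf(
        "simulation failed at concA = %g, concB = %g: %s", concA, concB,
        conditionMessage(e)), call. = FALSE))
    ts <- res$timeseries
    ts$total_live[nrow(ts)]
  }
  control <- end_count(0, 0)
  grid$viability_pct <- vapply(seq_len(nrow(grid)), function(i) {
    if (grid$concA[i] == 0 && grid$concB[i] == 0) return(100)
    viability_percent_of_control(end_count(grid$concA[i], grid$concB[i]),
                                 control)
  }, numeric(1))
  grid$effect_pct <- 100 - grid$viability_pct
  effA <- grid$effect_pct[match(paste(grid$concA, 0),
                                paste(grid$concA, grid$concB))]
  effB <- grid$effect_pct[match(paste(0, grid$concB),
                                paste(grid$concA, grid$concB))]
  if (anyNA(effA) || anyNA(effB)) {
    stop("grids must include concentration 0 for Bliss scoring",
         call. = FALSE)
  }
  grid$bliss_score_pct <- bliss_excess(grid$effect_pct, effA, effB)
  grid$profile <- profile$name
  grid <- grid[, c("concA", "concB", "profile", "viability_pct",
                   "effect_pct", "bliss_score_pct")]
  structure(grid, class = c("dose_response_surface", "data.frame"),
            drugA = drugA$name, drugB = drugB$name, horizon = horizon)
}

#' Headline interaction score of a surface
#' @param surface A [combination_surface()] result.
#' @param concA,concB Coordinates; default the highest grid concentrations.
#' @return Bliss score in percentage points.
#' @export
surface_score_at <- function(surface, concA = max(surface$concA),
                             concB = max(surface$concB)) {
  i <- which(surface$concA == concA & surface$concB == concB)
  if (length(i) != 1) stop("no unique surface point at those coordinates",
                           call. = FALSE)
  surface$bliss_score_pct[i]
}

#' Inter-drug delay scan for a normal/malignant profile pair
#'
#' Drug A starts at t = 0; drug B starts `delay` hours later.  For each
#' delay and each profile the end-of-horizon live count is expressed as
#' percent of that profile's untreated control, and the normal:malignant
#' viability ratio is reported; the delay maximising the ratio is the
#' suggested cyclotherapy window.
#'
#' @param profile_pair List with elements `normal` and `malignant`
#'   ([cell_line_profile()] objects sharing the protocol).
#' @param drugA,drugB [drug_model()] objects.
#' @param concA,concB Concentrations.
#' @param delays Non-negative delays (hours) of drug B relative to drug A.
#' @param durationA,durationB Exposure durations (hours).
#' @param horizon Viability read-out time (hours; default drug A start +
#'   72 h).
#' @param egf_conc,n0,record_every Passed to [simulate_population()].
#' @return Object of class `delay_scan`: data frame with `delay_h`,
#'   `viability_normal`, `viability_malignant`, `selectivity_ratio`, and
#'   attribute `best_delay_h` (argmax of the ratio).
#' @export
delay_scan <- function(profile_pair, drugA, drugB, concA, concB,
                       delays = 0:24, durationA = 48, durationB = 24,
                       horizon = 72, egf_conc = 0, n0 = 1000,
                       record_every = 1) {
  stopifnot(all(delays >= 0), all(c("normal", "malignant") %in%
                                    names(profile_pair)))
  drugs <- stats::setNames(list(drugA, drugB), c(drugA$name, drugB$name))
  end_count <- function(profile, schedule) {
    res <- simulate_population(profile, drugs, schedule,
                               egf_conc = egf_conc, horizon = horizon,
                               n0 = n0, record_every = record_every)
    ts <- res$timeseries
    ts$total_live[nrow(ts)]
  }
  controls <- lapply(profile_pair[c("normal", "malignant")], end_count,
                     schedule = exposure_schedule())
  viab <- function(profile, control, delay) {
    sch <- exposure_schedule(data.frame(
      drug = c(drugA$name, drugB$name),
      concentration = c(concA, concB),
      t_start = c(0, delay),
      t_end = c(durationA, delay + durationB)))
    viability_percent_of_control(end_count(profile, sch), control)
  }
  out <- data.frame(delay_h = delays)
  out$viability_normal <- vapply(delays, function(dl)
    viab(profile_pair$normal, controls$normal, dl), numeric(1))
  out$viability_malignant <- vapply(delays, function(dl)
    viab(profile_pair$malignant, controls$malignant, dl), numeric(1))
  out$selectivity_ratio <- out$viability_normal / out$viability_malignant
  best <- out$delay_h[which.max(out$selectivity_ratio)]
  structure(out, class = c("delay_scan", "data.frame"),
            best_delay_h = best, horizon = horizon,
            drugA = drugA$name, drugB = drugB$name,
            concA = concA, concB = concB)
}

#' Exhaustive protocol optimisation over a concentration/delay grid
#'
#' Grid search over candidate protocols (drug A concentration, drug B
#' concentration, inter-drug delay) with optional viability constraints,
#' maximising the normal:malignant selectivity ratio.
#'
#' @param profile_pair List with `normal` and `malignant` profiles.
#' @param drugA,drugB [drug_model()] objects.
#' @param grid Data frame with columns `concA`, `concB`, `delay_h` (one row
#'   per candidate protocol).
#' @param min_normal_viability Optional constraint: keep only protocols with
#'   normal viability (% of control) at or above this value.
#' @param max_malignant_viability Optional constraint: malignant viability
#'   at or below this value.
#' @param ... Passed to [delay_scan()] (`durationA`, `durationB`, `horizon`,
#'   `egf_conc`, ...).
#' @return List with `best` (the argmax row, or `NULL` if the feasible set
#'   is empty), `table` (the full evaluated grid with viabilities, ratio and
#'   a `feasible` flag), and `objective`.
#' @export
optimize_schedule <- function(profile_pair, drugA, drugB, grid,
                              min_normal_viability = NULL,
                              max_malignant_viability = NULL, ...) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0,
            all(c("concA", "concB", "delay_h") %in% names(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- delay_scan(profile_pair, drugA, drugB,
                     concA = grid$concA[i], concB = grid$concB[i],
                     delays = grid$delay_h[i], ...)
    data.frame(grid[i, , drop = FALSE],
               viability_normal = sc$viability_normal,
               viability_malignant = sc$viability_malignant,
               selectivity_ratio = sc$selectivity_ratio,
               row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  tab$feasible <- TRUE
  if (!is.null(min_normal_viability)) {
    tab$feasible <- tab$feasible & tab$viability_normal >=
      min_normal_viability
  }
  if (!is.null(max_malignant_viability)) {
    tab$feasible <- tab$feasible & tab$viability_malignant <=
      max_malignant_viability
  }
  feas <- tab[tab$feasible, , drop = FALSE]
  best <- if (nrow(feas) == 0) NULL else
    feas[which.max(feas$selectivity_ratio), , drop = FALSE]
  if (is.null(best)) {
    message("optimize_schedule: feasible set is empty under the stated constraints")
  }
  list(best = best, table = tab, objective = "selectivity-ratio")
}
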