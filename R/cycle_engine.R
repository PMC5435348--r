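# Compartment layout of the 63-state cytokinetic structure:
#   1:15   G1 (increasing protein / cyclin E content)
#   16:45  S  (DNA content 2N -> 4N)
#   46:55  G2 (elapsed G2 time)
#   56:60  M  (prophase, prometaphase, metaphase, anaphase, telophase)
#   61     G0 (reversibly quiescent)
#   62     terminally differentiated / senescent
#   63     irreversibly damaged, metabolically active, non-replicating
.idx <- list(g1 = 1:15, s = 16:45, g2 = 46:55, m = 56:60,
             prophase = 56L, prometaphase = 57L, metaphase = 58L,
             anaphase = 59L, telophase = 60L,
             g0 = 61L, differentiated = 62L, damaged = 63L)

#' Labels of the 63 cytokinetic compartments
#' @return Character vector of length 63 (`g1_01..g1_15`, `s_01..s_30`,
#'   `g2_01..g2_10`, `m_prophase..m_telophase`, `g0`, `differentiated`,
#'   `damaged`).
#' @export
compartment_labels <- function() {
  c(sprintf("g1_%02d", 1:15), sprintf("s_%02d", 1:30),
    sprintf("g2_%02d", 1:10),
    c("m_prophase", "m_prometaphase", "m_metaphase", "m_anaphase",
      "m_telophase"),
    "g0", "differentiated", "damaged")
}

#' Population state over the 63 cytokinetic compartments
#'
#' Cell counts are deterministic (mean-field) real values, appropriate for
#' populations of many cells.  Besides the 63 compartments the state carries
#' the cumulative dead tally, the cumulative net births (one per division)
#' and the simulation time; together these satisfy the book-keeping identity
#' `sum(counts) + cumulative_dead - births = constant`.
#'
#' @param counts Numeric vector of length 63 (non-negative), named as
#'   [compartment_labels()].
#' @param cumulative_dead,births,slipped Non-negative tallies (`slipped` is
#'   the cumulative number of cells that left mitosis by checkpoint slippage
#'   rather than completed division).
#' @param time Hours.
#' @return Object of class `population_state`.
#' @export
population_state <- function(counts = numeric(63), cumulative_dead = 0,
                             births = 0, slipped = 0, time = 0) {
  stopifnot(length(counts) == 63, all(counts >= 0), cumulative_dead >= 0)
  names(counts) <- compartment_labels()
  structure(list(counts = counts, cumulative_dead = cumulative_dead,
                 births = births, slipped = slipped, time = time),
            class = "population_state")
}

#' Total live cells (cycling + G0 + differentiated + damaged)
#' @param state A [population_state()].
#' @return Numeric.
#' @export
total_live <- function(state) sum(state$counts)

#' Transition context for one engine step
#'
#' Bundles the per-step inputs the compartment engine needs: the
#' signalling-derived G1 duration and G1-S permissiveness, kill rates from
#' pharmacodynamics, the metaphase exit signal from the spindle checkpoint,
#' the apoptosis kill rate for arrest-committed cohorts, and the profile's
#' cytokinetic fractions and phase durations.
#'
#' @param profile A [cell_line_profile()].
#' @param g1_duration_h Effective mean G1 dwell (hours).
#' @param g1s_permissiveness Multiplier in \[0,1\] on the G1->S flux.
#' @param s_phase_kill_rate,global_kill_rate Per-hour kill rates.
#' @param m_exit List with `anaphase_allowed` and `slippage_rate`
#'   (see [m_exit_signal()]).
#' @param apoptosis_kill_rate Per-hour removal of arrest-committed metaphase
#'   cells.
#' @return Object of class `transition_context`.
#' @export
transition_context <- function(profile,
                               g1_duration_h = phase_durations(profile)[["G1"]],
                               g1s_permissiveness = 1,
                               s_phase_kill_rate = 0,
                               global_kill_rate = 0,
                               m_exit = list(anaphase_allowed = TRUE,
                                             slippage_rate = 0),
                               apoptosis_kill_rate = 0) {
  stopifnot(g1_duration_h > 0,
            g1s_permissiveness >= 0, g1s_permissiveness <= 1,
            s_phase_kill_rate >= 0, global_kill_rate >= 0,
            is.finite(s_phase_kill_rate), is.finite(global_kill_rate),
            m_exit$slippage_rate >= 0, apoptosis_kill_rate >= 0)
  dur <- phase_durations(profile)
  structure(list(
    g1_duration_h = g1_duration_h,
    g1s_permissiveness = g1s_permissiveness,
    s_phase_kill_rate = s_phase_kill_rate,
    global_kill_rate = global_kill_rate,
    m_exit = m_exit,
    apoptosis_kill_rate = apoptosis_kill_rate,
    s_duration_h = dur[["S"]],
    g2_duration_h = dur[["G2"]],
    m_duration_h = dur[["M"]],
    loss_factor = profile$cell_loss_factor,
    quiescent_fraction = profile$quiescent_fraction,
    differentiating_fraction = profile$differentiating_fraction,
    g0_return_rate = profile$g0_return_rate
  ), class = "transition_context")
}

# Per-stage outflow rates (length 60) for the cycling chain under a context.
stage_rates <- function(ctx) {
  k <- c(rep(15 / ctx$g1_duration_h, 15),
         rep(30 / ctx$s_duration_h, 30),
         rep(10 / ctx$g2_duration_h, 10),
         rep(5 / ctx$m_duration_h, 5))
  k[15] <- k[15] * ctx$g1s_permissiveness
  if (!ctx$m_exit$anaphase_allowed) k[.idx$metaphase] <- 0
  k
}

# Kill-rate vector (length 63). Non-cycle-specific kill spares the 5 M
# compartments (no transcription during mitosis); S-phase kill hits only S;
# the apoptosis kill removes arrest-committed metaphase cohorts.
kill_rates <- function(ctx) {
  kv <- numeric(63)
  kv[c(.idx$g1, .idx$s, .idx$g2, .idx$g0, .idx$differentiated,
       .idx$damaged)] <- ctx$global_kill_rate
  kv[.idx$s] <- kv[.idx$s] + ctx$s_phase_kill_rate
  kv[.idx$metaphase] <- kv[.idx$metaphase] + ctx$apoptosis_kill_rate
  kv
}

# Time derivative of c(counts, cumulative_dead, births).
population_deriv <- function(x, k, kv, ctx) {
  n <- x[1:63]
  cyc <- n[1:60]
  out <- k * cyc
  slip_out <- ctx$m_exit$slippage_rate * n[.idx$metaphase]
  f_div <- out[60]
  daughters <- 2 * f_div
  dead_div <- daughters * ctx$loss_factor
  surv <- daughters - dead_div
  to_diff <- surv * ctx$differentiating_fraction
  rest <- surv - to_diff
  to_g0 <- rest * ctx$quiescent_fraction
  to_g1 <- rest - to_g0
  g0_ret <- ctx$g0_return_rate * n[.idx$g0]
  dn <- numeric(63)
  dn[1:60] <- c(0, out[1:59]) - out
  dn[1] <- dn[1] + to_g1 + slip_out + g0_ret
  dn[.idx$metaphase] <- dn[.idx$metaphase] - slip_out
  dn[.idx$g0] <- to_g0 - g0_ret
  dn[.idx$differentiated] <- to_diff
  kill <- kv * n
  dn <- dn - kill
  c(dn, sum(kill) + dead_div, f_div, slip_out)
}

#' Advance a population by one time step
#'
#' Integrates the 63-compartment flow system over `dt` with a classical
#' fourth-order Runge-Kutta step, with the context's rates held constant
#' across the step.  Cohorts progress G1 -> S -> G2 -> M; at division each
#' cell yields two daughters which are partitioned, in this order, by the
#' spontaneous loss factor, the differentiating fraction and the quiescent
#' fraction; the G1->S flux is scaled by the checkpoint permissiveness; the
#' metaphase-anaphase transition is gated by the spindle checkpoint exit
#' signal (plus its slippage leak straight to G1); kill rates act as
#' exponential decrements on their target compartments.
#'
#' @param state A [population_state()].
#' @param ctx A [transition_context()].
#' @param dt Step in hours; must satisfy `dt * max(rate) <= 1`, otherwise the
#'   step is rejected.
#' @return Updated [population_state()].
#' @export
advance <- function(state, ctx, dt) {
  stopifnot(inherits(state, "population_state"),
            inherits(ctx, "transition_context"), dt > 0)
  k <- stage_rates(ctx)
  kv <- kill_rates(ctx)
  maxrate <- max(k + kv[1:60], kv, ctx$m_exit$slippage_rate +
                   kv[.idx$metaphase])
  if (dt * maxrate > 1) {
    stop(sprintf("dt = %g too large for max transition rate %.3g/h", dt,
                 maxrate), call. = FALSE)
  }
  x <- c(state$counts, state$cumulative_dead, state$births, state$slipped)
  k1 <- population_deriv(x, k, kv, ctx)
  k2 <- population_deriv(x + dt / 2 * k1, k, kv, ctx)
  k3 <- population_deriv(x + dt / 2 * k2, k, kv, ctx)
  k4 <- population_deriv(x + dt * k3, k, kv, ctx)
  x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  tot <- sum(abs(x))
  if (any(x[1:63] < -1e-8 * max(tot, 1))) {
    stop("negative compartment counts after step: dt too large",
         call. = FALSE)
  }
  x[1:63][x[1:63] < 0] <- 0
  state$counts <- stats::setNames(x[1:63], compartment_labels())
  state$cumulative_dead <- unname(x[64])
  state$births <- unname(x[65])
  state$slipped <- unname(x[66])
  state$time <- state$time + dt
  state
}

# Characteristic (Euler-Lotka) equation for the stage-structured chain:
# the exponential growth rate lambda solves R * prod(k_i/(k_i+lambda)) = 1,
# where R is the effective number of cycling daughters per division.
solve_growth_rate <- function(k, R) {
  if (R <= 1) {
    g <- function(lam) log(R) + sum(log(k) - log(k + lam))
    lo <- -0.99 * min(k)
    if (g(lo) < 0) return(lo)  # decaying faster than resolvable
    return(stats::uniroot(g, c(lo, 0 + 1e-12), tol = 1e-12)$root)
  }
  g <- function(lam) log(R) + sum(log(k) - log(k + lam))
  stats::uniroot(g, c(1e-9, 10), tol = 1e-12, extendInt = "downX")$root
}

# Stable stage distribution for growth rate lambda: v_{i+1} = v_i k_i/(k_{i+1}+lambda)
stable_stage_distribution <- function(k, lambda) {
  v <- numeric(60)
  v[1] <- 1 / (k[1] + lambda)
  for (i in 2:60) v[i] <- v[i - 1] * k[i - 1] / (k[i] + lambda)
  v / sum(v)
}

#' Analytic drug-free growth of a profile
#'
#' Computes the steady signalling at the given EGF, the resulting stage
#' rates, and the exponential growth rate from the stage-structured
#' Euler-Lotka equation, together with the stable stage distribution.
#'
#' @param profile A [cell_line_profile()].
#' @param egf_conc EGF concentration.
#' @return List with `lambda` (per hour), `doubling_time_h`, `stage_rates`,
#'   `stable_distribution` (length 60), `signalling`.
#' @export
drugfree_growth <- function(profile, egf_conc = 0) {
  sig <- g1s_steady(profile, egf_conc = egf_conc)
  ctx <- transition_context(profile, g1_duration_h = sig$g1_duration_h,
                            g1s_permissiveness = sig$permissiveness)
  k <- stage_rates(ctx)
  R <- 2 * (1 - profile$cell_loss_factor) *
    (1 - profile$differentiating_fraction) *
    (1 - profile$quiescent_fraction)
  lambda <- solve_growth_rate(k, R)
  list(lambda = lambda,
       doubling_time_h = log(2) / lambda,
       stage_rates = k,
       stable_distribution = stable_stage_distribution(k, lambda),
       signalling = sig)
}

#' Initialise a population
#'
#' `"synchronous-G1"` places every cell in the first G1 compartment.
#' `"asynchronous-steady"` distributes the cycling cells over the 60 cycling
#' compartments according to the stable (exponentially growing) age
#' structure implied by the profile's drug-free growth at the given EGF,
#' places the profile's quiescent fraction in G0, and seeds the terminally
#' differentiated pool at its stationary share so the whole population is
#' on the balanced-growth trajectory from t = 0.
#'
#' @param profile A [cell_line_profile()].
#' @param n0 Initial total cell count (> 0, finite).
#' @param mode `"asynchronous-steady"` or `"synchronous-G1"`.
#' @param egf_conc EGF concentration defining the drug-free steady state.
#' @return A [population_state()].
#' @export
initialize_population <- function(profile, n0 = 1000,
                                  mode = c("asynchronous-steady",
                                           "synchronous-G1"),
                                  egf_conc = 0) {
  mode <- match.arg(mode)
  if (!is.finite(n0) || n0 <= 0) stop("n0 must be finite and > 0",
                                      call. = FALSE)
  counts <- numeric(63)
  if (mode == "synchronous-G1") {
    counts[1] <- n0
  } else {
    gr <- drugfree_growth(profile, egf_conc)
    q <- profile$quiescent_fraction
    v <- gr$stable_distribution
    flux <- gr$stage_rates[60] * v[60]  # division flux per unit cycling mass
    diff_stat <- if (gr$lambda > 0) {
      2 * flux * (1 - profile$cell_loss_factor) *
        profile$differentiating_fraction / gr$lambda
    } else 0
    cyc_mass <- (1 - q) * n0 / (1 + diff_stat)
    counts[1:60] <- cyc_mass * v
    counts[.idx$differentiated] <- cyc_mass * diff_stat
    counts[.idx$g0] <- q * n0
  }
  population_state(counts = counts, time = 0)
}

#' Phase distribution of the live population
#'
#' @param state A [population_state()].
#' @return Named numeric vector of fractions over
#'   `G1, S, G2, M, G0, differentiated, damaged`, summing to 1 over the live
#'   population.
#' @export
phase_distribution <- function(state) {
  live <- total_live(state)
  if (live <= 0) stop("empty population", call. = FALSE)
  n <- state$counts
  c(G1 = sum(n[.idx$g1]), S = sum(n[.idx$s]), G2 = sum(n[.idx$g2]),
    M = sum(n[.idx$m]), G0 = n[[.idx$g0]],
    differentiated = n[[.idx$differentiated]],
    damaged = n[[.idx$damaged]]) / live
}

#' Fitted exponential doubling time over a window
#'
#' Log-linear least-squares fit of total live cells versus time over
#' `window`; returns `log(2) / slope`.
#'
#' @param result A `simulation_result` (from [simulate_population()]) or a
#'   data frame with columns `time_h` and `total_live`.
#' @param window Length-2 numeric `(t_start, t_end)` in hours; defaults to
#'   the full series.
#' @return Doubling time in hours.
#' @export
doubling_time <- function(result, window = NULL) {
  ts <- if (inherits(result, "simulation_result")) result$timeseries else
    result
  stopifnot(all(c("time_h", "total_live") %in% names(ts)))
  if (!is.null(window)) {
    ts <- ts[ts$time_h >= window[1] & ts$time_h <= window[2], , drop = FALSE]
  }
  if (nrow(ts) < 3) stop("window contains fewer than 3 points",
                         call. = FALSE)
  if (any(ts$total_live <= 0)) stop("non-positive counts in window",
                                    call. = FALSE)
  fit <- stats::lm(log(ts$total_live) ~ ts$time_h)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("population is not growing over the window", call. = FALSE)
  }
  log(2) / slope
}

#' @export
print.population_state <- function(x, ...) {
  pd <- phase_distribution(x)
  cat(sprintf("<population_state> t = %.2f h, live = %.4g, dead = %.4g\n",
              x$time, total_live(x), x$cumulative_dead))
  cat("  phases: ", paste(sprintf("%s %.1f%%", names(pd), 100 * pd),
                          collapse = ", "), "\n")
  invisible(x)
}
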