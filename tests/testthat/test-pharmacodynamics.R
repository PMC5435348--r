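test_that("the Hill law has its defining anchor points", {
  dr <- drug_model("x", "s_phase_kill", ec50 = 20, hill_n = 2, emax = 1.5)
  expect_equal(hill_effect(0, dr), 0)
  expect_equal(hill_effect(20, dr), 1.5 / 2)
  expect_equal(hill_effect(1e9, dr), 1.5, tolerance = 1e-6)
  conc <- c(0, 1, 5, 20, 100, 1000)
  expect_true(all(diff(hill_effect(conc, dr)) > 0))
})

test_that("drug model invariants are enforced", {
  expect_error(drug_model("x", "cdk46_inhibition", ec50 = 10, hill_n = 1,
                          emax = 1.2), "emax")
  expect_error(drug_model("x", "s_phase_kill", ec50 = -1, hill_n = 1,
                          emax = 1))
})

test_that("cytotoxicity follows the count-reduction definition, including net growth", {
  expect_equal(cytotoxicity(1000, 1000), 0)
  expect_equal(cytotoxicity(1000, 0), 100)
  expect_equal(cytotoxicity(1000, 2000), -100)
  expect_error(cytotoxicity(0, 10))
})

test_that("viability percent of control behaves at its edges", {
  expect_equal(viability_percent_of_control(500, 500), 100)
  expect_equal(viability_percent_of_control(0, 500), 0)
  expect_error(viability_percent_of_control(10, 0))
})

test_that("Bliss excess is exactly zero for independent exponential kills", {
  # closed-form construction: two drugs with survival fractions exp(-a) and
  # exp(-b) acting independently give combined survival exp(-a-b)
  for (a in c(0.2, 1, 3)) for (b in c(0.1, 0.7, 2)) {
    ea <- 100 * (1 - exp(-a))
    eb <- 100 * (1 - exp(-b))
    eab <- 100 * (1 - exp(-a - b))
    expect_equal(bliss_excess(eab, ea, eb), 0, tolerance = 1e-10)
  }
  expect_equal(bliss_excess(40, 40, 0), 0)  # monotherapy
})

test_that("schedules report the concentrations in force and sharp washout", {
  sch <- exposure_schedule(data.frame(
    drug = c("gemcitabine", "palbociclib"),
    concentration = c(30, 100), t_start = c(12, 0), t_end = c(36, 48)))
  expect_equal(exposure_at(sch, 0), c(palbociclib = 100))
  expect_equal(sort(names(exposure_at(sch, 12))),
               c("gemcitabine", "palbociclib"))
  expect_equal(exposure_at(sch, 36), c(palbociclib = 100))  # washout at end
  expect_equal(schedule_breaks(sch), c(0, 12, 36, 48))
  expect_error(exposure_schedule(data.frame(drug = "x", concentration = 1,
                                            t_start = 5, t_end = 2)))
})

test_that("mechanisms route to the right model inputs and unknown drugs fail", {
  drugs <- list(actinomycin_d = builtin_drug("actinomycin_d"),
                paclitaxel = builtin_drug("paclitaxel"),
                palbociclib = builtin_drug("palbociclib"),
                gemcitabine = builtin_drug("gemcitabine"))
  sch <- exposure_schedule(data.frame(
    drug = c("actinomycin_d", "paclitaxel", "palbociclib", "gemcitabine"),
    concentration = c(100, 10, 30, 30), t_start = 0, t_end = 24))
  ctx <- exposure_to_context(sch, 1, drugs)
  expect_gt(ctx$global_kill_rate, 0)
  expect_gt(ctx$s_phase_kill_rate, 0)
  expect_gt(ctx$sac$microtubule_stabilization, 0.5)
  expect_gt(ctx$palbociclib_inhibition, 0.5)
  expect_error(exposure_to_context(single_exposure("mystery", 1), 0, drugs),
               "mystery")
  # before a segment starts the drug contributes nothing
  late <- single_exposure("gemcitabine", 30, t_start = 12, t_end = 36)
  expect_equal(exposure_to_context(late, 6, drugs)$s_phase_kill_rate, 0)
})

test_that("kill fluxes spare the compartments their mechanism excludes", {
  prof <- plain_profile(loss = 0, diff = 0)
  # all mass in metaphase: a non-cycle-specific kill must not touch it
  counts <- numeric(63); counts[58] <- 1000  # m_metaphase
  st <- population_state(counts = counts)
  ctx <- transition_context(prof, global_kill_rate = 2,
                            m_exit = list(anaphase_allowed = FALSE,
                                          slippage_rate = 0))
  st2 <- advance(st, ctx, 0.15)
  expect_equal(st2$cumulative_dead, 0)
  # all mass in G2: an S-phase kill must not touch it
  counts <- numeric(63); counts[50] <- 1000
  st <- population_state(counts = counts)
  ctx <- transition_context(prof, s_phase_kill_rate = 2)
  st2 <- advance(st, ctx, 0.1)
  expect_equal(st2$cumulative_dead, 0)
  # but mass in S is killed by it
  counts <- numeric(63); counts[20] <- 1000
  st <- population_state(counts = counts)
  st2 <- advance(st, ctx, 0.1)
  expect_gt(st2$cumulative_dead, 0)
})
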