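test_that("the compartment structure has exactly 63 named states", {
  lab <- compartment_labels()
  expect_length(lab, 63)
  expect_equal(sum(startsWith(lab, "g1_")), 15)
  expect_equal(sum(startsWith(lab, "s_")), 30)
  expect_equal(sum(startsWith(lab, "g2_")), 10)
  expect_equal(sum(startsWith(lab, "m_")), 5)
  expect_true(all(c("g0", "differentiated", "damaged") %in% lab))
})

test_that("synchronous initialisation puts every cell in the first G1 state", {
  st <- initialize_population(study_pair$malignant, 1000, "synchronous-G1")
  expect_equal(unname(st$counts[["g1_01"]]), 1000)
  expect_equal(total_live(st), 1000)
  pd <- phase_distribution(st)
  expect_equal(unname(pd[["G1"]]), 1)
})

test_that("asynchronous initialisation honours the quiescent fraction", {
  st <- initialize_population(builtin_profile("arpe19_like_normal"), 1000,
                              "asynchronous-steady")
  expect_equal(unname(st$counts[["g0"]]), 150)  # 15% quiescent
  expect_equal(total_live(st), 1000)
  expect_error(initialize_population(study_pair$malignant, Inf))
})

test_that("asynchronous phase fractions match the exponential age-structure oracle", {
  # independent oracle: stable age density f(a) = 2 lambda exp(-lambda a) on
  # one deterministic-transit cycle of the profile's effective durations,
  # integrated over each phase's age interval
  prof <- study_pair$malignant
  gr <- drugfree_growth(prof, 0)
  k <- gr$stage_rates
  dur <- cumsum(1 / k)  # stage boundary ages along the chain
  bounds <- c(0, dur[c(15, 45, 55, 60)])
  lam <- log(1 / (2 * (1 - prof$cell_loss_factor))) / -bounds[5]
  wt <- exp(-lam * bounds[-5]) - exp(-lam * bounds[-1])
  oracle <- wt / sum(wt)  # G1, S, G2, M fractions of cycling cells
  st <- initialize_population(prof, 1000, "asynchronous-steady")
  pd <- phase_distribution(st)
  got <- pd[c("G1", "S", "G2", "M")] / sum(pd[c("G1", "S", "G2", "M")])
  expect_equal(unname(got), unname(oracle), tolerance = 0.02)
})

test_that("advancing an empty population leaves it empty", {
  st <- population_state()
  ctx <- transition_context(plain_profile())
  st2 <- advance(st, ctx, 0.1)
  expect_equal(total_live(st2), 0)
  expect_equal(st2$cumulative_dead, 0)
})

test_that("no kill and no loss means no deaths", {
  prof <- plain_profile(loss = 0, diff = 0)
  res <- simulate_population(prof, horizon = 24, record_every = 4)
  expect_equal(res$final_state$cumulative_dead, 0, tolerance = 1e-9)
})

test_that("the conservation identity holds through a drugged run", {
  drugs <- list(gemcitabine = builtin_drug("gemcitabine"),
                paclitaxel = builtin_drug("paclitaxel"))
  sch <- exposure_schedule(data.frame(
    drug = c("gemcitabine", "paclitaxel"), concentration = c(30, 10),
    t_start = c(6, 0), t_end = c(30, 24)))
  res <- simulate_population(study_pair$normal, drugs, sch, horizon = 36,
                             record_every = 2)
  ts <- res$timeseries
  balance <- ts$total_live + ts$cumulative_dead - ts$births
  expect_equal(balance, rep(balance[1], length(balance)),
               tolerance = 1e-6)
  expect_true(all(as.matrix(ts[, compartment_labels()]) >= 0))
})

test_that("too-large steps are rejected, not clamped", {
  st <- initialize_population(plain_profile(), 100, "synchronous-G1")
  ctx <- transition_context(plain_profile(), g1_duration_h = 0.1)
  expect_error(advance(st, ctx, 0.5), "too large")
})

test_that("doubling_time recovers an exact exponential and rejects decay", {
  ts <- data.frame(time_h = 0:48)
  ts$total_live <- 1000 * 2^(ts$time_h / 20)
  expect_equal(doubling_time(ts), 20, tolerance = 1e-9)
  ts$total_live <- 1000 * 2^(-ts$time_h / 20)
  expect_error(doubling_time(ts), "not growing")
})

test_that("drug-free growth matches the closed-form doubling time within 2%", {
  prof <- plain_profile(loss = 0.05, diff = 0.1)
  gr <- drugfree_growth(prof, 0)
  tc_eff <- sum(1 / gr$stage_rates)  # effective cycle time incl. gate dwell
  td_closed <- tc_eff * log(2) / log(2 * (1 - 0.05) * (1 - 0.1))
  res <- simulate_population(prof, horizon = 96, record_every = 2)
  td_sim <- doubling_time(res, c(12, 96))
  expect_lt(abs(td_sim - td_closed) / td_closed, 0.02)
})

test_that("halving the integrator step changes the 96 h count by < 0.5%", {
  prof <- study_pair$normal
  n1 <- final_live(simulate_population(prof, horizon = 96, dt = 0.05,
                                       record_every = 8))
  n2 <- final_live(simulate_population(prof, horizon = 96, dt = 0.025,
                                       record_every = 8))
  expect_lt(abs(n1 - n2) / n2, 0.005)
})

test_that("the drug-free steady phase distribution is stationary over a full cycle", {
  prof <- study_pair$normal
  res <- simulate_population(prof, horizon = 25, record_every = 25)
  p0 <- phase_distribution(population_state(
    counts = unlist(res$timeseries[1, compartment_labels()])))
  p1 <- phase_distribution(res$final_state)
  expect_true(all(abs(p1 - p0) < 0.01))
  expect_equal(sum(p1), 1, tolerance = 1e-9)
})
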