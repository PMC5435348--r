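# time for the mean-field ensemble, started all-unattached, to exceed an
# amphitelic fraction of 0.99 (no dilution; fresh cohort)
meanfield_t99 <- function(drugs = sac_drug_effects(), dt = 0.002,
                          t_max = 5) {
  ens <- kinetochore_ensemble()
  t <- 0
  while (t < t_max) {
    ens <- update_attachments(ens, drugs, dt)
    t <- t + dt
    if (ens$frac_amphitelic > 0.99) return(t)
  }
  NA_real_
}

test_that("an all-amphitelic ensemble is absorbing without drugs", {
  ens <- kinetochore_ensemble(frac_unattached = 0, frac_monotelic = 0,
                              frac_syntelic = 0, frac_amphitelic = 1,
                              wait_signal = 0)
  out <- update_attachments(ens, sac_drug_effects(), dt = 0.5)
  expect_equal(out$frac_amphitelic, 1, tolerance = 1e-9)
})

test_that("aurora kinase B inhibition removes the only escape from syntelic attachment", {
  ens <- kinetochore_ensemble(frac_unattached = 0.3, frac_monotelic = 0.3,
                              frac_syntelic = 0.2, frac_amphitelic = 0.2)
  drugs <- sac_drug_effects(akb_inhibition = 1)
  prev <- ens$frac_syntelic
  for (i in 1:40) {
    ens <- update_attachments(ens, drugs, dt = 0.02)
    expect_gte(ens$frac_syntelic, prev - 1e-9)
    prev <- ens$frac_syntelic
  }
})

test_that("attachment fractions stay on the simplex under random perturbations", {
  set.seed(7)
  ens <- kinetochore_ensemble()
  for (i in 1:100) {
    drugs <- sac_drug_effects(microtubule_stabilization = runif(1, 0, 0.95),
                              akb_inhibition = runif(1, 0, 1))
    ens <- update_attachments(ens, drugs, dt = runif(1, 0.01, 0.3),
                              reset_rate = runif(1, 0, 5))
    f <- c(ens$frac_unattached, ens$frac_monotelic, ens$frac_syntelic,
           ens$frac_amphitelic)
    expect_true(all(f >= 0))
    expect_equal(sum(f), 1, tolerance = 1e-8)
  }
})

test_that("the wait signal decays rapidly once attachment is complete, never below 0", {
  ens <- kinetochore_ensemble(frac_unattached = 0, frac_monotelic = 0,
                              frac_syntelic = 0, frac_amphitelic = 1,
                              wait_signal = 2)
  tau <- 1 / cyclosim:::.cyclosim_defaults$sac_wait_decay
  for (i in 1:10) ens <- update_wait_signal(ens, aka_fold = 1,
                                            dt = 5 * tau / 10)
  expect_lt(ens$wait_signal, 0.01 * 2)
  expect_gte(ens$wait_signal, 0)
})

test_that("aurora kinase A over-expression lowers the sustained wait signal", {
  mk <- function(fold) {
    ens <- kinetochore_ensemble(frac_unattached = 0.5, frac_monotelic = 0.2,
                                frac_syntelic = 0.2, frac_amphitelic = 0.1,
                                wait_signal = 0)
    for (i in 1:200) {
      ens$frac_amphitelic <- 0.1  # hold the attachment state fixed
      ens$frac_unattached <- 0.5
      ens <- update_wait_signal(ens, aka_fold = fold, dt = 0.05)
    }
    ens$wait_signal
  }
  expect_lt(mk(3), mk(1))
})

test_that("metaphase exit logic: open gate below threshold, slippage only while blocked", {
  ens <- kinetochore_ensemble(wait_signal = 0)
  open <- m_exit_signal(ens, threshold = 0.5)
  expect_true(open$anaphase_allowed)
  expect_identical(open$slippage_rate, 0)
  ens$wait_signal <- 2
  blk1 <- m_exit_signal(ens, threshold = 0.5, aka_fold = 1,
                        arrest_clock = 12)
  blk3 <- m_exit_signal(ens, threshold = 0.5, aka_fold = 3,
                        arrest_clock = 12)
  blk3_late <- m_exit_signal(ens, threshold = 0.5, aka_fold = 3,
                             arrest_clock = 2)
  expect_false(blk1$anaphase_allowed)
  expect_gt(blk1$slippage_rate, 0)
  expect_gt(blk3$slippage_rate, blk1$slippage_rate)
  expect_gt(blk3$slippage_rate, blk3_late$slippage_rate)
})

test_that("time to attachment completion is non-decreasing in stabilisation and AK-B inhibition", {
  t0 <- meanfield_t99()
  t_ms <- meanfield_t99(sac_drug_effects(microtubule_stabilization = 0.5))
  t_akb <- meanfield_t99(sac_drug_effects(akb_inhibition = 0.8))
  expect_gte(t_ms, t0)
  expect_gte(t_akb, t0)
})

test_that("mean-field attachment kinetics agree with the stochastic per-kinetochore oracle", {
  mc <- sac_stochastic_oracle(n_cells = 1500, t_max = 2, seed = 99)
  # population amphitelic fraction crossing 0.99
  tt <- seq(0.05, 2, by = 0.005)
  fr <- mc$frac_amphitelic(tt)
  mc_t99 <- tt[which(fr > 0.99)[1]]
  mf_t99 <- meanfield_t99()
  expect_lt(abs(mf_t99 - mc_t99) / mc_t99, 0.05)
  # per-cell completion time (all 46 pairs amphitelic) is finite drug-free
  expect_true(all(is.finite(mc$time_to_all_amphitelic)))
})
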