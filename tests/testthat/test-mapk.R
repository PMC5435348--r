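test_that("wild-type cascade is basal without ligand and saturates with it", {
  low <- update_mapk(mapk_state(), egf_conc = 0, ras_status = "wild")
  hi <- update_mapk(mapk_state(), egf_conc = 1e4, ras_status = "wild")
  expect_lt(low$erk_active, 0.1)
  expect_gt(hi$erk_active, 0.95)
  # monotone in EGF
  egfs <- c(0, 0.1, 0.5, 1, 5, 50, 1e3)
  erks <- vapply(egfs, function(e)
    update_mapk(mapk_state(), e, "wild")$erk_active, numeric(1))
  expect_true(all(diff(erks) > 0))
  expect_true(all(erks >= 0 & erks <= 1))
})

test_that("mutant RAS output equals the EGF-saturated wild-type equilibrium", {
  # constitutive activation: zero ligand plus full receptor blockade still
  # yields the wild-type EGF-saturated ERK output
  mut <- update_mapk(mapk_state(), egf_conc = 0, ras_status = "mutant",
                     inhibitions = c(1, 0, 0, 0, 0))
  wt_sat <- update_mapk(mapk_state(), egf_conc = 1e9, ras_status = "wild")
  expect_equal(mut$erk_active, wt_sat$erk_active, tolerance = 1e-6)
  # and is invariant to ligand concentration (exact, by construction)
  erks <- vapply(c(0, 1, 100), function(e)
    update_mapk(mapk_state(), e, "mutant")$erk_active, numeric(1))
  expect_equal(max(erks) - min(erks), 0)
})

test_that("cyclin D production is basal without ERK, monotone, and scales with fold", {
  s0 <- update_mapk(mapk_state(), 0, "wild")
  s0$erk_active <- 0
  expect_gt(cyclin_d_production(s0), 0)     # cells cycle slowly without EGF
  expect_equal(cyclin_d_production(s0, overexpression_fold = 0), 0)
  erks <- seq(0, 1, by = 0.1)
  prods <- vapply(erks, function(e) {
    s <- s0; s$erk_active <- e; cyclin_d_production(s)
  }, numeric(1))
  expect_true(all(diff(prods) >= 0))
})
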