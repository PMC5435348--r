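relax_to_steady <- function(state, prod, inh = 0, n = 400, dt = 0.25, ...) {
  for (i in seq_len(n)) state <- update_g1s(state, prod, inh, dt = dt, ...)
  state
}

test_that("without cyclin kinase activity RB stays unphosphorylated and the gate shuts", {
  s <- g1s_state(cyclin_d = 0, cyclin_e = 0,
                 rb_phosphorylated_fraction = 0, e2f_free_fraction = 0,
                 myc_activity = 0)
  # zero cyclin D production and suppressed cyclin E basal input
  s <- relax_to_steady(s, prod = 0, inh = 1)
  expect_lt(s$rb_phosphorylated_fraction, 0.05)
  expect_lt(g1s_permissiveness(s), 1e-4)
})

test_that("full cdk4/6 inhibition zeroes the cdk4 contribution exactly", {
  s <- update_g1s(g1s_state(cyclin_d = 5), cyclin_d_production = 1,
                  palbociclib_inhibition = 1, dt = 0.1)
  expect_identical(s$cdk4_activity, 0)
})

test_that("permissiveness is a monotone saturating function of E2F activity", {
  set.seed(41)
  for (i in 1:30) {
    e <- sort(runif(2))
    s1 <- g1s_state(); s1$e2f_free_fraction <- e[1]; s1$myc_activity <- e[1]
    s2 <- g1s_state(); s2$e2f_free_fraction <- e[2]; s2$myc_activity <- e[2]
    expect_lte(g1s_permissiveness(s1), g1s_permissiveness(s2))
  }
  s0 <- g1s_state(); s0$e2f_free_fraction <- 0; s0$myc_activity <- 0
  expect_equal(g1s_permissiveness(s0), 0)
})

test_that("mutant-RAS steady state equals wild-type RAS at saturating EGF", {
  mal <- study_pair$malignant
  nor <- study_pair$normal
  ss_mut <- g1s_steady(mal, egf_conc = 0)
  ss_sat <- g1s_steady(nor, egf_conc = 1e9)
  expect_equal(ss_mut$g1s$cyclin_d, ss_sat$g1s$cyclin_d, tolerance = 1e-5)
  expect_equal(ss_mut$permissiveness, ss_sat$permissiveness,
               tolerance = 1e-5)
  expect_equal(ss_mut$g1_duration_h, ss_sat$g1_duration_h, tolerance = 1e-5)
})

test_that("checkpoint inhibition is reversible within one G1 transit", {
  nor <- study_pair$normal
  inh <- hill_effect(30, builtin_drug("palbociclib"))
  free <- g1s_steady(nor, 0)
  blocked <- g1s_steady(nor, 0, palbociclib_inhibition = inh,
                        from = free$g1s)
  expect_lt(blocked$permissiveness, 0.01)
  # washout: relax from the collapsed state for one (drug-free) G1 transit
  s <- blocked$g1s
  prod <- cyclin_d_production(update_mapk(mapk_state(), 0, "wild"))
  steps <- ceiling(free$g1_duration_h / 0.1)
  for (i in seq_len(steps)) s <- update_g1s(s, prod, 0, dt = 0.1)
  expect_gt(g1s_permissiveness(s), 0.9 * free$permissiveness)
})

test_that("the malignant line retains more permissiveness than normal under palbociclib", {
  for (conc in c(30, 100, 300)) {
    inh <- hill_effect(conc, builtin_drug("palbociclib"))
    pm <- g1s_steady(study_pair$malignant, 0, inh)$permissiveness
    pn <- g1s_steady(study_pair$normal, 0, inh)$permissiveness
    expect_gt(pm, pn)
  }
})

test_that("an RB-null genotype pins free E2F at 1", {
  s <- update_g1s(g1s_state(cyclin_d = 0, cyclin_e = 0), 0, 0, dt = 0.1,
                  rb_status = "null")
  expect_equal(s$e2f_free_fraction, 1)
})
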