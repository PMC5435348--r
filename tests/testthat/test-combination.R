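test_that("a surface with a zero-only partner grid scores 0 everywhere", {
  actd <- builtin_drug("actinomycin_d")
  pac <- builtin_drug("paclitaxel")
  sf <- combination_surface(study_pair$normal, actd, pac,
                            conc_gridA = c(0, 30), conc_gridB = 0,
                            horizon = 24, record_every = 4)
  expect_true(all(abs(sf$bliss_score_pct) < 1e-9))
  expect_equal(sf$viability_pct[sf$concA == 0 & sf$concB == 0], 100)
  # viability non-increasing in the kill-drug concentration
  mono <- sf[order(sf$concA), ]
  expect_true(all(diff(mono$viability_pct) <= 0))
})

test_that("delay 0 in a delay scan reduces to simultaneous administration", {
  pal <- builtin_drug("palbociclib"); gem <- builtin_drug("gemcitabine")
  sc <- delay_scan(study_pair, pal, gem, 30, 30, delays = 0,
                   durationA = 24, durationB = 24, horizon = 36,
                   record_every = 4)
  drugs <- list(palbociclib = pal, gemcitabine = gem)
  sch <- exposure_schedule(data.frame(
    drug = c("palbociclib", "gemcitabine"), concentration = 30,
    t_start = 0, t_end = 24))
  man_t <- final_live(simulate_population(study_pair$normal, drugs, sch,
                                          horizon = 36, record_every = 4))
  man_c <- final_live(simulate_population(study_pair$normal, horizon = 36,
                                          record_every = 4))
  expect_equal(sc$viability_normal,
               viability_percent_of_control(man_t, man_c),
               tolerance = 1e-9)
})

test_that("schedule optimisation is consistent with the delay scan and filters constraints", {
  pal <- builtin_drug("palbociclib"); gem <- builtin_drug("gemcitabine")
  grid <- data.frame(concA = 30, concB = 30, delay_h = c(0, 6, 12))
  opt <- optimize_schedule(study_pair, pal, gem, grid,
                           durationA = 24, durationB = 12, horizon = 36,
                           record_every = 4)
  sc <- delay_scan(study_pair, pal, gem, 30, 30, delays = c(0, 6, 12),
                   durationA = 24, durationB = 12, horizon = 36,
                   record_every = 4)
  expect_equal(opt$table$selectivity_ratio, sc$selectivity_ratio,
               tolerance = 1e-9)
  expect_equal(opt$best$delay_h,
               sc$delay_h[which.max(sc$selectivity_ratio)])
  # manual filter oracle on the evaluated table
  thr <- sort(opt$table$viability_normal)[2]  # keeps exactly two rows
  opt2 <- optimize_schedule(study_pair, pal, gem, grid,
                            min_normal_viability = thr,
                            durationA = 24, durationB = 12, horizon = 36,
                            record_every = 4)
  manual <- opt2$table[opt2$table$viability_normal >= thr, ]
  expect_equal(sum(opt2$table$feasible), nrow(manual))
  expect_equal(opt2$best$selectivity_ratio,
               max(manual$selectivity_ratio))
  # impossible constraint reports an empty feasible set
  expect_message(
    opt3 <- optimize_schedule(study_pair, pal, gem,
                              grid[1, , drop = FALSE],
                              min_normal_viability = 1000,
                              durationA = 24, durationB = 12,
                              horizon = 36, record_every = 4),
    "empty")
  expect_null(opt3$best)
})

test_that("a single-point grid optimisation returns that point", {
  pal <- builtin_drug("palbociclib"); gem <- builtin_drug("gemcitabine")
  grid <- data.frame(concA = 30, concB = 30, delay_h = 6)
  opt <- optimize_schedule(study_pair, pal, gem, grid,
                           durationA = 24, durationB = 12, horizon = 36,
                           record_every = 4)
  expect_equal(opt$best$delay_h, 6)
  expect_equal(nrow(opt$table), 1)
})
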