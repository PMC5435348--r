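test_that("built-in profiles carry the tabulated cytokinetic parameters", {
  mal <- builtin_profile("miapaca2")
  expect_equal(mal$cell_cycle_time, 19.5)
  expect_equal(mal$cell_loss_factor, 0.03)
  expect_equal(mal$quiescent_fraction, 0)
  expect_equal(mal$differentiating_fraction, 0)
  expect_identical(mal$p53_status, "mutant")
  expect_identical(mal$ras_status, "mutant")
  expect_equal(mal$aka_fold, 3)

  nor <- builtin_profile("arpe19_like_normal")
  expect_equal(nor$cell_cycle_time, 19.8)
  expect_equal(nor$cell_loss_factor, 0.05)
  expect_equal(nor$quiescent_fraction, 0.15)
  expect_equal(nor$differentiating_fraction, 0.20)
  expect_identical(nor$ras_status, "wild")
  expect_equal(nor$aka_fold, 1)

  expect_error(builtin_profile("hela"))
})

test_that("profile invariants are enforced and the doubling-time tension warns", {
  expect_error(cell_line_profile("bad", 20, cell_loss_factor = 1.2),
               "cell_loss_factor")
  expect_error(cell_line_profile("bad", 20,
                                 phase_duration_split = c(G1 = 0.5, S = 0.5,
                                                          G2 = 0.2, M = 0.05)),
               "sum to 1")
  expect_silent(validate_profile(plain_profile()))
  # the recorded ~26 h cannot follow from Tc 19.5 + loss 0.03 alone
  p <- builtin_profile("miapaca2")
  p$s_phase_extension_h <- 0
  expect_warning(validate_profile(p), "doubling time")
})

test_that("the normal counterpart resets checkpoint genotype but keeps cytokinetics", {
  mal <- builtin_profile("miapaca2")
  nor <- normalized_counterpart(mal)
  expect_identical(nor$ras_status, "wild")
  expect_identical(nor$p53_status, "wild")
  expect_equal(nor$aka_fold, 1)
  expect_equal(nor$s_phase_extension_h, 0)
  expect_equal(nor$cell_cycle_time, mal$cell_cycle_time)
  expect_equal(nor$cell_loss_factor, mal$cell_loss_factor)
  expect_equal(nor$quiescent_fraction, mal$quiescent_fraction)
})

test_that("profiles round-trip through the config format", {
  p <- builtin_profile("arpe19_like_normal")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_profile(p, f)
  q <- read_profile(f)
  expect_equal(unclass(q)[sort(names(unclass(q)))],
               unclass(p)[sort(names(unclass(p)))])
})

test_that("nominal phase durations split Tc and carry the S extension", {
  d <- phase_durations(builtin_profile("miapaca2"))
  expect_equal(sum(d), 19.5 + builtin_profile("miapaca2")$s_phase_extension_h)
  expect_equal(unname(d["G1"]), 0.4 * 19.5)
  expect_gt(d[["S"]], 0.4 * 19.5)  # replication-stress extension lives in S
})
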