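test_that("the off state is stable: zero damage never commits, at any step size", {
  for (dt in c(0.5, 0.05)) {
    s <- apoptosis_state()
    for (i in seq_len(ceiling(200 / dt) / 10)) {
      s <- update_apoptosis(s, damage_signal = 0, dt = dt * 10)
    }
    expect_false(s$committed)
    expect_lt(s$caspase3, 0.01)
  }
})

test_that("sustained damage commits in finite time and commitment is irreversible", {
  s <- apoptosis_state()
  t <- 0
  while (!s$committed && t < 100) {
    s <- update_apoptosis(s, damage_signal = 5, dt = 0.25)
    t <- t + 0.25
  }
  expect_true(s$committed)
  expect_lt(t, 100)
  for (i in 1:100) s <- update_apoptosis(s, damage_signal = 0, dt = 0.25)
  expect_true(s$committed)  # removing the signal does not uncommit
})

test_that("commitment time is non-increasing in damage magnitude", {
  commit_time <- function(dmg) {
    s <- apoptosis_state()
    t <- 0
    while (!s$committed && t < 200) {
      s <- update_apoptosis(s, dmg, dt = 0.25)
      t <- t + 0.25
    }
    t
  }
  times <- vapply(c(2, 5, 10), commit_time, numeric(1))
  expect_true(all(diff(times) <= 0))
})

test_that("caspase species stay non-negative under erratic inputs", {
  set.seed(11)
  s <- apoptosis_state()
  for (i in 1:200) {
    s <- update_apoptosis(s, damage_signal = rexp(1, 1 / 3),
                          dt = runif(1, 0.01, 0.5))
    expect_true(all(unlist(s[c("procaspase9", "caspase9", "procaspase3",
                               "caspase3")]) >= 0))
  }
})

test_that("the arrest damage signal engages only beyond the tolerance", {
  expect_equal(arrest_damage_signal(10, 24), 0)
  expect_equal(arrest_damage_signal(24, 24), 0)
  expect_gt(arrest_damage_signal(30, 24), 0)
})
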