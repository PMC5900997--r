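test_that("branch lag is residence time, additive along a path", {
  expect_equal(branch_lag(100, 50), 2)
  expect_equal(branch_lag(0, 50), 0)
  expect_equal(branch_lag(60, 30) + branch_lag(40, 20), 4)
  expect_error(branch_lag(10, 0), "lag undefined")
})

test_that("confluence mixing is the flow-weighted mean", {
  expect_equal(mix_at_confluence(c(1, 1), c(5, 5)), 5)
  expect_equal(mix_at_confluence(c(3, 1), c(100, 40)), 85)
  expect_equal(mix_at_confluence(7, 42), 42)
  m <- mix_at_confluence(c(2, 1), rbind(c(1, 2), c(4, 8)))
  expect_equal(m, c(2, 4))
  expect_error(mix_at_confluence(c(0, 0), c(1, 2)), "all-zero")
  expect_error(mix_at_confluence(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("identical inputs propagate unchanged and settle at steady state", {
  vc <- venous_chain()
  # both acini step from 90 to 600 at breath 10, then hold
  ec <- matrix(rep(c(rep(90, 9), rep(600, 21)), each = 2), nrow = 2)
  vf <- propagate_venous(vc$vein, ec, vc$perf, breath_s = 5)
  # same plateau everywhere once all lags have passed
  expect_lt(max(abs(vf$series[, 15:30] - 600)), 1e-6)
  expect_lt(max(abs(vf$series[, 1:8] - 90)), 1e-6)
  expect_true(all(vf$lag_s >= 0))
  # lags accumulate toward the heart along any path
  expect_true(all(vf$lag_s[1] + vf$lag_s[2] + vf$lag_s[3:4] >
                    vf$lag_s[3:4]))
})

test_that("a step is delayed by the cumulative path lag", {
  # choose volumes so branch lags are exactly one breath each
  vc <- venous_chain(Q = c(100, 100, 60, 40), L = c(10, 10, 1e-6, 1e-6))
  vol_target <- 100 * 5             # one 5-s breath at root flow
  r <- sqrt(vol_target / (pi * 10))
  vc$vein$radius_mm <- c(r, r, 1e-6, 1e-6)
  vc$perf$vein$D_mm <- 2 * vc$vein$radius_mm
  n <- 30; kstep <- 10
  ec <- matrix(40, 2, n)
  ec[, kstep:n] <- 600
  vf <- propagate_venous(vc$vein, ec, vc$perf, breath_s = 5)
  # terminals have negligible lag; the root sits two breath-lags upstream
  root <- vf$series[1, ]
  expect_lt(root[kstep + 1], 600)
  expect_equal(root[kstep + 2], 600, tolerance = 1e-6)
  expect_equal(root[kstep - 1], 40, tolerance = 1e-6)
})

test_that("the steady root concentration is the flow-weighted acinar mean", {
  vc <- venous_chain(Q = c(100, 100, 60, 40))
  ec <- matrix(c(rep(100, 30), rep(40, 30)), 2, byrow = TRUE)
  vf <- propagate_venous(vc$vein, ec, vc$perf, breath_s = 5)
  expect_equal(vf$series[1, 30], (60 * 100 + 40 * 40) / 100,
               tolerance = 1e-6)
})

test_that("topology mismatches are rejected", {
  vc <- venous_chain()
  ec <- matrix(100, 2, 10)
  bad <- vc$perf
  bad$vein <- bad$vein[1:3, ]
  expect_error(propagate_venous(vc$vein, ec, bad, 5), "match")
  expect_error(propagate_venous(vc$vein, ec[1, , drop = FALSE], vc$perf, 5),
               "terminals")
})
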