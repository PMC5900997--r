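test_that("the response library spans SV 0.01-10 in 15% increments", {
  lib <- build_library()
  expect_identical(length(lib$sv), 50L)
  expect_equal(lib$sv, 0.01 * 1.15^(0:49))
  expect_lt(max(lib$sv), 10)
  expect_equal(max(lib$sv), 0.01 * 1.15^49, tolerance = 1e-12)
  expect_true(all(diff(lib$sv) > 0))
  # monotone within each constant-FIO2 block
  s <- make_schedule()
  for (blk in list(21:40, 41:60)) {
    d <- t(apply(lib$curves[, blk], 1, diff))
    expect_true(all(d >= -1e-12) || all(d <= 1e-12))
  }
})

test_that("washin follows the closed form c_n = c_inf + (c0 - c_inf)(1+s)^-n", {
  lib <- build_library()
  s <- make_schedule()
  # inside the first O2 block (breaths 21-40) each curve relaxes toward 1
  for (k in c(5, 20, 35)) {
    sv <- lib$sv[k]
    c0 <- lib$curves[k, 20]
    m <- 1:20
    oracle <- 1 + (c0 - 1) * (1 + sv)^(-m)
    expect_equal(unname(lib$curves[k, 20 + m]), oracle, tolerance = 1e-12)
  }
})

test_that("a unit with SV 0.193 needs 14 breaths to reach 90% of a step", {
  cfg <- svi_config(inference = list(sv_min = 0.193, sv_n = 2))
  lib <- build_library(make_schedule(cfg), cfg)
  blk <- lib$curves[1, 21:40]
  c0 <- lib$curves[1, 20]
  frac <- (blk - c0) / (1 - c0)
  expect_identical(unname(which(frac >= 0.9)[1]), 14L)
  expect_identical(ceiling(log(0.1) / log(1 / 1.193)), 14)
})

test_that("in the infinite-SV limit the response is the schedule itself", {
  s <- make_schedule()
  inst <- inert_response(1e9, s)
  expect_equal(as.numeric(inst), s$fio2, tolerance = 1e-8)
})

test_that("a library curve matches itself with rank correlation one", {
  lib <- build_library()
  for (k in c(1, 25, 50)) {
    out <- infer_sv(lib$curves[k, ], lib)
    expect_equal(out$sv, lib$sv[k])
    expect_equal(out$rho, 1)
    expect_false(out$discarded)
  }
})

test_that("small perturbations stay within one library bin", {
  lib <- build_library()
  k <- 25
  rng <- diff(range(lib$curves[k, ]))
  set.seed(101)
  hits <- replicate(25, {
    x <- lib$curves[k, ] + stats::rnorm(220, 0, 0.01 * rng)
    which(lib$sv == infer_sv(x, lib)$sv)
  })
  expect_true(all(abs(hits - k) <= 1))
})

test_that("white noise is discarded in at least 90% of trials", {
  lib <- build_library()
  set.seed(77)
  noise <- matrix(stats::rnorm(400 * 220), 400, 220)
  out <- infer_sv(noise, lib)
  expect_gte(mean(out$discarded), 0.9)
  expect_true(all(out$reason[out$discarded] == "not_significant"))
})

test_that("constant series are discarded as zero-variance", {
  lib <- build_library()
  out <- infer_sv(rep(0.4, 220), lib)
  expect_true(out$discarded)
  expect_identical(out$reason, "zero_variance")
  expect_error(infer_sv(rep(1, 10), lib), "length")
})
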