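test_that("Peclet numbers and the advection-only rule", {
  expect_equal(peclet(10, 100, 22.5), 1000 / 22.5)
  expect_gt(peclet(10, 100, 22.5), 5)      # advection-only regime
  expect_equal(peclet(10, 0, 22.5), 0)     # diffusion stays active
  expect_equal(peclet(1.125, 100, 22.5), 5)  # boundary case is >= 5
  expect_error(peclet(10, 1, 0), "positive")
})

test_that("a uniform field is preserved by the transport step", {
  mesh <- discretize_tree(straight_tree(), 2)
  st <- airway_gas_state(mesh, 0.4, u_insp = 50, u_exp = -50, svi_config())
  st <- apply_boundaries(st, "inspiration", fio2 = 0.4)
  st$c_ac <- rep(0.4, length(mesh$term_nodes))
  for (k in 1:10) st <- transport_step(st, 0.05)
  expect_lt(max(abs(st$c - 0.4)), 1e-10)
})

test_that("pure diffusion grows a Gaussian's variance by 2 D t", {
  tr <- straight_tree(200, 2)
  mesh <- discretize_tree(tr, 1)
  pos <- seq(0, 200, length.out = mesh$n_nodes)
  c0 <- exp(-(pos - 100)^2 / (2 * 25))
  cfg <- svi_config(transport = list(dt_s = 0.01))
  st <- airway_gas_state(mesh, c0, u_insp = 0, u_exp = 0, cfg)
  st$c_ac <- c0[length(c0)]
  st <- apply_boundaries(st, "expiration")
  for (k in 1:100) st <- transport_step(st, 0.01)
  v0 <- sum(c0 * (pos - 100)^2) / sum(c0)
  cm <- sum(st$c * pos) / sum(st$c)
  v1 <- sum(st$c * (pos - cm)^2) / sum(st$c)
  expect_lt(abs((v1 - v0) - 2 * 22.5 * 1) / (2 * 22.5), 0.02)
  # diffusion conserves mass away from the boundaries
  expect_lt(abs(sum(st$c) - sum(c0)) / sum(c0), 1e-9)
})

test_that("pure advection displaces a front by u t within one node spacing", {
  tr <- straight_tree(200, 2)
  mesh <- discretize_tree(tr, 1)
  pos <- seq(0, 200, length.out = mesh$n_nodes)
  c0 <- as.numeric(pos < 50)
  cfg <- svi_config(transport = list(diffusion = FALSE))
  st <- airway_gas_state(mesh, c0, u_insp = 30, u_exp = 0, cfg)
  st <- apply_boundaries(st, "inspiration", fio2 = 1)
  half_cross <- function(cc) {
    i <- max(which(cc >= 0.5))
    pos[i] + (cc[i] - 0.5) / (cc[i] - cc[i + 1]) * diff(pos)[1]
  }
  f0 <- half_cross(c0)
  for (k in 1:40) st <- transport_step(st, 0.05)  # T = 2 s, 60 mm
  expect_lt(abs((half_cross(st$c) - f0) - 60), 1)
})

test_that("phase boundary conditions are imposed as stated", {
  mesh <- discretize_tree(straight_tree(), 2)
  st <- airway_gas_state(mesh, 0.21, u_insp = 50, u_exp = -50, svi_config())
  st <- apply_boundaries(st, "inspiration", fio2 = 1)
  expect_equal(st$c[mesh$root_node], 1)
  st$c_ac <- rep(0.37, length(mesh$term_nodes))
  st <- apply_boundaries(st, "expiration")
  expect_equal(unname(st$c[mesh$term_nodes]), rep(0.37, length(mesh$term_nodes)))
  expect_error(apply_boundaries(st, "inspiration", fio2 = 1.2), "FIO2")
})

test_that("acinar dilution bookkeeping follows the mixing identities", {
  # zero inflow, zero exchange: concentration constant
  upd <- acinar_volume_update(5, 0.3, 0, 0, 0.05)
  expect_equal(upd$f, 0.3)
  # inflow at equal concentration: concentration constant, volume grows
  upd <- acinar_volume_update(5, 0.3, 2, 2 * 0.05 * 0.3, 0.05)
  expect_equal(upd$f, 0.3)
  expect_equal(upd$V_mL, 5.1)
  # one breath of pure O2 into a unit with SV s (no uptake):
  # c' = c + s/(1+s) (c_in - c), the single-compartment mixing identity
  s <- 0.35; V0 <- 4; c <- 0.21
  dV <- s * V0
  upd <- acinar_volume_update(V0, c, dV, dV * 1.0, 1)
  expect_equal(upd$f, c + s / (1 + s) * (1 - c))
  expect_error(acinar_volume_update(1, 0.2, -2, 0, 1), "non-positive")
})

test_that("the O2 mass audit closes per breath on a full simulation", {
  fx <- tiny_fixture()
  # switch gravity off entirely so the bundle is fully homogeneous
  cfg <- fx$config
  cfg$perfusion$g_m_s2 <- 0
  vent <- solve_ventilation(fx$tree, fx$acini, cfg)
  perf <- solve_perfusion(fx$artery, fx$vein, fx$acini, cfg, fx$host,
                          gravity_model_from_config(cfg))
  sched <- make_schedule(cfg)[1:12, ]
  ser <- run_protocol(fx$tree, fx$acini, vent, perf, sched, cfg)
  expect_lt(max(ser$audits$o2_balance_rel), 0.005)
  # homogeneous lung: all acinar series identical
  expect_lt(max(abs(sweep(ser$PA, 2, ser$PA[1, ]))), 1e-6)
})

test_that("halving the transport step changes end-of-breath PA by < 0.2%", {
  fx <- tiny_fixture()
  vent <- solve_ventilation(fx$tree, fx$acini, fx$config)
  perf <- solve_perfusion(fx$artery, fx$vein, fx$acini, fx$config, fx$host,
                          gravity_model_from_config(fx$config))
  sched <- make_schedule(fx$config)[1:3, ]
  pa <- sapply(c(0.05, 0.025), function(dt) {
    cfg <- fx$config
    cfg$transport$dt_s <- dt
    ser <- run_protocol(fx$tree, fx$acini, vent, perf, sched, cfg)
    mean(ser$PA[, 3])
  })
  expect_lt(abs(pa[1] - pa[2]) / pa[2], 0.002)
})
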