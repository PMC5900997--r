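test_that("Poiseuille resistance follows 8 mu L / (pi r^4)", {
  rp <- poiseuille_resistance(10, 1, 1.8e-5)
  expect_equal(rp, 8 * 1.8e-5 * 10 / pi)
  expect_lt(abs(rp - 4.58e-4) / 4.58e-4, 0.005)
  expect_equal(poiseuille_resistance(20, 1, 1.8e-5), 2 * rp)
  expect_equal(poiseuille_resistance(10, 0.5, 1.8e-5), 16 * rp)
  expect_error(poiseuille_resistance(10, 0, 1.8e-5), "positive")
})

test_that("bifurcation correction has the Pedley form with a laminar floor", {
  expect_equal(bifurcation_factor(0, 2, 10), 1)
  expect_equal(bifurcation_factor(1e-9, 2, 10), 1)
  expect_equal(bifurcation_factor(1000, 1, 10, gamma = 0.327),
               0.327 * sqrt(100))
  re <- seq(0, 5000, by = 250)
  z <- bifurcation_factor(re, 2, 10)
  expect_true(all(diff(z) >= 0))
})

test_that("a symmetric Y tree splits tidal volume exactly in half", {
  fx <- y_fixture()
  vent <- solve_ventilation(fx$tree, fx$acini, fx$config)
  expect_lt(abs(diff(vent$acini$dVA_mL)) / vent$acini$dVA_mL[1], 1e-9)
  expect_equal(vent$tracheal_tidal_mL, 650)
  expect_lt(vent$audits$tidal_balance_rel, 0.001)
  expect_lt(vent$audits$junction_residual, 1e-8)
  expect_lt(vent$audits$cycle_drift, fx$config$ventilation$drift_tol)
})

test_that("unequal compliances match a two-unit RC oracle", {
  skip_if_not_installed("deSolve")
  fx <- y_fixture(c2 = 2)  # second acinus twice as compliant
  cfg <- fx$config
  cfg$ventilation$zpe_gamma <- 0  # pure Poiseuille for the closed oracle
  vent <- solve_ventilation(fx$tree, fx$acini, cfg)
  # oracle: constant tracheal inflow through fixed resistances into two
  # elastic units; junction pressure eliminated analytically
  mu <- cfg$ventilation$mu_air_Pa_s
  R <- poiseuille_resistance(fx$tree$length_mm, fx$tree$radius_mm, mu)[2:3]
  C <- fx$acini$C_mL_cmH2O * 1000 / 98.0665  # mm^3/Pa
  Pe <- fx$acini$Pe_cmH2O * 98.0665
  Ti <- 2.5
  Q <- 650 * 1000 / Ti
  deriv <- function(t, V, parms) {
    q_t <- if ((t %% 5) < Ti) Q else -Q
    Pel <- V / C - Pe
    Pj <- (q_t + sum(Pel / R)) / sum(1 / R)
    list((Pj - Pel) / R)
  }
  V0 <- fx$acini$V0_mL * 1000
  times <- seq(0, 40, by = 0.005)
  sol <- deSolve::ode(y = V0, times = times, func = deriv, parms = NULL)
  last_insp <- sol[times >= 35 & times <= 37.5, -1]
  dva_oracle <- (last_insp[nrow(last_insp), ] - last_insp[1, ]) / 1000
  expect_lt(max(abs(vent$acini$dVA_mL - dva_oracle) / dva_oracle), 0.005)
  # the doubly compliant unit takes more than half the tidal volume
  expect_gt(vent$acini$dVA_mL[2], sum(vent$acini$dVA_mL) / 2)
})

test_that("tidal volume is conserved to 0.1% on a grown lung", {
  cfg <- svi_config()
  host <- generate_host(cfg, 3)
  tree <- grow_airway_tree(host, 64, 3, cfg)
  ac <- place_acini(tree, host, cfg, 3)
  ac <- apply_gravity(ac, gravity_model_from_config(cfg), host)
  vent <- solve_ventilation(tree, ac, cfg)
  expect_lt(abs(sum(vent$acini$dVA_mL) +
                  vent$audits$dead_space_expansion_mL - 650) / 650, 0.001)
  expect_lt(vent$audits$junction_residual, 1e-8)
})

test_that("true SV is the tidal-to-FRC volume ratio", {
  expect_equal(true_sv(0, 5), 0)
  expect_equal(true_sv(0.193 * 7, 7), 0.193)
  expect_error(true_sv(1, 0), "positive")
  fx <- y_fixture()
  vent <- solve_ventilation(fx$tree, fx$acini, fx$config)
  expect_equal(true_sv(vent), vent$acini$dVA_mL / vent$acini$V0_mL)
})
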