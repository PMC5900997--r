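test_that("branch pressure drop combines Poiseuille and hydrostatic terms", {
  visc <- branch_pressure_drop(10, 2, 100, 3.36e-3, theta = pi / 2)
  expect_equal(visc, 128 * 3.36e-3 * 10 * 100 / (pi * 16))
  expect_lt(abs(visc - 8.56) / 8.56, 0.005)
  # vertical branch with no flow: pure hydrostatic column rho g L
  expect_equal(branch_pressure_drop(10, 2, 0, 3.36e-3, rho = 1060,
                                    g = 9.81, theta = 0),
               1060 * 9.81 * 0.010)
  expect_error(branch_pressure_drop(10, 0, 1, 3.36e-3), "positive")
})

test_that("the compliant tube law is linear in transmural pressure", {
  expect_equal(strained_diameter(3, 0, 1.49e-4), 3)
  expect_equal(strained_diameter(1, 2000, 1.49e-4), 1.298)
  p <- seq(-500, 3000, by = 500)
  expect_true(all(diff(strained_diameter(2, p, 1.49e-4)) > 0))
  expect_error(strained_diameter(2, -1e5, 1.49e-4), "collapse")
})

perf_fixture <- function(y_split = FALSE, ...) {
  cfg <- svi_config(mechanics = list(v0_gradient_per_cm = 0,
                                     pe_gradient_cmH2O_per_cm = 0,
                                     compliance_cv = 0), ...)
  host <- generate_host(cfg, 1)
  cx <- host$lungs$right$center[1]
  b <- if (y_split) {
    data.frame(id = 1:3, parent = c(0L, 1L, 1L),
               x0 = cx, y0 = c(0, 0, 0), z0 = c(60, 20, 20),
               x1 = cx, y1 = c(0, -25, 25), z1 = c(20, -20, -20),
               radius_mm = c(6, 4, 4))
  } else {
    data.frame(id = 1:3, parent = c(0L, 1L, 1L),
               x0 = cx, y0 = 0, z0 = c(60, 20, 20),
               x1 = c(cx, cx - 25, cx + 25), y1 = 0, z1 = c(20, -20, -20),
               radius_mm = c(6, 4, 4))
  }
  tree <- svi_tree(b, "airway")
  artery <- tree; attr(artery, "kind") <- "artery"
  vein <- tree; attr(vein, "kind") <- "vein"
  acini <- place_acini(tree, host, cfg, 1)
  acini <- apply_gravity(acini, gravity_model_from_config(cfg), host)
  list(host = host, artery = artery, vein = vein, acini = acini,
       config = cfg, gm = gravity_model_from_config(cfg))
}

test_that("a symmetric two-acinus network splits flow exactly in half", {
  fx <- perf_fixture()
  perf <- solve_perfusion(fx$artery, fx$vein, fx$acini, fx$config,
                          fx$host, fx$gm)
  expect_lt(abs(diff(perf$acini$Q_mm3_s)) / perf$acini$Q_mm3_s[1], 1e-9)
  expect_lt(perf$audits$junction_residual, 1e-8)
  expect_lt(perf$audits$flow_balance_rel, 0.001)
  expect_equal(perf$acini$transit_s,
               fx$acini$vb_mL * 1000 / perf$acini$Q_mm3_s)
})

test_that("gravity sends more flow to the dependent acinus", {
  fx <- perf_fixture(y_split = TRUE)
  perf <- solve_perfusion(fx$artery, fx$vein, fx$acini, fx$config,
                          fx$host, fx$gm)
  # acinus 1 is dorsal (y = -25), the dependent side when supine
  expect_gt(perf$acini$Q_mm3_s[1], perf$acini$Q_mm3_s[2])
  # two-path hand oracle: the dependent path sees a higher transmural
  # pressure, hence dilated vessels and capillary, hence lower resistance
  dP_tm <- 1060 * 9.81 * 0.050  # hydrostatic offset over 50 mm
  expect_gt(dP_tm, 0)
})

test_that("rigid vessels reduce to a single linear solve", {
  fx <- perf_fixture(perfusion = list(alpha_per_Pa = 0))
  perf <- solve_perfusion(fx$artery, fx$vein, fx$acini, fx$config,
                          fx$host, fx$gm)
  expect_identical(perf$iterations, 1L)
  expect_equal(perf$artery$D_mm, 2 * fx$artery$radius_mm)
  expect_lt(perf$audits$junction_residual, 1e-8)
})

test_that("ventilation-perfusion ratios are physiological on a grown lung", {
  cfg <- svi_config()
  host <- generate_host(cfg, 3)
  tree <- grow_airway_tree(host, 64, 3, cfg)
  vasc <- derive_vascular_trees(tree, cfg)
  ac <- place_acini(tree, host, cfg, 3)
  gm <- gravity_model_from_config(cfg)
  ac <- apply_gravity(ac, gm, host)
  vent <- solve_ventilation(tree, ac, cfg)
  perf <- solve_perfusion(vasc$artery, vasc$vein, ac, cfg, host, gm)
  va_q <- (vent$acini$dVA_mL / cfg$ventilation$breath_s) /
    (perf$acini$Q_mm3_s / 1000)
  expect_gt(mean(va_q), 0.8)
  expect_lt(mean(va_q), 1.2)
  # dependent flow exceeds nondependent flow overall
  h <- host_height_cm(host, cbind(ac$x, ac$y, ac$z))
  expect_lt(stats::cor(perf$acini$Q_mm3_s, h), 0)
})
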