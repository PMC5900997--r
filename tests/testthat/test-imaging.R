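test_that("the breathing schedule follows the five-cycle pattern", {
  s <- make_schedule()
  expect_identical(nrow(s), 220L)
  expect_true(all(s$fio2[1:20] == 0.21))
  expect_true(all(s$fio2[21:40] == 1.0))
  expect_true(all(s$fio2[181:220] == 1.0))  # final 40-breath O2 block
  blocks <- rle(s$fio2)
  expect_equal(blocks$lengths, c(rep(20L, 9), 40L))
  expect_equal(blocks$values, rep(c(0.21, 1.0), 5))
})

test_that("voxel fill fractions are geometric and bounded", {
  fx <- grid_fixture()
  v <- fx$grid$voxels
  expect_true(all(v$fill > 0 & v$fill <= 1))
  # deep interior voxels are fully filled
  cen <- fx$host$lungs$right$center
  inner <- which(abs(v$x - cen[1]) < 15 & abs(v$y - cen[2]) < 15 &
                   abs(v$z - cen[3]) < 15)
  expect_true(all(v$fill[inner] > 0.999))
})

test_that("the tissue partition conserves acinar volume", {
  fx <- grid_fixture()
  expect_lt(fx$grid$tissue_volume_audit, 0.005)
  W <- fx$grid$tissue_weights
  expect_equal(sum(W), sum(fx$acini$V0_mL) * 1000)
  # one acinus entirely inside the grid distributes exactly its volume
  expect_equal(unname(Matrix::colSums(W)), fx$acini$V0_mL * 1000)
})

test_that("an acinus straddling a voxel boundary splits its volume evenly", {
  fx <- grid_fixture()
  grid <- fx$grid
  # place a synthetic acinus centered exactly on an in-plane y boundary,
  # deep inside the right lung
  cen <- fx$host$lungs$right$center
  yb <- grid$yb[which.min(abs(grid$yb - cen[2]))]
  ac <- data.frame(id = 1L, branch_id = 1L,
                   x = cen[1], y = yb, z = cen[3],
                   V0_mL = 0.25, C_mL_cmH2O = 1, Pe_cmH2O = 0,
                   vt_mL = 0.1, vb_mL = 0.02, lung = "right")
  class(ac) <- c("svi_acini", "data.frame")
  g2 <- voxelize_tissue(ac, grid, fx$cfg)
  w <- g2$tissue_weights[, 1]
  lo <- sum(w[grid$voxels$y < yb])
  hi <- sum(w[grid$voxels$y > yb])
  expect_lt(abs(lo - hi) / (lo + hi), 0.06)
})

test_that("vein cylinders are rasterized at the printed point density", {
  fx <- grid_fixture()
  # a small branch fully inside the lung, at the printed 1e-3 mm^3/point
  cen <- fx$host$lungs$right$center
  vein <- svi_tree(data.frame(
    id = 1L, parent = 0L,
    x0 = cen[1] - 1.5, y0 = cen[2], z0 = cen[3],
    x1 = cen[1] + 1.5, y1 = cen[2], z1 = cen[3], radius_mm = 2
  ), "vein")
  perf <- list(vein = data.frame(id = 1L, Q_mm3_s = 10, D_mm = 4))
  cfg <- fx$cfg
  cfg$imaging$vein_point_volume_mm3 <- 1e-3
  g2 <- voxelize_veins(vein, perf, fx$grid, cfg)
  vol <- pi * 2^2 * 3
  expect_lt(g2$vein_volume_audit, 0.01)
  expect_lt(abs(sum(g2$vein_weights) - vol) / vol, 0.01)
  # zero-radius branch contributes nothing
  vein0 <- vein; vein0$radius_mm <- 1e-12
  perf0 <- list(vein = data.frame(id = 1L, Q_mm3_s = 10, D_mm = 0))
  g3 <- voxelize_veins(vein0, perf0, fx$grid, cfg)
  expect_equal(sum(g3$vein_weights), 0)
})

test_that("the fill filter drops voxels strictly below threshold", {
  grid <- list(voxels = data.frame(fill = c(1.0, 0.6, 0.3, 0.49, 0.50)),
               fill_threshold = 0.5)
  class(grid) <- "svi_voxel_grid"
  out <- apply_fill_filter(grid)
  expect_identical(out$voxels$retained, c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("the EELV series matches its stated moments and bounds", {
  e <- generate_eelv_series(n = 220, seed = 1)
  expect_identical(length(e), 220L)
  expect_true(all(abs(e) <= 0.40))
  expect_gt(mean(e), 0.07)
  expect_lt(mean(e), 0.11)
  expect_identical(e, generate_eelv_series(n = 220, seed = 1))
  es <- generate_eelv_series(n = 220, seed = 1, shuffle = TRUE)
  expect_identical(sort(es), sort(e))
  expect_false(identical(es, e))
})

test_that("zero EELV change leaves the imaged signal rank-identical", {
  fx <- grid_fixture()
  nb <- 10L
  sched <- make_schedule(fx$cfg)[1:nb, ]
  sig <- inert_response(seq(0.1, 0.6, length.out = nrow(fx$acini)), sched) *
    fx$acini$V0_mL * 1000
  mis <- simulate_misalignment(fx$acini, sig, fx$grid, rep(0, nb), fx$cfg)
  ids <- which(mis$valid_frac >= 1 & fx$grid$voxels$fill > 0.999)
  ref <- voxel_tissue_series(fx$grid, sig)[ids, ]
  got <- mis$series[ids, ]
  # identical deformation: every voxel's series is a fixed rescaling of
  # the aligned series (weighted mean versus weighted sum)
  r <- got / ref
  expect_lt(max(apply(r, 1, function(x) diff(range(x)) / mean(x))), 0.05)
  expect_equal(mis$achieved, rep(0, nb))
})

test_that("a prescribed EELV change is reached within tolerance", {
  fx <- grid_fixture()
  sig <- matrix(1, nrow(fx$acini), 1)
  mis <- simulate_misalignment(fx$acini, sig, fx$grid, 0.20, fx$cfg)
  expect_gte(mis$achieved[1], 0.18)
  expect_lte(mis$achieved[1], 0.22)
  expect_error(
    simulate_misalignment(fx$acini, sig, fx$grid, c(0.1, 0.2), fx$cfg),
    "length")
})
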