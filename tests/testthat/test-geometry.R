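test_that("host volume matches the FRC target and is reproducible", {
  for (frc in c(2.64, 3.62)) {
    host <- generate_host(svi_config(frc_L = frc), seed = 3)
    expect_lt(abs(host_volume(host) - frc * 1000) / (frc * 1000), 0.01)
  }
  h1 <- generate_host(svi_config(), 5)
  h2 <- generate_host(svi_config(), 5)
  expect_identical(h1, h2)
  expect_error(generate_host(svi_config(frc_L = -1)), "positive")
  bad <- svi_config()
  bad$host$right_semiaxes_mm[1] <- -3
  expect_error(generate_host(bad), "positive")
})

test_that("lungs are disjoint and contain their sample points", {
  host <- generate_host(svi_config(), 1)
  pr <- sample_lung_points(host, "right", 200, 11)
  pl <- sample_lung_points(host, "left", 200, 12)
  expect_true(all(host_lung_of(host, pr) == 1L))
  expect_true(all(host_lung_of(host, pl) == 2L))
  # midline gap separates the lungs
  expect_identical(host_lung_of(host, matrix(c(0, 0, 0), 1)), 0L)
})

test_that("volume-filling growth yields the requested terminals, inside the host", {
  cfg <- svi_config()
  host <- generate_host(cfg, 2)
  tree <- grow_airway_tree(host, 120, 2, cfg)
  term <- tree[tree$terminal, ]
  expect_identical(nrow(term), 120L)
  expect_true(all(host_contains(host, cbind(term$x1, term$y1, term$z1))))
  expect_true(all(tree$length_mm > 0))
  expect_true(all(tree$radius_mm > 0))
  expect_identical(sum(tree$parent == 0L), 1L)
  # parents-first storage implies connected and acyclic
  idx <- match(tree$parent, tree$id)
  kids <- which(tree$parent != 0L)
  expect_true(all(idx[kids] < kids))
  # same seed reproduces the tree exactly
  tree2 <- grow_airway_tree(host, 120, 2, cfg)
  expect_identical(tree, tree2)
})

test_that("terminal counts are space-filling across octants", {
  cfg <- svi_config()
  host <- generate_host(cfg, 4)
  tree <- grow_airway_tree(host, 400, 4, cfg)
  term <- tree[tree$terminal & tree$lung == "right", ]
  cen <- host$lungs$right$center
  oct <- paste(term$x1 > cen[1], term$y1 > cen[2], term$z1 > cen[3])
  cnt <- as.numeric(table(oct))
  expect_identical(length(cnt), 8L)
  expect_lt(stats::sd(cnt) / mean(cnt), 0.25)
})

test_that("over-packing the host is rejected with the limit named", {
  cfg <- svi_config()
  cfg$tree$min_length_mm <- 30
  host <- generate_host(cfg, 1)
  expect_error(grow_airway_tree(host, 480, 1, cfg), "packing capacity")
})

test_that("vascular trees share the airway centerlines with their own diameters", {
  cfg <- svi_config()
  host <- generate_host(cfg, 1)
  tree <- grow_airway_tree(host, 64, 1, cfg)
  vasc <- derive_vascular_trees(tree, cfg)
  for (tr in vasc) {
    expect_identical(tr$x1, tree$x1)
    expect_identical(tr$z0, tree$z0)
    expect_identical(sum(tr$terminal), sum(tree$terminal))
  }
  expect_equal(vasc$vein$radius_mm, vasc$artery$radius_mm * 1.2)
  # degenerate ratio 1 gives uniform diameters at the root value
  expect_equal(diameter_by_order(c(1, 3, 5), 18, 1), rep(18, 3))
  # Horsfield geometric rule: 5 orders at ratio 1.15 span 1.15^4
  d <- diameter_by_order(1:5, 20, 1.15)
  expect_equal(d[5] / d[1], 1.15^4)
  expect_error(diameter_by_order(1:30, 1e-9 * 0, 1.15), "positive")
})

test_that("acini sit on terminal ends and tile the FRC volume with dead space", {
  cfg <- svi_config()
  host <- generate_host(cfg, 1)
  tree <- grow_airway_tree(host, 64, 1, cfg)
  ac <- place_acini(tree, host, cfg, 1)
  term <- tree[tree$terminal, ]
  expect_identical(nrow(ac), 64L)
  expect_identical(ac$x, term$x1)
  expect_identical(ac$z, term$z1)
  total <- sum(ac$V0_mL) + attr(ac, "dead_space_mL")
  expect_lt(abs(total - host$frc_mL) / host$frc_mL, 0.01)
  expect_equal(dead_space_mL(tree),
               sum(pi * tree$radius_mm^2 * tree$length_mm) / 1000)
})
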