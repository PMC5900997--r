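# shared fixtures, built once per test session and cached

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

tiny_fixture <- function() memo("tiny", make_fixture("tiny", seed = 1L))

# a straight single-branch "tree" for 1D transport oracles
straight_tree <- function(length_mm = 200, radius_mm = 2) {
  svi_tree(data.frame(
    id = 1L, parent = 0L,
    x0 = 0, y0 = 0, z0 = 0, x1 = length_mm, y1 = 0, z1 = 0,
    radius_mm = radius_mm
  ), "airway")
}

# mirror-symmetric two-acinus Y tree inside the right lung of the default
# host, with uniform acini
y_fixture <- function(c2 = NULL) {
  cfg <- svi_config(mechanics = list(v0_gradient_per_cm = 0,
                                     pe_gradient_cmH2O_per_cm = 0,
                                     compliance_cv = 0))
  host <- generate_host(cfg, 1)
  cx <- host$lungs$right$center[1]
  b <- data.frame(
    id = 1:3, parent = c(0L, 1L, 1L),
    x0 = c(cx, cx, cx), y0 = c(0, 0, 0), z0 = c(60, 20, 20),
    x1 = c(cx, cx - 25, cx + 25), y1 = c(0, 0, 0), z1 = c(20, -20, -20),
    radius_mm = c(6, 4, 4)
  )
  tree <- svi_tree(b, "airway")
  acini <- place_acini(tree, host, cfg, 1)
  acini <- apply_gravity(acini, gravity_model_from_config(cfg), host)
  if (!is.null(c2)) acini$C_mL_cmH2O[2] <- c2 * acini$C_mL_cmH2O[2]
  list(host = host, tree = tree, acini = acini, config = cfg)
}

# minimal venous tree + perfusion stub for propagation tests:
# chain root(1) <- mid(2) <- two terminals (3, 4)
venous_chain <- function(Q = c(100, 100, 60, 40), L = c(10, 10, 10, 10),
                         D = c(4, 4, 3, 3)) {
  vein <- svi_tree(data.frame(
    id = 1:4, parent = c(0L, 1L, 2L, 2L),
    x0 = c(0, 0, 0, 0), y0 = c(0, 0, 0, 0), z0 = c(30, 20, 10, 10),
    x1 = c(0, 0, -5, 5), y1 = c(0, 0, 0, 0), z1 = c(20, 10, 0, 0),
    radius_mm = D / 2, length_mm = L
  ), "vein")
  perf <- list(vein = data.frame(id = 1:4, Q_mm3_s = Q, D_mm = D))
  list(vein = vein, perf = perf)
}

# a 64-acinus lung with its voxel grid, for imaging-side tests
grid_fixture <- function() memo("grid64", {
  cfg <- svi_config(n_terminals = 64)
  host <- generate_host(cfg, 6)
  tree <- grow_airway_tree(host, 64, 6, cfg)
  vasc <- derive_vascular_trees(tree, cfg)
  ac <- place_acini(tree, host, cfg, 6)
  gm <- gravity_model_from_config(cfg)
  ac <- apply_gravity(ac, gm, host)
  perf <- solve_perfusion(vasc$artery, vasc$vein, ac, cfg, host, gm)
  grid <- make_voxel_grid(host, cfg)
  grid <- voxelize_tissue(ac, grid, cfg)
  grid <- voxelize_veins(vasc$vein, perf, grid, cfg)
  grid <- apply_fill_filter(grid)
  list(cfg = cfg, host = host, tree = tree, vein = vasc$vein, acini = ac,
       perf = perf, grid = grid)
})

# the seeded default experiment shared by the integration and acceptance
# tests (expensive: computed once)
default_run <- function() memo("default_run",
                               svi_experiment(svi_config(), seed = 1L))
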