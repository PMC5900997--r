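#' Run a complete virtual SVI experiment
#'
#' End-to-end pipeline: synthetic lung generation (host, airway tree,
#' matched vascular trees, acini with the gravitational FRC distribution),
#' tidal ventilation and steady-state perfusion solves, the 220-breath
#' air/O2 protocol with airway transport and gas exchange, venous
#' propagation, voxelization of tissue and venous signal on the MR grid,
#' response-curve SV inference, and the three virtual experiments
#' (mid-slice versus whole lung, venous contribution, image misalignment).
#' All stochastic stages are fanned out from one master seed.
#'
#' @param config an [svi_config()].
#' @param seed master integer seed.
#' @param run_whole_lung infer SV for every lung voxel (else mid-slice
#'   only).
#' @param run_misalignment run the misalignment experiment on the
#'   mid-sagittal slice.
#' @param progress print stage messages.
#' @return an `svi_run` list: all intermediate model objects, voxel maps,
#'   inference tables, per-scenario [gravitational_summary()] rows in
#'   `$summaries`, the comparison table in `$comparison`, and conservation
#'   audits in `$audits`.
#' @export
svi_experiment <- function(config = svi_config(), seed = 1L,
                           run_whole_lung = TRUE, run_misalignment = TRUE,
                           progress = FALSE) {
  say <- function(...) if (progress) message(...)
  seed <- as.integer(seed)

  say("generating lung geometry")
  host <- generate_host(config, seed)
  tree <- grow_airway_tree(host, config$n_terminals, seed, config)
  vasc <- derive_vascular_trees(tree, config)
  gm <- gravity_model_from_config(config)
  acini <- place_acini(tree, host, config, seed)
  acini <- apply_gravity(acini, gm, host)

  say("solving ventilation")
  vent <- solve_ventilation(tree, acini, config)
  say("solving perfusion")
  perf <- solve_perfusion(vasc$artery, vasc$vein, acini, config, host, gm)

  say("running the breathing protocol")
  schedule <- make_schedule(config)
  series <- run_protocol(tree, acini, vent, perf, schedule, config,
                         progress = progress)
  venous <- propagate_venous(vasc$vein, series$Pc, perf,
                             config$ventilation$breath_s)

  say("voxelizing")
  grid <- make_voxel_grid(host, config)
  grid <- voxelize_tissue(acini, grid, config)
  grid <- voxelize_veins(vasc$vein, perf, grid, config)
  grid <- apply_fill_filter(grid)
  tissue_vox <- voxel_tissue_series(grid, series$tissue_signal)
  venous_vox <- voxel_venous_series(grid, venous, config)
  combined_vox <- tissue_vox + venous_vox

  say("inferring SV")
  library <- build_library(schedule, config)
  sv_true_ac <- true_sv(vent)
  wsum <- Matrix::rowSums(grid$tissue_weights)
  sv_true_vox <- as.numeric(grid$tissue_weights %*% sv_true_ac) /
    ifelse(wsum > 0, wsum, 1)
  retained <- grid$voxels$retained & wsum > 0
  h_vox <- grid$voxels$height_cm

  slices_r <- extract_slices(grid, "right")
  mid_ids <- slices_r$slices[[slices_r$mid]]
  infer_ids <- if (run_whole_lung) which(retained) else
    intersect(mid_ids, which(retained))
  alpha <- config$inference$alpha
  inf_tissue <- infer_sv(tissue_vox[infer_ids, , drop = FALSE], library, alpha)
  inf_comb <- infer_sv(combined_vox[infer_ids, , drop = FALSE], library, alpha)
  sv_map_tissue <- rep(NA_real_, nrow(grid$voxels))
  sv_map_comb <- rep(NA_real_, nrow(grid$voxels))
  sv_map_tissue[infer_ids] <- inf_tissue$sv
  sv_map_comb[infer_ids] <- inf_comb$sv

  sec <- config$analysis$section_mm
  summaries <- list()
  if (run_whole_lung) {
    summaries$true_sv_whole <- gravitational_summary(
      sv_true_vox[retained], h_vox[retained], sec)
    summaries$svi_whole <- gravitational_summary(
      sv_map_comb[retained], h_vox[retained], sec)
    summaries$svi_tissue_whole <- gravitational_summary(
      sv_map_tissue[retained], h_vox[retained], sec)
  }
  mid_ret <- intersect(mid_ids, which(retained))
  summaries$true_sv_mid <- gravitational_summary(
    sv_true_vox[mid_ret], h_vox[mid_ret], sec)
  summaries$svi_mid <- gravitational_summary(
    sv_map_comb[mid_ret], h_vox[mid_ret], sec)
  summaries$svi_tissue_mid <- gravitational_summary(
    sv_map_tissue[mid_ret], h_vox[mid_ret], sec)

  mis <- NULL
  if (run_misalignment) {
    say("simulating misalignment")
    slab_ix <- slices_r$slab_index[slices_r$mid]
    slab_lo <- grid$xb[slab_ix]; slab_hi <- grid$xb[slab_ix + 1]
    r_ac <- (3 * acini$V0_mL * 1000 / (4 * pi))^(1 / 3)
    in_slab <- acini$x + r_ac > slab_lo & acini$x - r_ac < slab_hi
    vr <- pmax(vasc$vein$radius_mm, perf$vein$D_mm / 2)
    vein_in <- pmin(vasc$vein$x0, vasc$vein$x1) - vr < slab_hi &
      pmax(vasc$vein$x0, vasc$vein$x1) + vr > slab_lo
    eelv <- generate_eelv_series(
      n = nrow(schedule),
      mean = config$misalignment$eelv_mean,
      sd = config$misalignment$eelv_sd,
      max = config$misalignment$eelv_max,
      seed = seed + 11L)
    vein_sub <- vasc$vein[vein_in, , drop = FALSE]
    perf_sub <- perf
    perf_sub$vein <- perf$vein[vein_in, , drop = FALSE]
    venous_sub <- venous
    venous_sub$series <- venous$series[vein_in, , drop = FALSE]
    mis <- simulate_misalignment(
      acini[in_slab, , drop = FALSE],
      series$tissue_signal[in_slab, , drop = FALSE],
      grid, eelv, config,
      vein = vein_sub, perf = perf_sub, venous = venous_sub)
    # analyse only voxels that hold lung in every image (voxels that empty
    # intermittently sit at the moving diaphragm boundary) and whose imaged
    # composition is stable (voxels a large vein slides in and out of have
    # no single response curve at this model granularity)
    mis_ids <- mid_ret[mis$valid_frac[mid_ret] >= 1 &
                         mis$vein_frac_range[mid_ret] <= 0.2]
    inf_mis <- infer_sv(mis$series[mis_ids, , drop = FALSE], library, alpha)
    mis$sv <- inf_mis$sv
    mis$voxel_ids <- mis_ids
    mis$eelv <- eelv
    mis$sv_aligned_same_voxels <- sv_map_comb[mis_ids]
    summaries$svi_mid_misaligned <- gravitational_summary(
      inf_mis$sv, h_vox[mis_ids], sec)
    summaries$svi_mid_aligned_common <- gravitational_summary(
      sv_map_comb[mis_ids], h_vox[mis_ids], sec)
  }

  comparison <- compare_experiments(summaries)

  # venous localization: voxels crossed by the largest veins
  big <- which(perf$vein$D_mm >= stats::quantile(perf$vein$D_mm, 0.75))
  crossed <- Matrix::rowSums(grid$vein_weights[, big, drop = FALSE]) > 0

  out <- list(
    config = config, seed = seed,
    host = host, tree = tree, artery = vasc$artery, vein = vasc$vein,
    acini = acini, vent = vent, perf = perf,
    schedule = schedule, series = series, venous = venous,
    grid = grid, library = library,
    voxel = list(
      tissue_series = tissue_vox, venous_series = venous_vox,
      combined_series = combined_vox,
      sv_true = sv_true_vox, sv_tissue = sv_map_tissue,
      sv_combined = sv_map_comb,
      retained = retained, height_cm = h_vox,
      mid_slice_ids = mid_ids, infer_ids = infer_ids,
      vein_crossed = crossed,
      discard_rate = mean(inf_comb$discarded)
    ),
    inference = list(tissue = inf_tissue, combined = inf_comb),
    misalignment = mis,
    summaries = summaries,
    comparison = comparison,
    audits = list(
      ventilation = vent$audits,
      perfusion = perf$audits,
      o2_balance_rel = series$audits$o2_balance_rel,
      tissue_volume = grid$tissue_volume_audit,
      vein_volume = grid$vein_volume_audit
    )
  )
  class(out) <- "svi_run"
  out
}

#' @export
print.svi_run <- function(x, ...) {
  cat("<svi_run> seed ", x$seed, ", ", nrow(x$acini), " acini, ",
      sum(x$voxel$retained), " retained voxels\n", sep = "")
  print(x$comparison)
  invisible(x)
}

#' Deterministic model fixtures
#'
#' `"tiny"` builds a hand-made mirror-symmetric 8-terminal tree inside the
#' right lung with uniform acini (no gravity, no compliance variability):
#' every acinus receives the same tidal share, which makes symmetry
#' properties exact. `"small"` generates the default 500-terminal synthetic
#' lung used by the integration runs.
#'
#' @param size `"tiny"` or `"small"`.
#' @param seed integer seed.
#' @param config base configuration (overridden as needed per fixture).
#' @return list with `host`, `tree`, `artery`, `vein`, `acini`, `config`.
#' @export
make_fixture <- function(size = c("tiny", "small"), seed = 1L,
                         config = svi_config()) {
  size <- match.arg(size)
  if (size == "small") {
    host <- generate_host(config, seed)
    tree <- grow_airway_tree(host, config$n_terminals, seed, config)
    vasc <- derive_vascular_trees(tree, config)
    acini <- place_acini(tree, host, config, seed)
    acini <- apply_gravity(acini, gravity_model_from_config(config), host)
    return(list(host = host, tree = tree, artery = vasc$artery,
                vein = vasc$vein, acini = acini, config = config))
  }
  config <- merge_config(config, list(
    mechanics = list(v0_gradient_per_cm = 0, pe_gradient_cmH2O_per_cm = 0,
                     compliance_cv = 0)))
  class(config) <- "svi_config"
  host <- generate_host(config, seed)
  cx <- host$lungs$right$center[1]
  rows <- list()
  add <- function(parent, p0, p1)
    rows[[length(rows) + 1]] <<- data.frame(
      id = length(rows) + 1L, parent = parent,
      x0 = p0[1], y0 = p0[2], z0 = p0[3],
      x1 = p1[1], y1 = p1[2], z1 = p1[3])
  add(0L, c(cx, 0, 70), c(cx, 0, 40))
  add(1L, c(cx, 0, 40), c(cx - 20, 0, 20))
  add(1L, c(cx, 0, 40), c(cx + 20, 0, 20))
  for (i in 1:2) {
    px <- c(cx - 20, cx + 20)[i]
    for (sy in c(-1, 1)) {
      add(i + 1L, c(px, 0, 20), c(px, sy * 20, 0))
      p2 <- length(rows)
      for (sx in c(-1, 1))
        add(p2, c(px, sy * 20, 0), c(px + sx * 10, sy * 20, -25))
    }
  }
  b <- do.call(rbind, rows)
  ord <- strahler_order(b)
  b$radius_mm <- diameter_by_order(ord, 10, 1.3) / 2
  b$lung <- c(NA, rep("right", nrow(b) - 1))
  tree <- svi_tree(b, "airway")
  artery <- tree; attr(artery, "kind") <- "artery"
  artery$radius_mm <- diameter_by_order(ord, 12, 1.3) / 2
  vein <- artery; attr(vein, "kind") <- "vein"
  vein$radius_mm <- artery$radius_mm * config$tree$vein_artery_ratio
  acini <- place_acini(tree, host, config, seed)
  acini <- apply_gravity(acini, gravity_model_from_config(config), host)
  list(host = host, tree = tree, artery = artery, vein = vein,
       acini = acini, config = config)
}
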