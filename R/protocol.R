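#' The alternating air / 100% O2 breathing schedule
#'
#' Five cycles of 20 room-air breaths followed by 20 breaths of 100% O2,
#' with an additional 20 O2 breaths appended to the final cycle: 220
#' breaths in total, one image per breath.
#'
#' @param config an [svi_config()] (group `protocol`).
#' @return data frame with `breath` and `fio2`.
#' @export
make_schedule <- function(config = svi_config()) {
  p <- config$protocol
  fio2 <- c(rep(c(rep(p$fio2_air, p$breaths_per_block),
                  rep(p$fio2_o2, p$breaths_per_block)), p$n_cycles),
            rep(p$fio2_o2, p$extra_o2_breaths))
  data.frame(breath = seq_along(fio2), fio2 = fio2)
}

#' Run the SVI breathing protocol through the physiological model
#'
#' Integrates airway O2 transport and acinar gas exchange breath by breath
#' under the inspired-gas schedule, with the time-invariant per-breath
#' ventilation and perfusion supplied by the flow solvers. At the end of
#' every breath the alveolar, tissue and end-capillary PO2 of each acinus
#' are recorded; the end-capillary series can subsequently be propagated
#' through the venous tree with [propagate_venous()].
#'
#' @param tree airway `svi_tree`.
#' @param acini `svi_acini` (after [apply_gravity()]).
#' @param vent `svi_ventilation`.
#' @param perf `svi_perfusion`.
#' @param schedule from [make_schedule()] (any length).
#' @param config an [svi_config()].
#' @param progress print a line every 20 breaths.
#' @return object of class `svi_breath_series`: matrices (acini x breaths)
#'   `PA`, `Pt`, `Pc` (mmHg), the per-acinus tissue signal (compartment
#'   volume x solubility x PO2 summed over alveolar gas, tissue and
#'   capillary blood), and a per-breath O2 mass-balance audit.
#' @export
run_protocol <- function(tree, acini, vent, perf,
                         schedule = make_schedule(config),
                         config = svi_config(), progress = FALSE) {
  tp <- config$transport
  gas <- config$gas
  mesh <- discretize_tree(tree, tp$node_spacing_mm, tp$coarsen_by_radius)
  na <- nrow(acini)
  nb_breaths <- nrow(schedule)

  st <- airway_gas_state(mesh, 0.21, vent$u_insp_mm_s, vent$u_exp_mm_s, config)
  ops <- list(
    inspiration = build_advection(mesh, vent$u_insp_mm_s, tp$cfl),
    expiration = build_advection(mesh, vent$u_exp_mm_s, tp$cfl)
  )
  dops <- list(inspiration = NULL, expiration = NULL)
  if (tp$diffusion) {
    # conservative variant: the advective coupling already carries the
    # acinar concentration into the terminals each sub-step
    dops$inspiration <- build_diffusion(mesh, vent$u_insp_mm_s, tp$dt_s,
                                        gas$D_mm2_s, tp$peclet_cutoff,
                                        dirichlet = FALSE)
    dops$expiration <- build_diffusion(mesh, vent$u_exp_mm_s, tp$dt_s,
                                       gas$D_mm2_s, tp$peclet_cutoff,
                                       dirichlet = FALSE)
  }

  dry_P <- gas$dry_pressure_mmHg
  idx <- match(acini$branch_id, tree$id)
  Q_ac_i <- vent$branch_flow_insp_mm3_s[idx] / 1000   # mL/s, > 0
  Q_ac_e <- vent$branch_flow_exp_mm3_s[idx] / 1000    # mL/s, < 0
  ni <- max(1L, round(vent$Ti_s / tp$dt_s))
  ne <- max(1L, round(vent$Te_s / tp$dt_s))
  dti <- vent$Ti_s / ni
  dte <- vent$Te_s / ne

  sim <- list(
    st = st,
    V = acini$V0_mL,
    f = rep(0.15, na),            # near room-air alveolar fraction
    Pt = rep(0.13 * dry_P, na),
    Pc = rep(0.13 * dry_P, na)
  )
  transit <- perf$acini$transit_s
  vb <- acini$vb_mL
  vt <- acini$vt_mL
  T_ta <- gas$T_ta_lung_mmol_mmHg_s * vt / sum(vt)
  T_b <- gas$T_b_lung_mmol_mmHg_s * vb / sum(vb)
  nsub <- tp$transit_substeps

  one_phase <- function(sim, phase, fio2, nstep, dt_phase, Q_ac) {
    sim$st$phase <- phase
    sim$st$fio2 <- fio2
    sim$st$ops <- ops[[phase]]
    sim$st$diff_ops <- dops[[phase]]
    uptake <- 0; inflow <- 0; outflow <- 0
    for (k in seq_len(nstep)) {
      sim$st$c_ac <- sim$f
      sim$st <- advance_transport(sim$st, dt_phase)
      o2_in <- if (phase == "inspiration")
        sim$st$flux$to_acini_mm3 / 1000 else 0
      upd <- acinar_volume_update(sim$V, sim$f, Q_ac, o2_in, dt_phase)
      sim$V <- upd$V_mL
      sim$f <- upd$f
      ex <- exchange_step(sim$Pt, sim$f * dry_P, transit, vb, vt,
                          T_ta, T_b, dt_phase, gas, nsub)
      sim$Pt <- ex$Pt
      sim$Pc <- ex$Pc
      sim$f <- pmax(0, sim$f - ex$uptake_mmol_s / gas$gas_mmol_per_mL *
                      dt_phase / sim$V)
      uptake <- uptake + sum(ex$uptake_mmol_s) / gas$gas_mmol_per_mL * dt_phase
      inflow <- inflow + sim$st$flux$inlet_in_mm3 / 1000
      outflow <- outflow + sim$st$flux$inlet_out_mm3 / 1000
    }
    sim$phase_fluxes <- c(uptake = uptake, inflow = inflow, outflow = outflow)
    sim
  }

  PA_rec <- matrix(NA_real_, na, nb_breaths)
  Pt_rec <- matrix(NA_real_, na, nb_breaths)
  Pc_rec <- matrix(NA_real_, na, nb_breaths)
  audit_rel <- numeric(nb_breaths)

  warm <- config$protocol$warmup_breaths
  for (bi in seq_len(warm + nb_breaths)) {
    rec <- bi > warm
    fio2 <- if (rec) schedule$fio2[bi - warm] else config$protocol$fio2_air
    m0 <- tree_o2_mL(sim$st) + sum(sim$V * sim$f)
    sim$st$c[mesh$root_node] <- fio2
    sim <- one_phase(sim, "inspiration", fio2, ni, dti, Q_ac_i)
    fx1 <- sim$phase_fluxes
    sim$st$c[mesh$term_nodes] <- sim$f
    sim <- one_phase(sim, "expiration", fio2, ne, dte, Q_ac_e)
    fx2 <- sim$phase_fluxes
    m1 <- tree_o2_mL(sim$st) + sum(sim$V * sim$f)
    expected <- m0 + fx1[["inflow"]] + fx2[["inflow"]] -
      fx1[["outflow"]] - fx2[["outflow"]] - fx1[["uptake"]] - fx2[["uptake"]]
    if (rec) {
      k <- bi - warm
      audit_rel[k] <- abs(m1 - expected) / max(m1, 1e-9)
      PA_rec[, k] <- sim$f * dry_P
      Pt_rec[, k] <- sim$Pt
      Pc_rec[, k] <- sim$Pc
      if (progress && k %% 20 == 0)
        message("breath ", k, "/", nb_breaths, ": mean PA ",
                round(mean(PA_rec[, k]), 1), " mmHg")
    }
  }

  # proton-MR signal arises from water, so the O2-sensitive part is the
  # dissolved O2 in tissue water and capillary blood; alveolar gas carries
  # no protons and enters only through the tissue PO2 it sets
  sig <- gas$sigma_O2_mmol_L_mmHg / 1000 * (vt * Pt_rec + vb * Pc_rec)
  out <- list(
    PA = PA_rec, Pt = Pt_rec, Pc = Pc_rec,
    tissue_signal = sig,
    schedule = schedule,
    audits = list(o2_balance_rel = audit_rel),
    breath_s = config$ventilation$breath_s
  )
  class(out) <- "svi_breath_series"
  out
}

#' @export
print.svi_breath_series <- function(x, ...) {
  cat("<svi_breath_series> ", nrow(x$PA), " acini x ", ncol(x$PA),
      " breaths, worst O2 balance ",
      signif(max(x$audits$o2_balance_rel), 2), "\n", sep = "")
  invisible(x)
}
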