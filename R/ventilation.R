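CMH2O_PA <- 98.0665

#' Poiseuille resistance of a cylindrical branch
#'
#' `R = 8 mu L / (pi r^4)` with length and radius in mm, viscosity in Pa s,
#' giving resistance in Pa s per mm^3 (pressure in Pa, flow in mm^3/s).
#'
#' @param length_mm branch length (mm).
#' @param radius_mm branch radius (mm).
#' @param mu dynamic viscosity (Pa s).
#' @export
poiseuille_resistance <- function(length_mm, radius_mm, mu) {
  if (any(radius_mm <= 0)) stop("radius must be positive", call. = FALSE)
  if (any(length_mm <= 0)) stop("length must be positive", call. = FALSE)
  8 * mu * length_mm / (pi * radius_mm^4)
}

#' Reynolds number of flow in a branch
#' @param flow_mm3_s volumetric flow (mm^3/s).
#' @param radius_mm branch radius (mm).
#' @param rho fluid density (kg/m^3).
#' @param mu dynamic viscosity (Pa s).
#' @export
reynolds_number <- function(flow_mm3_s, radius_mm, rho, mu) {
  u_m_s <- abs(flow_mm3_s) / (pi * radius_mm^2) / 1000
  rho * u_m_s * (2 * radius_mm / 1000) / mu
}

#' Bifurcation energy-dissipation correction factor
#'
#' Pedley-type correction multiplying the Poiseuille resistance:
#' `Zpe = max(1, gamma * sqrt(Re * D / L))`. Reduces to 1 in the laminar
#' low-Reynolds limit and grows with the square root of the Reynolds
#' number.
#'
#' @param reynolds Reynolds number (dimensionless).
#' @param diameter_mm,length_mm branch geometry (mm).
#' @param gamma correction coefficient (default 0.327).
#' @export
bifurcation_factor <- function(reynolds, diameter_mm, length_mm,
                               gamma = 0.327) {
  pmax(1, gamma * sqrt(pmax(0, reynolds) * diameter_mm / length_mm))
}

#' Solve tidal ventilation on the conducting tree with elastic acini
#'
#' Time-steps a square-wave tidal breath (constant inspiratory and
#' expiratory tracheal flow derived from tidal volume, breath duration and
#' I:E ratio) through the rigid conducting airway network. Each branch
#' carries a Poiseuille resistance with a Pedley-type bifurcation
#' correction; each terminal branch feeds an elastic acinus whose pressure
#' is `Va/C - Pe`, coupled semi-implicitly so each time step is one sparse
#' SPD solve with flow conserved exactly at every junction. Breaths are
#' repeated until the per-acinus tidal volumes are cycle-converged.
#'
#' @param tree airway `svi_tree`.
#' @param acini `svi_acini` (after [apply_gravity()]).
#' @param config an [svi_config()].
#' @return object of class `svi_ventilation`: per-acinus `dVA_mL`, `V0_mL`
#'   and `SV`; per-branch phase-averaged flows and air velocities; the
#'   tracheal waveform; and conservation audits.
#' @export
solve_ventilation <- function(tree, acini, config = svi_config()) {
  vt <- config$ventilation
  nb <- nrow(tree)
  n_nodes <- nb + 1L
  start_node <- ifelse(tree$parent == 0L, 1L, tree$parent + 1L)
  end_node <- tree$id + 1L

  term_rows <- which(tree$terminal)
  if (!all(acini$branch_id == tree$id[term_rows]))
    stop("acini do not match the terminal branches of the tree", call. = FALSE)
  term_nodes <- end_node[term_rows]
  na <- nrow(acini)

  Ti <- vt$breath_s * vt$ie_ratio / (1 + vt$ie_ratio)
  Te <- vt$breath_s - Ti
  Q_in <- vt$tidal_volume_mL * 1000 / Ti       # mm^3/s square wave
  Q_ex <- vt$tidal_volume_mL * 1000 / Te
  dt <- vt$dt_s
  ni <- max(1L, round(Ti / dt))
  ne <- max(1L, round(Te / dt))
  dti <- Ti / ni
  dte <- Te / ne

  C_mm3_Pa <- acini$C_mL_cmH2O * 1000 / CMH2O_PA
  Pe_Pa <- acini$Pe_cmH2O * CMH2O_PA
  Rp <- poiseuille_resistance(tree$length_mm, tree$radius_mm, vt$mu_air_Pa_s)

  laplacian <- function(g) {
    i <- c(start_node, end_node, start_node, end_node)
    j <- c(end_node, start_node, start_node, end_node)
    x <- c(-g, -g, g, g)
    Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_nodes, n_nodes))
  }

  make_system <- function(g, dt_phase) {
    A <- laplacian(g)
    diag_add <- numeric(n_nodes)
    diag_add[term_nodes] <- C_mm3_Pa / dt_phase
    A <- A + Matrix::Diagonal(n_nodes, diag_add)
    Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  }

  step_phase <- function(ch, g, Va, Q_bc, dt_phase) {
    b <- numeric(n_nodes)
    b[1] <- Q_bc
    b[term_nodes] <- b[term_nodes] +
      (C_mm3_Pa / dt_phase) * (Va / C_mm3_Pa - Pe_Pa)
    P <- as.numeric(Matrix::solve(ch, b))
    Vdot <- (C_mm3_Pa * (P[term_nodes] + Pe_Pa) - Va) / dt_phase
    list(P = P, Vdot = Vdot, Va = Va + Vdot * dt_phase,
         Qb = g * (P[start_node] - P[end_node]))
  }

  zpe_resist <- function(Qb) {
    re <- reynolds_number(Qb, tree$radius_mm, vt$rho_air_kg_m3, vt$mu_air_Pa_s)
    z <- bifurcation_factor(re, 2 * tree$radius_mm, tree$length_mm,
                            vt$zpe_gamma)
    Rp * z
  }

  Va <- acini$V0_mL * 1000  # mm^3
  R <- Rp
  prev_dva <- NULL
  converged <- FALSE
  max_breaths <- vt$max_warmup_breaths
  breath <- 0L
  res <- NULL
  while (breath < max_breaths) {
    breath <- breath + 1L
    Va_start <- Va
    # inspiration: fixed-point refinement of the flow-dependent correction
    for (k in 1:3) {
      ch <- make_system(1 / R, dti)
      s <- step_phase(ch, 1 / R, Va_start, Q_in, dti)
      R <- zpe_resist(s$Qb)
    }
    ch_i <- make_system(1 / R, dti)
    g_i <- 1 / R
    Qi_sum <- numeric(nb); junc_res <- 0
    for (k in seq_len(ni)) {
      s <- step_phase(ch_i, g_i, Va, Q_in, dti)
      Va <- s$Va
      Qi_sum <- Qi_sum + s$Qb
      if (k == ni) {
        net <- as.numeric(laplacian(g_i) %*% s$P)
        internal <- setdiff(seq_len(n_nodes), c(1L, term_nodes))
        if (length(internal))
          junc_res <- max(junc_res, max(abs(net[internal])) / Q_in)
      }
    }
    Va_end_insp <- Va
    R_e <- zpe_resist(-Qi_sum / ni * Ti / Te)
    ch_e <- make_system(1 / R_e, dte)
    g_e <- 1 / R_e
    Qe_sum <- numeric(nb)
    for (k in seq_len(ne)) {
      s <- step_phase(ch_e, g_e, Va, -Q_ex, dte)
      Va <- s$Va
      Qe_sum <- Qe_sum + s$Qb
    }
    dva <- (Va_end_insp - Va_start) / 1000  # mL
    if (!is.null(prev_dva) && breath >= vt$warmup_breaths) {
      drift <- max(abs(dva - prev_dva) / pmax(abs(prev_dva), 1e-9))
      if (drift < vt$drift_tol) {
        converged <- TRUE
        res <- list(dva = dva, Qi = Qi_sum / ni, Qe = Qe_sum / ne,
                    junc = junc_res, drift = drift)
        break
      }
    }
    prev_dva <- dva
  }
  if (!converged)
    stop("ventilation cycle failed to converge: per-breath acinar volume ",
         "drift exceeded ", vt$drift_tol, " after ", max_breaths, " breaths",
         call. = FALSE)

  area <- pi * tree$radius_mm^2
  tracheal_tidal_mL <- Q_in * Ti / 1000
  out <- list(
    acini = data.frame(
      id = acini$id, branch_id = acini$branch_id,
      dVA_mL = res$dva, V0_mL = acini$V0_mL, SV = res$dva / acini$V0_mL
    ),
    branch_flow_insp_mm3_s = res$Qi,
    branch_flow_exp_mm3_s = res$Qe,
    u_insp_mm_s = res$Qi / area,
    u_exp_mm_s = res$Qe / area,
    Ti_s = Ti, Te_s = Te, dt_s = dt,
    Q_in_mm3_s = Q_in, Q_ex_mm3_s = Q_ex,
    tracheal_tidal_mL = tracheal_tidal_mL,
    audits = list(
      junction_residual = res$junc,
      tidal_balance_rel = abs(sum(res$dva) - tracheal_tidal_mL) /
        tracheal_tidal_mL,
      cycle_drift = res$drift,
      dead_space_expansion_mL = 0  # conducting airways are rigid
    )
  )
  class(out) <- "svi_ventilation"
  out
}

#' @export
print.svi_ventilation <- function(x, ...) {
  cat("<svi_ventilation> ", nrow(x$acini), " acini, tidal ",
      round(sum(x$acini$dVA_mL), 1), " mL, mean SV ",
      round(mean(x$acini$SV), 3), "\n", sep = "")
  invisible(x)
}

#' Simulated true specific ventilation
#'
#' `SV_i = dVA_i / V0_i`: breath-averaged fresh-gas delivery per unit
#' end-expiratory volume. This is the reference field that the imaging-side
#' pipeline tries to recover.
#'
#' @param dVA_mL per-acinus alveolar tidal volume (mL/breath), or an
#'   `svi_ventilation` object.
#' @param V0_mL per-acinus end-expiratory gas volume (mL).
#' @return numeric vector of SV values.
#' @export
true_sv <- function(dVA_mL, V0_mL = NULL) {
  if (inherits(dVA_mL, "svi_ventilation"))
    return(dVA_mL$acini$dVA_mL / dVA_mL$acini$V0_mL)
  if (any(V0_mL <= 0)) stop("V0 must be positive", call. = FALSE)
  dVA_mL / V0_mL
}
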