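#' Pressure drop along a vessel branch
#'
#' Viscous Poiseuille term plus the hydrostatic column of the branch:
#' `dP = 128 mu L Qdot / (pi D^4) + rho_b g L cos(theta)`, with the
#' hydrostatic gradient scaled by the branch length for dimensional
#' consistency. Theta is the angle between the branch axis and gravity, so
#' a horizontal branch (theta = 90 degrees) has no hydrostatic term.
#'
#' @param length_mm,diameter_mm branch geometry (mm).
#' @param flow_mm3_s volumetric flow (mm^3/s).
#' @param mu blood viscosity (Pa s).
#' @param rho blood density (kg/m^3).
#' @param g gravitational acceleration (m/s^2).
#' @param theta angle between branch and gravity (radians).
#' @return pressure drop (Pa).
#' @export
branch_pressure_drop <- function(length_mm, diameter_mm, flow_mm3_s, mu,
                                 rho = 1060, g = 9.81, theta = pi / 2) {
  if (any(diameter_mm <= 0)) stop("diameter must be positive", call. = FALSE)
  visc <- 128 * mu * length_mm * flow_mm3_s / (pi * diameter_mm^4)
  hydro <- rho * g * (length_mm / 1000) * cos(theta)
  visc + hydro
}

#' Compliant vessel diameter under transmural pressure
#'
#' Linear tube law `D = D0 (1 + alpha * Ptm)`. The compliance constant
#' alpha has units 1/Pa; a transmural pressure at or below `-1/alpha`
#' means vessel collapse and is rejected.
#'
#' @param D0_mm unstrained diameter (mm).
#' @param Ptm_Pa transmural pressure (Pa): blood pressure plus local
#'   elastic recoil.
#' @param alpha_per_Pa vessel compliance constant (1/Pa).
#' @export
strained_diameter <- function(D0_mm, Ptm_Pa, alpha_per_Pa) {
  f <- 1 + alpha_per_Pa * Ptm_Pa
  if (any(f <= 0)) {
    bad <- which(f <= 0)[1]
    stop("vessel collapse: alpha * Ptm <= -1 at branch ", bad, call. = FALSE)
  }
  D0_mm * f
}

#' Steady-state perfusion through arteries, acinar capillaries and veins
#'
#' Solves Kirchhoff flow on the combined arterial-capillary-venous network
#' with gravitational hydrostatic pressure (via the potential
#' `P + rho g h`) and pressure-dependent vessel diameters, by fixed-point
#' iteration: a sparse linear solve for pressures and flows at the current
#' diameters, then a diameter update from the linear tube law with
#' `Ptm = Pb + Pe`, until the largest relative diameter change falls below
#' tolerance. Each acinus closes the arterial-venous path with a lumped
#' capillary resistance and blood volume.
#'
#' @param artery,vein matched `svi_tree`s.
#' @param acini `svi_acini` (after [apply_gravity()]).
#' @param config an [svi_config()].
#' @param host `svi_host` (height datum for recoil interpolation).
#' @param model `svi_gravity_model` providing the recoil field.
#' @return object of class `svi_perfusion` with per-branch flows, pressures
#'   and strained diameters for both trees, per-acinus flow, capillary
#'   volume and transit time, and conservation audits.
#' @export
solve_perfusion <- function(artery, vein, acini, config = svi_config(),
                            host, model = gravity_model_from_config(config)) {
  pf <- config$perfusion
  nb <- nrow(artery)
  if (nrow(vein) != nb || !all(vein$id == artery$id))
    stop("arterial and venous trees must share topology", call. = FALSE)
  na <- nrow(acini)

  start_node <- ifelse(artery$parent == 0L, 1L, artery$parent + 1L)
  end_node <- artery$id + 1L
  n1 <- nb + 1L               # nodes per tree
  # combined numbering: artery nodes 1..n1, vein nodes n1+1..2*n1
  a_start <- start_node; a_end <- end_node
  v_start <- start_node + n1; v_end <- end_node + n1

  term_rows <- which(artery$terminal)
  if (length(term_rows) != na)
    stop("acinus count does not match terminal branches", call. = FALSE)

  node_xyz <- rbind(
    as.matrix(artery[1, c("x0", "y0", "z0")]),
    as.matrix(artery[, c("x1", "y1", "z1")])
  )
  up <- -host$gravity
  h_m <- as.numeric(node_xyz %*% up) / 1000
  h_m2 <- c(h_m, h_m)
  rho_g <- pf$rho_blood_kg_m3 * pf$g_m_s2

  mid_h_cm <- host_height_cm(host, (node_xyz[start_node, , drop = FALSE] +
                                      node_xyz[end_node, , drop = FALSE]) / 2)
  h_ref_cm <- mean(host_height_cm(host, cbind(acini$x, acini$y, acini$z)))
  Pe_branch_Pa <- (model$pe_ref_cmH2O +
                     model$pe_gradient_cmH2O_per_cm * (mid_h_cm - h_ref_cm)) *
    CMH2O_PA

  # lumped acinar capillary: reference resistance shared by all units, with
  # the same linear transmural tube law as the vessels (diameter factor
  # (1 + alpha Ptm), resistance ~ D^-4), which carries the gravitational
  # perfusion gradient into the capillary bed
  R_cap0 <- pf$cap_resistance_lung_Pa_s_mm3 * na
  h_ac_cm <- host_height_cm(host, cbind(acini$x, acini$y, acini$z))
  Pe_ac_Pa <- (model$pe_ref_cmH2O +
                 model$pe_gradient_cmH2O_per_cm * (h_ac_cm - h_ref_cm)) *
    CMH2O_PA
  g_cap <- rep(1 / R_cap0, na)

  edges_i <- c(a_start, v_start)
  edges_j <- c(a_end, v_end)
  cap_i <- a_end[term_rows]
  cap_j <- v_end[term_rows]

  n_tot <- 2L * n1
  inlet <- 1L
  outlet <- n1 + 1L
  phi_in <- pf$inlet_Pa + rho_g * h_m2[inlet]
  phi_out <- pf$outlet_Pa + rho_g * h_m2[outlet]

  solve_linear <- function(g_branch_art, g_branch_vein) {
    gi <- c(edges_i, cap_i)
    gj <- c(edges_j, cap_j)
    gx <- c(g_branch_art, g_branch_vein, g_cap)
    A <- Matrix::sparseMatrix(
      i = c(gi, gj, gi, gj), j = c(gj, gi, gi, gj),
      x = c(-gx, -gx, gx, gx), dims = c(n_tot, n_tot)
    )
    fixed <- c(inlet, outlet)
    free <- setdiff(seq_len(n_tot), fixed)
    phi_d <- c(phi_in, phi_out)
    rhs <- -as.numeric(A[free, fixed, drop = FALSE] %*% phi_d)
    phi_f <- as.numeric(Matrix::solve(
      Matrix::forceSymmetric(A[free, free, drop = FALSE]), rhs))
    phi <- numeric(n_tot)
    phi[fixed] <- phi_d
    phi[free] <- phi_f
    phi
  }

  D0_art <- 2 * artery$radius_mm
  D0_vein <- 2 * vein$radius_mm
  D_art <- D0_art
  D_vein <- D0_vein
  mu <- pf$mu_blood_Pa_s
  alpha <- pf$alpha_per_Pa

  iter <- 0L
  repeat {
    iter <- iter + 1L
    g_art <- pi * D_art^4 / (128 * mu * artery$length_mm)
    g_vein <- pi * D_vein^4 / (128 * mu * vein$length_mm)
    phi <- solve_linear(g_art, g_vein)
    P <- phi - rho_g * h_m2
    Ptm_art <- (P[a_start] + P[a_end]) / 2 + Pe_branch_Pa
    Ptm_vein <- (P[v_start] + P[v_end]) / 2 + Pe_branch_Pa
    D_art_new <- strained_diameter(D0_art, Ptm_art, alpha)
    D_vein_new <- strained_diameter(D0_vein, Ptm_vein, alpha)
    Ptm_cap <- (P[cap_i] + P[cap_j]) / 2 + Pe_ac_Pa
    g_cap_new <- strained_diameter(1, Ptm_cap, alpha)^4 / R_cap0
    rel <- max(abs(D_art_new - D_art) / D_art,
               abs(D_vein_new - D_vein) / D_vein,
               abs(g_cap_new - g_cap) / g_cap)
    D_art <- D_art_new
    D_vein <- D_vein_new
    g_cap <- g_cap_new
    if (rel < pf$tol || alpha == 0) break
    if (iter >= pf$max_iter)
      stop("perfusion diameter iteration did not converge: residual ", rel,
           call. = FALSE)
  }

  g_art <- pi * D_art^4 / (128 * mu * artery$length_mm)
  g_vein <- pi * D_vein^4 / (128 * mu * vein$length_mm)
  phi <- solve_linear(g_art, g_vein)
  P <- phi - rho_g * h_m2
  Q_art <- g_art * (phi[a_start] - phi[a_end])
  Q_vein <- g_vein * (phi[v_end] - phi[v_start])  # positive toward the heart
  Q_cap <- g_cap * (phi[cap_i] - phi[cap_j])

  net <- numeric(n_tot)
  add_flow <- function(net, from, to, q) {
    s <- rowsum(c(-q, q), c(from, to))
    idx <- as.integer(rownames(s))
    net[idx] <- net[idx] + s[, 1]
    net
  }
  net <- add_flow(net, a_start, a_end, Q_art)
  net <- add_flow(net, cap_i, cap_j, Q_cap)
  net <- add_flow(net, v_end, v_start, Q_vein)
  internal <- setdiff(seq_len(n_tot), c(inlet, outlet))
  junc_res <- max(abs(net[internal])) / max(abs(Q_art[1]), 1e-12)

  vb <- acini$vb_mL * 1000  # mm^3
  transit <- vb / pmax(Q_cap, 1e-12)
  out <- list(
    artery = data.frame(id = artery$id, Q_mm3_s = Q_art,
                        P_Pa = P[a_end], D_mm = D_art),
    vein = data.frame(id = vein$id, Q_mm3_s = Q_vein,
                      P_Pa = P[v_end], D_mm = D_vein),
    acini = data.frame(id = acini$id, Q_mm3_s = Q_cap,
                       vb_mL = acini$vb_mL, transit_s = transit),
    total_flow_mm3_s = Q_art[1],
    iterations = iter,
    audits = list(
      junction_residual = junc_res,
      flow_balance_rel = abs(sum(Q_cap) - Q_art[1]) / abs(Q_art[1])
    )
  )
  class(out) <- "svi_perfusion"
  out
}

#' @export
print.svi_perfusion <- function(x, ...) {
  cat("<svi_perfusion> total flow ",
      round(x$total_flow_mm3_s / 1e6 * 60, 2), " L/min over ",
      nrow(x$acini), " acini (", x$iterations, " iterations)\n", sep = "")
  invisible(x)
}
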