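#' Oxyhemoglobin saturation (Hill form)
#'
#' `S = P^n / (P50^n + P^n)` with analytic derivative; defaults P50 = 26.8
#' mmHg and n = 2.7.
#'
#' @param P_mmHg oxygen partial pressure (mmHg), non-negative.
#' @param p50 half-saturation pressure (mmHg).
#' @param n Hill exponent.
#' @return list with `S` (saturation in `[0, 1]`) and `dSdP` (per mmHg).
#' @export
hb_saturation <- function(P_mmHg, p50 = 26.8, n = 2.7) {
  if (any(P_mmHg < 0)) stop("PO2 must be non-negative", call. = FALSE)
  pn <- P_mmHg^n
  den <- p50^n + pn
  S <- pn / den
  dS <- ifelse(P_mmHg > 0, n * p50^n * pn / (P_mmHg * den^2), 0)
  list(S = S, dSdP = dS)
}

# Hemoglobin buffering factor [1 + (4 Hb / sigma) dS/dP]^-1 that slows the
# blood PO2 response while hemoglobin is still loading.
hb_buffer_factor <- function(P_mmHg, pars) {
  hs <- hb_saturation(P_mmHg, pars$p50, pars$hill_n)
  1 / (1 + 4 * pars$hb_mmol_L / pars$sigma_O2_mmol_L_mmHg * hs$dSdP)
}

#' Integrate the capillary blood PO2 over one RBC transit
#'
#' Solves the blood update ODE
#' `dPb/dt = Tb / (vb sigma) * [1 + (4 Hb / sigma) dS/dP]^-1 * (Pt - Pb)`
#' from the mixed-venous inflow pressure over the red-cell transit time,
#' with the tissue pressure held fixed; implicit sub-steps with a Picard
#' refresh of the buffering factor keep the integration stable for stiff
#' transfer factors. Returns the end-capillary PO2 and the transit-averaged
#' capillary PO2 (used by the tissue equation).
#'
#' @param Pt_mmHg tissue PO2 (vector over acini).
#' @param transit_s RBC transit time (s).
#' @param vb_mL capillary blood volume (mL).
#' @param T_b tissue-capillary transfer factor for this acinus
#'   (mmol/(mmHg s)); the lung-total configuration value is apportioned to
#'   acini in proportion to capillary volume.
#' @param pars gas parameter list (see [svi_config()]`$gas`).
#' @param Pv_mmHg inflow mixed-venous PO2.
#' @param nsub number of sub-steps.
#' @return list with `Pc` (end-capillary) and `Pb_mean` (mmHg).
#' @export
capillary_transit <- function(Pt_mmHg, transit_s, vb_mL, T_b, pars,
                              Pv_mmHg = pars$pv_mmHg, nsub = 8L) {
  k <- T_b / (vb_mL / 1000 * pars$sigma_O2_mmol_L_mmHg)
  h <- transit_s / nsub
  P <- rep_len(Pv_mmHg, length(Pt_mmHg))
  acc <- numeric(length(Pt_mmHg))
  for (s in seq_len(nsub)) {
    beta <- hb_buffer_factor(P, pars)
    r <- k * beta * h
    Pn <- (P + r * Pt_mmHg) / (1 + r)
    beta <- hb_buffer_factor(Pn, pars)  # Picard refresh at the new point
    r <- k * beta * h
    P <- (P + r * Pt_mmHg) / (1 + r)
    acc <- acc + P
  }
  list(Pc = P, Pb_mean = acc / nsub)
}

#' One gas-exchange step for the acinar tissue and blood compartments
#'
#' Updates tissue PO2 with a semi-implicit step of
#' `dPt/dt = T_ta/(vt sigma) (PA - Pt) - T_b/(vt sigma) (Pt - Pb)`
#' (O2 flows down both partial-pressure gradients), with the capillary
#' pressure taken from [capillary_transit()]. Reports the O2 flux drawn
#' from the alveolar gas so the caller can debit the gas compartment.
#'
#' @param Pt_mmHg tissue PO2 (vector over acini).
#' @param PA_mmHg alveolar PO2.
#' @param transit_s,vb_mL,vt_mL per-acinus perfusion and volumes.
#' @param T_ta,T_b per-acinus transfer factors (mmol/(mmHg s)); the
#'   lung-total configuration values are apportioned to acini in
#'   proportion to their tissue and capillary volumes.
#' @param dt time step (s).
#' @param pars gas parameter list.
#' @param nsub capillary transit sub-steps.
#' @return list with updated `Pt`, end-capillary `Pc`, transit-mean `Pb`,
#'   and `uptake_mmol_s` (flux from alveolar gas into tissue).
#' @export
exchange_step <- function(Pt_mmHg, PA_mmHg, transit_s, vb_mL, vt_mL,
                          T_ta, T_b, dt, pars, nsub = 8L) {
  if (any(PA_mmHg < 0 | PA_mmHg > 760) || any(Pt_mmHg < 0 | Pt_mmHg > 760))
    stop("PO2 left the physiological range [0, 760] mmHg; reduce dt",
         call. = FALSE)
  cap <- capillary_transit(Pt_mmHg, transit_s, vb_mL, T_b, pars, nsub = nsub)
  vt_sig <- vt_mL / 1000 * pars$sigma_O2_mmol_L_mmHg
  k_ta <- T_ta / vt_sig
  k_b <- T_b / vt_sig
  Pt_new <- (Pt_mmHg + dt * (k_ta * PA_mmHg + k_b * cap$Pb_mean)) /
    (1 + dt * (k_ta + k_b))
  uptake <- T_ta * (PA_mmHg - Pt_new)
  list(Pt = Pt_new, Pc = cap$Pc, Pb = cap$Pb_mean, uptake_mmol_s = uptake)
}

#' Acinar volume and dilution update over one time step
#'
#' During inspiration the acinus inflates at its ventilation share and its
#' O2 fraction is diluted by the incoming gas
#' (`c' = (V c + q dt c_in) / (V + q dt)`); during expiration it deflates
#' at its own concentration, which therefore changes only through gas
#' exchange.
#'
#' @param V_mL acinar gas volume (vector).
#' @param f O2 fraction (vector).
#' @param inflow_mL_s signed gas inflow rate (positive inflates).
#' @param inflow_o2_mL O2 volume entering with the inflow over the step
#'   (mL; ignored when deflating).
#' @param dt time step (s).
#' @return list with updated `V_mL` and `f`.
#' @export
acinar_volume_update <- function(V_mL, f, inflow_mL_s, inflow_o2_mL, dt) {
  dV <- inflow_mL_s * dt
  V_new <- V_mL + dV
  if (any(V_new <= 0)) stop("acinar volume became non-positive", call. = FALSE)
  f_new <- ifelse(dV > 0, (V_mL * f + inflow_o2_mL) / V_new, f)
  list(V_mL = V_new, f = f_new)
}
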