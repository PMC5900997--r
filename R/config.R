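#' Default run configuration
#'
#' Builds the configuration list that drives every stage of a virtual SVI
#' experiment. Defaults follow the imaging protocol and physical constants of
#' the oxygen-enhanced SVI literature: 650 mL tidal volume, 5 s breaths at
#' I:E 1:1, O2-in-N2 diffusivity 22.5 mm^2/s, O2 solubility 1.4e-3
#' mmol/L/mmHg, vessel compliance 1.49e-4 /Pa, mixed-venous PO2 40 mmHg,
#' 1.6 x 1.6 x 15 mm voxels, a 0.5 tissue-fill threshold, and a 50-curve
#' response library spanning SV 0.01-10 in 15% increments.
#'
#' @param ... named overrides. Nested groups are replaced key-by-key, e.g.
#'   `svi_config(ventilation = list(dt_s = 0.005))`. Unknown keys (top level
#'   or within a group) are rejected.
#' @return A named list of class `svi_config`.
#' @examples
#' cfg <- svi_config(n_terminals = 64)
#' cfg$ventilation$tidal_volume_mL
#' @export
svi_config <- function(...) {
  cfg <- list(
    frc_L = 2.64,
    n_terminals = 500,
    host = list(
      # semi-axis proportions (x = left-right, y = anterior-posterior
      # = gravity axis when supine, z = cranio-caudal)
      right_fraction = 0.54,
      right_semiaxes_mm = c(52.5, 65, 100),
      left_semiaxes_mm = c(47.5, 62, 98),
      gap_mm = 20
    ),
    tree = list(
      branching_fraction = 0.4,
      angle_cap_deg = 60,
      min_length_mm = 1.0,
      airway_root_diameter_mm = 18,
      airway_diameter_ratio = 1.30,
      artery_root_diameter_mm = 24,
      artery_diameter_ratio = 1.35,
      vein_artery_ratio = 1.2
    ),
    mechanics = list(
      v0_gradient_per_cm = 0.060,
      pe_ref_cmH2O = 5,
      pe_gradient_cmH2O_per_cm = 0.25,
      compliance_total_mL_per_cmH2O = 100,
      compliance_cv = 0.05
    ),
    ventilation = list(
      tidal_volume_mL = 650,
      breath_s = 5,
      ie_ratio = 1,
      dt_s = 0.01,
      mu_air_Pa_s = 1.8e-5,
      rho_air_kg_m3 = 1.12,
      zpe_gamma = 0.327,
      warmup_breaths = 3,
      max_warmup_breaths = 20,
      drift_tol = 0.005
    ),
    perfusion = list(
      mu_blood_Pa_s = 3.36e-3,
      rho_blood_kg_m3 = 1060,
      g_m_s2 = 9.81,
      inlet_Pa = 2000,
      outlet_Pa = 666,
      alpha_per_Pa = 1.49e-4,
      cap_resistance_lung_Pa_s_mm3 = 0.026,
      cap_volume_total_mL = 100,
      tol = 1e-6,
      max_iter = 60
    ),
    gas = list(
      D_mm2_s = 22.5,
      sigma_O2_mmol_L_mmHg = 1.4e-3,
      hb_mmol_L = 2.3,
      p50_mmHg = 26.8,
      hill_n = 2.7,
      T_ta_lung_mmol_mmHg_s = 0.010,
      T_b_lung_mmol_mmHg_s = 0.025,
      tissue_volume_total_mL = 500,
      pv_mmHg = 40,
      dry_pressure_mmHg = 713,
      gas_mmol_per_mL = 0.0393
    ),
    transport = list(
      dt_s = 0.05,
      node_spacing_mm = 3,
      coarsen_by_radius = TRUE,
      cfl = 0.9,
      peclet_cutoff = 5,
      diffusion = TRUE,
      transit_substeps = 8
    ),
    protocol = list(
      breaths_per_block = 20,
      n_cycles = 5,
      extra_o2_breaths = 20,
      fio2_air = 0.21,
      fio2_o2 = 1.0,
      warmup_breaths = 6,
      include_arterial = FALSE
    ),
    imaging = list(
      voxel_inplane_mm = 1.6,
      voxel_slab_mm = 15,
      fill_threshold = 0.5,
      vein_point_volume_mm3 = 0.1,
      sphere_sample_spacing_mm = 1.6
    ),
    inference = list(
      sv_min = 0.01,
      sv_increment = 0.15,
      sv_n = 50,
      sv_max = 10,
      alpha = 0.05
    ),
    analysis = list(
      section_mm = 10,
      slice_mm = 15
    ),
    misalignment = list(
      eelv_mean = 0.09,
      eelv_sd = 0.12,
      eelv_max = 0.40,
      volume_tol = 0.10
    )
  )
  cfg <- merge_config(cfg, list(...))
  class(cfg) <- "svi_config"
  cfg
}

merge_config <- function(base, override, path = "") {
  if (length(override) == 0) return(base)
  nm <- names(override)
  if (is.null(nm) || any(!nzchar(nm)))
    stop("configuration overrides must be named", call. = FALSE)
  for (k in nm) {
    full <- if (nzchar(path)) paste0(path, "$", k) else k
    if (!k %in% names(base))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(override[[k]]))
        stop("configuration group ", full, " must be a named list",
             call. = FALSE)
      base[[k]] <- merge_config(base[[k]], override[[k]], full)
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read and write configurations as YAML
#'
#' The configuration round-trips unchanged through serialization; files with
#' keys not present in the default configuration are rejected with the
#' offending key named.
#'
#' @param path file path.
#' @param cfg an `svi_config` list.
#' @return `read_svi_config` returns an `svi_config`;
#'   `write_svi_config` returns `path` invisibly.
#' @export
read_svi_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(svi_config, raw)
}

#' @rdname read_svi_config
#' @export
write_svi_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "svi_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.svi_config <- function(x, ...) {
  cat("<svi_config>  FRC", x$frc_L, "L,", x$n_terminals, "terminals,",
      "VT", x$ventilation$tidal_volume_mL, "mL /",
      x$ventilation$breath_s, "s\n")
  invisible(x)
}
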