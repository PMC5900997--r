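#' Gravitational tissue-mechanics model
#'
#' Parameterized stand-in for a continuum soft-tissue model: in the supine
#' posture, acinar FRC volumes vary linearly with height along the gravity
#' axis (dependent/dorsal units are smaller, hence higher specific
#' ventilation once tidal volume is distributed), and the local elastic
#' recoil pressure carries a matching height gradient. The density gradient
#' is the calibration handle for the simulated-true-SV vertical gradient.
#'
#' @param direction gravity unit vector (default supine, anterior-posterior).
#' @param v0_gradient_per_cm fractional change in V0 per cm of height.
#' @param pe_ref_cmH2O recoil pressure at mid-height.
#' @param pe_gradient_cmH2O_per_cm recoil height gradient.
#' @return object of class `svi_gravity_model`.
#' @export
gravity_model <- function(direction = c(0, -1, 0),
                          v0_gradient_per_cm = 0.060,
                          pe_ref_cmH2O = 5,
                          pe_gradient_cmH2O_per_cm = 0.25) {
  stopifnot(all(is.finite(direction)), all(is.finite(v0_gradient_per_cm)),
            all(is.finite(pe_ref_cmH2O)), all(is.finite(pe_gradient_cmH2O_per_cm)))
  m <- list(direction = direction / sqrt(sum(direction^2)),
            v0_gradient_per_cm = v0_gradient_per_cm,
            pe_ref_cmH2O = pe_ref_cmH2O,
            pe_gradient_cmH2O_per_cm = pe_gradient_cmH2O_per_cm)
  class(m) <- "svi_gravity_model"
  m
}

#' @rdname gravity_model
#' @param config an [svi_config()]; builds the model from its `mechanics`
#'   group.
#' @export
gravity_model_from_config <- function(config = svi_config()) {
  gravity_model(v0_gradient_per_cm = config$mechanics$v0_gradient_per_cm,
                pe_ref_cmH2O = config$mechanics$pe_ref_cmH2O,
                pe_gradient_cmH2O_per_cm = config$mechanics$pe_gradient_cmH2O_per_cm)
}

#' Apply the gravitational volume and recoil distribution to the acini
#'
#' V0 is scaled linearly with height above the dependent (dorsal) edge and
#' then rescaled so the total FRC gas volume is exactly preserved; tissue
#' and capillary blood volumes are re-apportioned proportionally to the new
#' V0. Recoil pressure Pe gets the matching linear height dependence about
#' its mid-height reference.
#'
#' @param acini an `svi_acini` data frame.
#' @param model an `svi_gravity_model`.
#' @param host the `svi_host` (for the height datum).
#' @return the acini with `V0_mL`, `Pe_cmH2O`, `vt_mL`, `vb_mL` updated.
#' @export
apply_gravity <- function(acini, model, host) {
  stopifnot(inherits(model, "svi_gravity_model"))
  h <- host_height_cm(host, cbind(acini$x, acini$y, acini$z))
  hc <- h - mean(h)
  f <- 1 + model$v0_gradient_per_cm * hc
  if (any(f <= 0)) {
    bad <- which.min(f)
    stop(sprintf(paste0("V0 gradient too steep: non-positive volume at ",
                        "height %.1f cm above the dependent edge"), h[bad]),
         call. = FALSE)
  }
  tot <- sum(acini$V0_mL)
  v0 <- acini$V0_mL * f
  acini$V0_mL <- v0 * (tot / sum(v0))
  acini$Pe_cmH2O <- model$pe_ref_cmH2O + model$pe_gradient_cmH2O_per_cm * hc
  share <- acini$V0_mL / sum(acini$V0_mL)
  acini$vt_mL <- sum(acini$vt_mL) * share
  acini$vb_mL <- sum(acini$vb_mL) * share
  attr(acini, "height_cm") <- h
  acini
}
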