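#' Blood residence lag of a venous branch
#'
#' `lag = blood volume / flow` (seconds); the volume is the cylinder around
#' the branch centerline at the strained diameter.
#'
#' @param volume_mm3 branch blood volume (mm^3).
#' @param flow_mm3_s branch blood flow (mm^3/s).
#' @export
branch_lag <- function(volume_mm3, flow_mm3_s) {
  if (any(flow_mm3_s <= 0)) {
    bad <- which(flow_mm3_s <= 0)[1]
    stop("zero or reverse flow in venous branch ", bad,
         ": lag undefined", call. = FALSE)
  }
  volume_mm3 / flow_mm3_s
}

#' Flow-weighted mixing at a venous confluence
#'
#' @param flows_mm3_s non-negative flows of the merging streams.
#' @param conc concentrations of the streams (same length, or a matrix with
#'   one row per stream for time series).
#' @return mixed concentration (scalar or vector over time).
#' @export
mix_at_confluence <- function(flows_mm3_s, conc) {
  if (any(flows_mm3_s < 0)) stop("flows must be non-negative", call. = FALSE)
  tot <- sum(flows_mm3_s)
  if (tot <= 0) stop("all-zero flows at confluence", call. = FALSE)
  if (is.matrix(conc)) {
    as.numeric(crossprod(flows_mm3_s, conc)) / tot
  } else {
    sum(flows_mm3_s * conc) / tot
  }
}

# shift a once-per-breath sampled series backwards by `lag_s` with linear
# interpolation between breath samples; the pre-protocol past is held at
# the first sample.
delay_series <- function(x, lag_s, breath_s) {
  if (lag_s <= 0) return(x)
  shift <- lag_s / breath_s
  n <- length(x)
  pos <- seq_len(n) - shift
  lo <- floor(pos)
  w <- pos - lo
  x_at <- function(k) x[pmin(pmax(k, 1L), n)]
  out <- (1 - w) * x_at(lo) + w * x_at(lo + 1L)
  out[pos <= 1] <- x[1]
  out
}

#' Propagate end-capillary O2 through the venous tree
#'
#' Topological sweep from the acinar terminals to the venous root: each
#' branch carries the flow-weighted mixture of its upstream series, delayed
#' by the branch residence time (volume / flow), with linear interpolation
#' between the once-per-breath samples. At steady state the root series
#' equals the flow-weighted mean of all end-capillary values (mixed
#' pulmonary-venous PO2).
#'
#' @param vein venous `svi_tree`.
#' @param ec_series matrix (acini x breaths) of end-capillary PO2 sampled at
#'   the end of each breath.
#' @param perfusion an `svi_perfusion` solution on matching trees.
#' @param breath_s breath duration (s).
#' @return object of class `svi_venous_field`: per-branch series matrix
#'   (branches x breaths), per-branch lag (s) and blood volume (mm^3).
#' @export
propagate_venous <- function(vein, ec_series, perfusion, breath_s = 5) {
  nb <- nrow(vein)
  if (nrow(perfusion$vein) != nb || !all(perfusion$vein$id == vein$id))
    stop("perfusion solution does not match the venous tree", call. = FALSE)
  term_rows <- which(vein$terminal)
  if (nrow(ec_series) != length(term_rows))
    stop("end-capillary series does not match the venous terminals",
         call. = FALSE)
  Q <- perfusion$vein$Q_mm3_s
  D <- perfusion$vein$D_mm
  vol <- pi * (D / 2)^2 * vein$length_mm
  lag <- branch_lag(vol, Q)

  n_breaths <- ncol(ec_series)
  series <- matrix(NA_real_, nb, n_breaths)
  children <- split(seq_len(nb), factor(vein$parent, levels = vein$id))
  ac_of_term <- match(seq_len(nb), term_rows)
  for (b in rev(seq_len(nb))) {
    if (vein$terminal[b]) {
      inp <- ec_series[ac_of_term[b], ]
    } else {
      kids <- children[[as.character(vein$id[b])]]
      inp <- mix_at_confluence(Q[kids], series[kids, , drop = FALSE])
    }
    series[b, ] <- delay_series(inp, lag[b], breath_s)
  }
  out <- list(series = series, lag_s = lag, volume_mm3 = vol,
              flow_mm3_s = Q, breath_s = breath_s)
  class(out) <- "svi_venous_field"
  out
}
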