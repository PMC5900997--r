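#' Build the characteristic response-curve library
#'
#' Fifty single-compartment washin/washout templates indexed by specific
#' ventilation: a geometric series of SV values from 0.01 in 15% increments
#' (none exceeding 10), each driven through the breathing schedule by the
#' inert end-expiratory mixing update `c' = c + s/(1+s) (c_insp - c)`.
#' Units with higher SV equilibrate in fewer breaths, which is what the
#' Spearman matching exploits.
#'
#' @param schedule from [make_schedule()].
#' @param config an [svi_config()] (group `inference`).
#' @return an `svi_response_library`: `sv` (length 50) and `curves`
#'   (50 x breaths).
#' @export
build_library <- function(schedule = make_schedule(config),
                          config = svi_config()) {
  inf <- config$inference
  sv <- inf$sv_min * (1 + inf$sv_increment)^(seq_len(inf$sv_n) - 1)
  if (any(sv > inf$sv_max))
    stop("response library SV values exceed the configured maximum",
         call. = FALSE)
  out <- list(sv = sv, curves = inert_response(sv, schedule))
  class(out) <- "svi_response_library"
  out
}

#' Inert single-compartment washin/washout response
#'
#' End-expiratory concentration of a well-mixed compartment with specific
#' ventilation `s` driven by the inspired-gas schedule:
#' `c_k = c_{k-1} + s/(1+s) (fio2_k - c_{k-1})`. Within a constant-FIO2
#' block this has the closed form
#' `c_n = c_inf + (c_0 - c_inf) (1+s)^(-n)`.
#'
#' @param sv specific ventilation value(s).
#' @param schedule data frame with `fio2` per breath.
#' @param c0 starting concentration (defaults to the first breath's FIO2).
#' @return matrix `length(sv)` x `nrow(schedule)`.
#' @export
inert_response <- function(sv, schedule, c0 = schedule$fio2[1]) {
  n <- nrow(schedule)
  curves <- matrix(NA_real_, length(sv), n)
  frac <- sv / (1 + sv)
  cprev <- rep_len(c0, length(sv))
  for (k in seq_len(n)) {
    cprev <- cprev + frac * (schedule$fio2[k] - cprev)
    curves[, k] <- cprev
  }
  curves
}

#' @export
print.svi_response_library <- function(x, ...) {
  cat("<svi_response_library> ", length(x$sv), " curves, SV ",
      signif(min(x$sv), 3), "-", signif(max(x$sv), 3), " x ",
      ncol(x$curves), " breaths\n", sep = "")
  invisible(x)
}

#' Translate voxel time series into SV estimates
#'
#' Each voxel's end-of-breath series is Spearman-rank-correlated with all
#' library curves; the highest correlation gives the SV estimate, kept only
#' if significant (default P <= 0.05, large-sample t approximation). Ties
#' break toward the lower SV value; constant series are discarded as
#' zero-variance.
#'
#' @param series numeric matrix (voxels x breaths) or a single series.
#' @param library an `svi_response_library`.
#' @param alpha significance level.
#' @return data frame with `sv`, `rho`, `p`, `discarded`, `reason`.
#' @export
infer_sv <- function(series, library, alpha = 0.05) {
  if (is.null(dim(series))) series <- matrix(series, nrow = 1)
  n <- ncol(series)
  if (n != ncol(library$curves))
    stop("series length does not match the library curves", call. = FALSE)
  tmpl <- t(apply(library$curves, 1, rank))
  tmpl <- tmpl - rowMeans(tmpl)
  tmpl <- tmpl / sqrt(rowSums(tmpl^2))
  nv <- nrow(series)
  sdv <- apply(series, 1, stats::sd)
  const <- !is.finite(sdv) | sdv == 0
  rk <- matrix(0, nv, n)
  if (any(!const))
    rk[!const, ] <- t(apply(series[!const, , drop = FALSE], 1, rank))
  rk <- rk - rowMeans(rk)
  nrm <- sqrt(rowSums(rk^2))
  nrm[nrm == 0] <- 1
  rho_all <- (rk / nrm) %*% t(tmpl)
  best <- max.col(rho_all, ties.method = "first")
  rho <- rho_all[cbind(seq_len(nv), best)]
  rho_c <- pmin(pmax(rho, -0.9999999), 0.9999999)
  tstat <- rho_c * sqrt((n - 2) / (1 - rho_c^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  discarded <- const | p > alpha
  reason <- rep(NA_character_, nv)
  reason[const] <- "zero_variance"
  reason[!const & p > alpha] <- "not_significant"
  data.frame(
    sv = ifelse(discarded, NA_real_, library$sv[best]),
    rho = ifelse(const, NA_real_, rho),
    p = ifelse(const, NA_real_, p),
    discarded = discarded,
    reason = reason
  )
}
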