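#' Gravitational gradient, mean and heterogeneity of an SV field
#'
#' The region is divided into 10 mm thick iso-gravitational sections; the
#' gradient is the ordinary least-squares slope of per-section mean SV
#' against section height (cm, measured upward from the dependent edge),
#' the mean is over all values in the region, and the coefficient of
#' variation is 100 x SD / mean over the same values.
#'
#' @param sv SV values (voxels or acini); `NA`s are dropped.
#' @param height_cm matching heights above the dependent edge (cm).
#' @param section_mm iso-gravitational section thickness (mm).
#' @return a `data.frame` row: `gradient_per_cm`, `mean_sv`, `cov_pct`,
#'   `n`, plus the per-section table as attribute `"sections"`.
#' @export
gravitational_summary <- function(sv, height_cm, section_mm = 10) {
  ok <- is.finite(sv) & is.finite(height_cm)
  sv <- sv[ok]; h <- height_cm[ok]
  sec_cm <- section_mm / 10
  bin <- floor((h - min(h)) / sec_cm)
  tab <- data.frame(
    height_cm = tapply(h, bin, mean),
    mean_sv = tapply(sv, bin, mean),
    sd_sv = tapply(sv, bin, stats::sd),
    n = as.integer(table(bin))
  )
  if (nrow(tab) < 3)
    stop("fewer than 3 non-empty iso-gravitational sections", call. = FALSE)
  fit <- stats::lm(mean_sv ~ height_cm, data = tab)
  out <- data.frame(
    gradient_per_cm = unname(stats::coef(fit)[2]),
    mean_sv = mean(sv),
    cov_pct = 100 * stats::sd(sv) / mean(sv),
    n = length(sv)
  )
  attr(out, "sections") <- tab
  out
}

#' Split the voxel grid into sagittal slices
#'
#' Slices are the contiguous 15 mm slabs of the voxel grid. The
#' mid-sagittal slice of a lung is the slab containing the most retained
#' lung voxels (the largest cross-section), the usual choice for
#' single-slice SVI away from the hilum.
#'
#' @param grid `svi_voxel_grid` (after [apply_fill_filter()]).
#' @param lung restrict to `"right"`, `"left"` or `"both"`.
#' @return list with `slices` (list of voxel-id vectors, ordered laterally),
#'   `slab_index`, and `mid` (index into `slices` of the mid-sagittal
#'   slab).
#' @export
extract_slices <- function(grid, lung = c("right", "left", "both")) {
  lung <- match.arg(lung)
  v <- grid$voxels
  keep <- if (lung == "both") rep(TRUE, nrow(v)) else
    v$lung == match(lung, c("right", "left"))
  if (!is.null(v$retained)) keep <- keep & v$retained
  ix_used <- sort(unique(v$ix[keep]))
  slices <- lapply(ix_used, function(i) v$id[keep & v$ix == i])
  counts <- lengths(slices)
  list(slices = slices, slab_index = ix_used, mid = which.max(counts))
}

#' Compare SV summaries across the virtual experiments
#'
#' Assembles the standard comparison table: simulated true SV against the
#' SVI measurement, mid-sagittal slice against whole lung, tissue+vein
#' signal against tissue-only, and aligned against misaligned — each as
#' gradient / mean / COV rows from [gravitational_summary()].
#'
#' @param summaries named list of single-row summary data frames.
#' @return one data frame with a `scenario` column.
#' @export
compare_experiments <- function(summaries) {
  out <- do.call(rbind, lapply(names(summaries), function(nm) {
    cbind(scenario = nm, summaries[[nm]])
  }))
  rownames(out) <- NULL
  out
}
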