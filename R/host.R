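#' Generate the synthetic host lung volume
#'
#' The host stands in for subject-specific lobar surfaces: two disjoint
#' ellipsoidal lungs (x = left-right, y = anterior-posterior, z =
#' cranio-caudal) scaled so that their combined enclosed volume equals the
#' functional residual capacity (FRC) target. Supine posture is assumed
#' throughout, so the gravity unit vector points along -y (dependent tissue
#' is dorsal/posterior).
#'
#' @param config an [svi_config()] list (fields `frc_L` and `host` are used).
#' @param seed integer seed; the host is analytic so the same inputs always
#'   give the same surfaces, but the seed is stored and fanned out to later
#'   stochastic stages.
#' @return An object of class `svi_host`: per-lung center and semi-axes (mm),
#'   total volume (mL), gravity direction, and the seed.
#' @export
generate_host <- function(config = svi_config(), seed = 1L) {
  frc_mL <- config$frc_L * 1000
  if (!is.finite(frc_mL) || frc_mL <= 0)
    stop("FRC target must be positive", call. = FALSE)
  h <- config$host
  if (any(h$right_semiaxes_mm <= 0) || any(h$left_semiaxes_mm <= 0) ||
      h$gap_mm < 0)
    stop("host dimensions must be positive", call. = FALSE)
  if (h$right_fraction <= 0 || h$right_fraction >= 1)
    stop("right_fraction must lie in (0, 1)", call. = FALSE)

  scale_lung <- function(semi, target_mL) {
    raw <- 4 / 3 * pi * prod(semi) / 1000
    semi * (target_mL / raw)^(1 / 3)
  }
  right_semi <- scale_lung(h$right_semiaxes_mm, frc_mL * h$right_fraction)
  left_semi <- scale_lung(h$left_semiaxes_mm, frc_mL * (1 - h$right_fraction))
  right_center <- c(h$gap_mm / 2 + right_semi[1], 0, 0)
  left_center <- c(-(h$gap_mm / 2 + left_semi[1]), 0, 0)

  host <- list(
    lungs = list(
      right = list(center = right_center, semi = right_semi),
      left = list(center = left_center, semi = left_semi)
    ),
    frc_mL = frc_mL,
    gravity = c(0, -1, 0),
    seed = as.integer(seed)
  )
  class(host) <- "svi_host"
  host
}

#' Host volume enclosed by the lung surfaces (mL)
#' @param host an `svi_host`.
#' @export
host_volume <- function(host) {
  sum(vapply(host$lungs, function(l) 4 / 3 * pi * prod(l$semi) / 1000,
             numeric(1)))
}

#' Test points for containment in the host
#'
#' @param host an `svi_host`.
#' @param pts n x 3 matrix of coordinates (mm).
#' @return integer vector: 0 outside, 1 right lung, 2 left lung.
#' @export
host_lung_of <- function(host, pts) {
  pts <- matrix(pts, ncol = 3)
  out <- integer(nrow(pts))
  for (i in seq_along(host$lungs)) {
    l <- host$lungs[[i]]
    d <- sweep(pts, 2, l$center)
    r2 <- (d[, 1] / l$semi[1])^2 + (d[, 2] / l$semi[2])^2 +
      (d[, 3] / l$semi[3])^2
    out[out == 0L & r2 <= 1] <- i
  }
  out
}

#' @rdname host_lung_of
#' @export
host_contains <- function(host, pts) host_lung_of(host, pts) > 0L

host_bbox <- function(host) {
  lo <- rep(Inf, 3); hi <- rep(-Inf, 3)
  for (l in host$lungs) {
    lo <- pmin(lo, l$center - l$semi)
    hi <- pmax(hi, l$center + l$semi)
  }
  rbind(lo = lo, hi = hi)
}

#' Uniform random points inside one lung (rejection sampling)
#'
#' Optionally enforces a minimum pairwise separation (greedy thinning),
#' used so terminal branches can respect the minimum branch length; if the
#' separation cannot be achieved the lung is over-packed and an error
#' names the limit.
#'
#' @param host an `svi_host`.
#' @param lung `"right"` or `"left"`.
#' @param n number of points.
#' @param seed integer seed.
#' @param min_sep minimum pairwise distance (mm), 0 to disable.
#' @return n x 3 matrix (mm).
#' @export
sample_lung_points <- function(host, lung, n, seed, min_sep = 0) {
  l <- host$lungs[[lung]]
  set.seed(as.integer(seed))
  pts <- matrix(NA_real_, 0, 3)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("cannot place ", n, " seed points in the ", lung,
           " lung at the minimum branch length limit (", min_sep,
           " mm): packing capacity exceeded", call. = FALSE)
    m <- max(2L * (n - nrow(pts)), 32L)
    cand <- sweep(matrix(stats::runif(3 * m, -1, 1), ncol = 3), 2, l$semi, `*`)
    keep <- rowSums(sweep(cand, 2, l$semi, `/`)^2) <= 1
    cand <- sweep(cand[keep, , drop = FALSE], 2, l$center, `+`)
    for (i in seq_len(nrow(cand))) {
      if (nrow(pts) >= n) break
      p <- cand[i, ]
      if (min_sep > 0 && nrow(pts) > 0) {
        d2 <- (pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2 + (pts[, 3] - p[3])^2
        if (min(d2) < min_sep^2) next
      }
      pts <- rbind(pts, p)
    }
  }
  pts[seq_len(n), , drop = FALSE]
}

#' @export
print.svi_host <- function(x, ...) {
  cat("<svi_host> volume", round(host_volume(x), 1), "mL (target",
      x$frc_mL, "mL), supine gravity along (",
      paste(x$gravity, collapse = ", "), ")\n")
  invisible(x)
}

#' Height above the dependent lung edge, along gravity (cm)
#'
#' In the supine posture gravity acts along -y, so height is measured from
#' the most dorsal extent of the host upward (ventral).
#'
#' @param host an `svi_host`.
#' @param pts n x 3 matrix (mm) or vector of length 3.
#' @return numeric vector of heights in cm.
#' @export
host_height_cm <- function(host, pts) {
  pts <- matrix(pts, ncol = 3)
  up <- -host$gravity
  proj <- pts %*% up
  base <- min(vapply(host$lungs, function(l)
    sum(l$center * up) - sum(abs(up) * l$semi), numeric(1)))
  as.numeric(proj - base) / 10
}
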