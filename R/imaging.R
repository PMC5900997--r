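#' Build the MR voxel grid over the host
#'
#' Voxels are 1.6 x 1.6 mm in the sagittal (y-z) plane and 15 mm thick in
#' the left-right direction (one sagittal slab per slice), as in the SVI
#' acquisition. The tissue fill fraction of every voxel is computed by
#' subsampling against the host surfaces; voxels with no lung content are
#' dropped.
#'
#' @param host an `svi_host`.
#' @param config an [svi_config()] (group `imaging`).
#' @return an `svi_voxel_grid`: voxel table (`ix`, `iy`, `iz`, centers,
#'   `fill`, `height_cm`, `lung`), axis break points, and bookkeeping slots
#'   for signal series added by the voxelizers.
#' @export
make_voxel_grid <- function(host, config = svi_config()) {
  im <- config$imaging
  bb <- host_bbox(host)
  margin <- 16
  xb <- seq(bb["lo", 1] - margin, bb["hi", 1] + margin + im$voxel_slab_mm,
            by = im$voxel_slab_mm)
  yb <- seq(bb["lo", 2] - margin, bb["hi", 2] + margin + im$voxel_inplane_mm,
            by = im$voxel_inplane_mm)
  zb <- seq(bb["lo", 3] - margin, bb["hi", 3] + margin + im$voxel_inplane_mm,
            by = im$voxel_inplane_mm)
  nx <- length(xb) - 1L; ny <- length(yb) - 1L; nz <- length(zb) - 1L

  # fill fraction by voxel subsampling (5 x 3 x 3 points per voxel)
  qx <- (seq_len(5) - 0.5) / 5
  qy <- (seq_len(3) - 0.5) / 3
  qz <- (seq_len(3) - 0.5) / 3
  vox <- vector("list", nx)
  cx_all <- (xb[-1] + xb[-length(xb)]) / 2
  cy_all <- (yb[-1] + yb[-length(yb)]) / 2
  cz_all <- (zb[-1] + zb[-length(zb)]) / 2
  for (ix in seq_len(nx)) {
    centers <- expand.grid(iy = seq_len(ny), iz = seq_len(nz))
    fill <- numeric(nrow(centers))
    lung <- integer(nrow(centers))
    for (ox in qx) for (oy in qy) for (oz in qz) {
      pts <- cbind(xb[ix] + ox * im$voxel_slab_mm,
                   yb[centers$iy] + oy * im$voxel_inplane_mm,
                   zb[centers$iz] + oz * im$voxel_inplane_mm)
      lg <- host_lung_of(host, pts)
      fill <- fill + (lg > 0L)
      lung <- pmax(lung, lg)
    }
    fill <- fill / (length(qx) * length(qy) * length(qz))
    keep <- fill > 0
    if (!any(keep)) next
    vox[[ix]] <- data.frame(
      ix = ix, iy = centers$iy[keep], iz = centers$iz[keep],
      x = cx_all[ix], y = cy_all[centers$iy[keep]],
      z = cz_all[centers$iz[keep]],
      fill = fill[keep], lung = lung[keep]
    )
  }
  voxels <- do.call(rbind, vox)
  voxels$id <- seq_len(nrow(voxels))
  voxels$height_cm <- host_height_cm(host, cbind(voxels$x, voxels$y, voxels$z))
  key <- function(ix, iy, iz) (ix - 1) * (ny * nz) + (iy - 1) * nz + iz
  lookup <- new.env(hash = TRUE)
  grid <- list(
    voxels = voxels,
    xb = xb, yb = yb, zb = zb,
    dims = c(nx, ny, nz),
    voxel_mm = c(im$voxel_slab_mm, im$voxel_inplane_mm, im$voxel_inplane_mm),
    voxel_volume_mm3 = im$voxel_slab_mm * im$voxel_inplane_mm^2,
    key = key,
    id_of_key = local({
      v <- integer(0)
      v[key(voxels$ix, voxels$iy, voxels$iz)] <- voxels$id
      v
    }),
    fill_threshold = im$fill_threshold
  )
  class(grid) <- "svi_voxel_grid"
  grid
}

#' @export
print.svi_voxel_grid <- function(x, ...) {
  cat("<svi_voxel_grid> ", nrow(x$voxels), " lung voxels of ",
      paste(x$voxel_mm, collapse = " x "), " mm\n", sep = "")
  invisible(x)
}

# map points (n x 3) to voxel ids (NA outside the grid / non-lung voxels)
points_to_voxel <- function(grid, pts) {
  ix <- findInterval(pts[, 1], grid$xb, rightmost.closed = TRUE)
  iy <- findInterval(pts[, 2], grid$yb, rightmost.closed = TRUE)
  iz <- findInterval(pts[, 3], grid$zb, rightmost.closed = TRUE)
  ok <- ix >= 1 & ix <= grid$dims[1] & iy >= 1 & iy <= grid$dims[2] &
    iz >= 1 & iz <= grid$dims[3]
  id <- rep(NA_integer_, nrow(pts))
  kk <- grid$key(ix[ok], iy[ok], iz[ok])
  v <- grid$id_of_key[kk]
  v[is.na(v)] <- NA_integer_
  id[ok] <- v
  id
}

# symmetric regular lattice (half-spacing offset, no point on the center
# planes) for a sphere centered at the origin
sphere_lattice <- function(radius, spacing) {
  g <- seq(spacing / 2, radius, by = spacing)
  g <- c(-rev(g), g)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
}

#' Distribute acinar volumes over the voxel grid
#'
#' Each acinus is represented as a sphere of its FRC gas volume centered at
#' its location, subsampled with a regular lattice and apportioned to the
#' voxels it overlaps. The resulting sparse weight matrix (voxels x acini,
#' in mm^3) turns per-acinus signal series into voxel series by
#' volume-proportional summation.
#'
#' @param acini `svi_acini`.
#' @param grid `svi_voxel_grid`.
#' @param config an [svi_config()].
#' @return the grid with `tissue_weights` (dgCMatrix, mm^3) and the
#'   partition audit `tissue_volume_audit` (relative loss).
#' @export
voxelize_tissue <- function(acini, grid, config = svi_config()) {
  spacing <- config$imaging$sphere_sample_spacing_mm
  n <- nrow(acini)
  ii <- vector("list", n); jj <- vector("list", n); xx <- vector("list", n)
  for (i in seq_len(n)) {
    r <- (3 * acini$V0_mL[i] * 1000 / (4 * pi))^(1 / 3)
    pts <- sphere_lattice(r, spacing)
    pts <- sweep(pts, 2, c(acini$x[i], acini$y[i], acini$z[i]), `+`)
    id <- points_to_voxel(grid, pts)
    ok <- !is.na(id)
    if (!any(ok)) {
      # degenerate: whole kernel outside lung voxels; keep the unit in the
      # voxel holding its center
      id <- points_to_voxel(grid, matrix(c(acini$x[i], acini$y[i],
                                           acini$z[i]), 1))
      ok <- !is.na(id)
      if (!any(ok)) stop("acinus ", i, " lies outside the voxel grid")
    }
    # the sphere is a sampling kernel: the acinar volume is apportioned
    # over the lung voxels the kernel hits, so the partition is exact
    w <- acini$V0_mL[i] * 1000 / sum(ok)
    tab <- table(id[ok])
    ii[[i]] <- as.integer(names(tab))
    jj[[i]] <- rep(i, length(tab))
    xx[[i]] <- as.numeric(tab) * w
  }
  W <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(nrow(grid$voxels), n))
  grid$tissue_weights <- W
  grid$tissue_volume_audit <-
    abs(sum(W) - sum(acini$V0_mL) * 1000) / (sum(acini$V0_mL) * 1000)
  grid
}

#' Voxel tissue signal series from per-acinus series
#'
#' @param grid grid after [voxelize_tissue()].
#' @param signal matrix (acini x breaths) of per-acinus signal.
#' @return matrix (voxels x breaths): each acinus's signal split across
#'   voxels in proportion to the acinar volume in each voxel.
#' @export
voxel_tissue_series <- function(grid, signal) {
  frac <- grid$tissue_weights %*%
    Matrix::Diagonal(ncol(grid$tissue_weights),
                     1 / Matrix::colSums(grid$tissue_weights))
  as.matrix(frac %*% signal)
}

# regular lattice filling a cylinder from p0 to p1 with the given radius;
# returns points and the exact per-point volume weight
cylinder_lattice <- function(p0, p1, radius, point_volume) {
  axis <- p1 - p0
  L <- sqrt(sum(axis^2))
  if (L <= 0 || radius <= 0) return(NULL)
  d <- axis / L
  # orthonormal frame
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- ref - sum(ref * d) * d
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d[2] * e1[3] - d[3] * e1[2],
          d[3] * e1[1] - d[1] * e1[3],
          d[1] * e1[2] - d[2] * e1[1])
  s <- point_volume^(1 / 3)
  ax <- seq(s / 2, L, by = s)
  rad <- seq(s / 2, radius, by = s)
  rad <- c(-rev(rad), rad)
  gr <- expand.grid(a = ax, u = rad, v = rad)
  gr <- gr[gr$u^2 + gr$v^2 <= radius^2, , drop = FALSE]
  if (nrow(gr) == 0) gr <- data.frame(a = L / 2, u = 0, v = 0)
  pts <- outer(gr$a, d) + outer(gr$u, e1) + outer(gr$v, e2)
  pts <- sweep(pts, 2, p0, `+`)
  vol <- pi * radius^2 * L
  list(pts = pts, w = vol / nrow(gr), volume = vol)
}

#' Distribute venous branch volumes over the voxel grid
#'
#' Every venous branch is a cylinder at its strained diameter around the
#' 1D centerline, represented as a dense cloud of uniformly spaced points
#' of configurable unit volume; points are binned to voxels, so the venous
#' signal a voxel receives is proportional to the branch blood volume it
#' contains.
#'
#' @param vein venous `svi_tree`.
#' @param perf `svi_perfusion` (for strained diameters).
#' @param grid `svi_voxel_grid`.
#' @param config an [svi_config()] (`imaging$vein_point_volume_mm3`).
#' @return the grid with `vein_weights` (voxels x branches, mm^3) and the
#'   audit `vein_volume_audit`.
#' @export
voxelize_veins <- function(vein, perf, grid, config = svi_config()) {
  pv <- config$imaging$vein_point_volume_mm3
  nb <- nrow(vein)
  ii <- vector("list", nb); jj <- vector("list", nb); xx <- vector("list", nb)
  total <- 0; lattice_vol <- 0
  for (b in seq_len(nb)) {
    cl <- cylinder_lattice(
      c(vein$x0[b], vein$y0[b], vein$z0[b]),
      c(vein$x1[b], vein$y1[b], vein$z1[b]),
      perf$vein$D_mm[b] / 2, pv)
    if (is.null(cl)) next
    total <- total + cl$volume
    lattice_vol <- lattice_vol + nrow(cl$pts) * pv
    id <- points_to_voxel(grid, cl$pts)
    ok <- !is.na(id)
    if (!any(ok)) next
    tab <- table(id[ok])
    ii[[b]] <- as.integer(names(tab))
    jj[[b]] <- rep(b, length(tab))
    # every point carries the unit point volume
    xx[[b]] <- as.numeric(tab) * pv
  }
  W <- Matrix::sparseMatrix(
    i = as.integer(unlist(ii)), j = as.integer(unlist(jj)),
    x = as.numeric(unlist(xx)), dims = c(nrow(grid$voxels), nb))
  grid$vein_weights <- W
  # lattice fidelity: point count x point volume against analytic volume
  grid$vein_volume_audit <- abs(lattice_vol - total) / total
  # fraction of venous blood lying in lung voxels (hilar vessels fall
  # outside and are excluded with their low-fill voxels)
  grid$vein_in_lung_fraction <- sum(W) / total
  grid
}

#' Voxel venous signal series
#'
#' @param grid grid after [voxelize_veins()].
#' @param venous an `svi_venous_field`.
#' @param config an [svi_config()] (solubility).
#' @return matrix (voxels x breaths): branch blood volume in the voxel
#'   times dissolved O2 concentration (solubility x PO2).
#' @export
voxel_venous_series <- function(grid, venous, config = svi_config()) {
  sig <- config$gas$sigma_O2_mmol_L_mmHg / 1e6  # mmol per mm^3 per mmHg
  as.matrix(grid$vein_weights %*% (venous$series * sig))
}

#' Flag voxels below the tissue fill threshold
#'
#' Voxels less than half filled with lung tissue are excluded from further
#' analysis (partial-volume removal at the lung edge); the rule is strictly
#' "less than", so a voxel exactly at the threshold is retained.
#'
#' @param grid `svi_voxel_grid`.
#' @param threshold fill threshold (default from the grid, 0.5).
#' @return the grid with a logical `retained` column on the voxel table.
#' @export
apply_fill_filter <- function(grid, threshold = grid$fill_threshold) {
  grid$voxels$retained <- !(grid$voxels$fill < threshold)
  grid
}

#' Synthetic end-expiratory lung-volume change series
#'
#' Seeded draws from a normal distribution truncated at the stated maximum
#' magnitude, emulating the per-image EELV changes recorded in a poorly
#' gated SVI experiment (about 9 +/- 12% with a 40% maximum).
#'
#' @param n number of images (breaths).
#' @param mean,sd,max distribution parameters (fractions).
#' @param seed integer seed.
#' @param shuffle also return a reshuffled copy (used for a second
#'   subject).
#' @return numeric vector of length `n` (fractional EELV change per image).
#' @export
generate_eelv_series <- function(n = 220, mean = 0.09, sd = 0.12,
                                 max = 0.40, seed = 1L, shuffle = FALSE) {
  set.seed(as.integer(seed))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * n, mean, sd)
    out <- c(out, x[abs(x) <= max])
  }
  out <- out[seq_len(n)]
  if (shuffle) out <- sample(out)
  out
}

#' Simulate in-plane image misalignment of a sagittal slice
#'
#' For every image (breath) the slice is stretched along the cranio-caudal
#' axis with the apex fixed and the diaphragm edge displaced downward until
#' the slice volume change matches the prescribed EELV change to within the
#' relative tolerance; acinar locations and volumes (and venous point
#' clouds) follow the deformation, signals are re-binned on the original
#' voxel grid, and tissue displaced outside the initial lung boundary is
#' discarded.
#'
#' @param acini `svi_acini` restricted to the slice (or whole lung).
#' @param tissue_signal matrix (acini x breaths) per-acinus signal.
#' @param grid `svi_voxel_grid` (the initial, undeformed grid) after
#'   [voxelize_tissue()] so the initial lung voxel set is known.
#' @param eelv fractional EELV change per image, length = breaths.
#' @param config an [svi_config()].
#' @param vein,perf,venous optional venous tree, perfusion and venous field
#'   to include the venous signal in the displaced stack.
#' @param vol_tol relative tolerance on the achieved volume change.
#' @return list with `series` (voxels x breaths, displaced volume-weighted
#'   mean concentration), `achieved` volume change per image, `stretch`
#'   factors, and `valid_frac` (per voxel, the fraction of images in which
#'   it contains lung; voxels that empty in some images sit at the moving
#'   boundary and are excluded from analysis).
#' @export
simulate_misalignment <- function(acini, tissue_signal, grid, eelv,
                                  config = svi_config(),
                                  vein = NULL, perf = NULL, venous = NULL,
                                  vol_tol = config$misalignment$volume_tol,
                                  intensive = TRUE) {
  nbreath <- ncol(tissue_signal)
  if (length(eelv) != nbreath)
    stop("EELV series length must match the number of images", call. = FALSE)
  n <- nrow(acini)
  z_apex <- max(grid$voxels$z[grid$voxels$fill > 0]) + grid$voxel_mm[3] / 2

  # precompute undeformed sphere lattices (unit spheres scaled per breath)
  spacing <- config$imaging$sphere_sample_spacing_mm
  base_pts <- vector("list", n)
  for (i in seq_len(n)) {
    r <- (3 * acini$V0_mL[i] * 1000 / (4 * pi))^(1 / 3)
    base_pts[[i]] <- sphere_lattice(r, spacing)
  }
  npts <- vapply(base_pts, nrow, integer(1))
  ac_of_pt <- rep(seq_len(n), npts)
  pts0 <- do.call(rbind, base_pts) +
    cbind(rep(acini$x, npts), rep(acini$y, npts), rep(acini$z, npts))
  w0 <- rep(acini$V0_mL * 1000 / npts, npts)

  vein_pts <- NULL
  if (!is.null(vein)) {
    pvol <- config$imaging$vein_point_volume_mm3
    vp <- vector("list", nrow(vein))
    for (b in seq_len(nrow(vein))) {
      cl <- cylinder_lattice(
        c(vein$x0[b], vein$y0[b], vein$z0[b]),
        c(vein$x1[b], vein$y1[b], vein$z1[b]),
        perf$vein$D_mm[b] / 2, pvol)
      if (is.null(cl)) next
      vp[[b]] <- cbind(cl$pts, b, cl$w)
    }
    vein_pts <- do.call(rbind, vp)
  }
  sigma_mm3 <- config$gas$sigma_O2_mmol_L_mmHg / 1e6

  # per-volume concentrations: the voxel signal is the volume-weighted mean
  # over whatever tissue and blood occupy the voxel in each image, so that
  # in-plane motion exchanges contributing units (pseudo-unit mixing)
  # rather than modulating the amplitude
  conc_tissue <- tissue_signal / (acini$V0_mL * 1000)

  nvox <- nrow(grid$voxels)
  series <- matrix(0, nvox, nbreath)
  has_content <- matrix(FALSE, nvox, nbreath)
  vfrac_min <- matrix(1, nvox, 1)
  vfrac_max <- matrix(0, nvox, 1)
  achieved <- numeric(nbreath)
  stretch <- numeric(nbreath)
  for (k in seq_len(nbreath)) {
    target <- eelv[k]
    lam <- 1 + target
    it <- 0L
    repeat {
      it <- it + 1L
      got <- lam - 1  # uniform cranio-caudal stretch scales volume by lam
      if (abs(got - target) <= vol_tol * max(abs(target), 1e-6) || it > 25L)
        break
      lam <- lam * (1 + target) / (1 + got)
    }
    if (abs(got - target) > vol_tol * max(abs(target), 1e-6))
      stop("misalignment search failed to reach the target volume change",
           call. = FALSE)
    stretch[k] <- lam
    achieved[k] <- got
    zz <- z_apex - lam * (z_apex - pts0[, 3])
    id <- points_to_voxel(grid, cbind(pts0[, 1], pts0[, 2], zz))
    ok <- !is.na(id)
    num <- rowsum(w0[ok] * conc_tissue[ac_of_pt[ok], k], id[ok])
    den <- rowsum(w0[ok], id[ok])
    if (!is.null(vein_pts)) {
      zzv <- z_apex - lam * (z_apex - vein_pts[, 3])
      idv <- points_to_voxel(grid, cbind(vein_pts[, 1], vein_pts[, 2], zzv))
      okv <- !is.na(idv)
      numv <- rowsum(vein_pts[okv, 5] * sigma_mm3 *
                       venous$series[vein_pts[okv, 4], k], idv[okv])
      denv <- rowsum(vein_pts[okv, 5], idv[okv])
      iv <- as.integer(rownames(numv))
      add_num <- numeric(nvox); add_den <- numeric(nvox)
      add_num[as.integer(rownames(num))] <- num[, 1]
      add_den[as.integer(rownames(den))] <- den[, 1]
      add_num[iv] <- add_num[iv] + numv[, 1]
      add_den[iv] <- add_den[iv] + denv[, 1]
      series[, k] <- if (intensive)
        ifelse(add_den > 0, add_num / add_den, 0) else add_num
      has_content[, k] <- add_den > 0
      vf <- numeric(nvox)
      vf[iv] <- denv[, 1]
      vf <- ifelse(add_den > 0, vf / add_den, 0)
      vfrac_min[, 1] <- pmin(vfrac_min[, 1], vf)
      vfrac_max[, 1] <- pmax(vfrac_max[, 1], vf)
    } else {
      iid <- as.integer(rownames(num))
      series[iid, k] <- if (intensive) num[, 1] / den[, 1] else num[, 1]
      has_content[iid, k] <- TRUE
    }
  }
  list(series = series, achieved = achieved, stretch = stretch,
       valid_frac = rowMeans(has_content),
       vein_frac_range = if (is.null(vein_pts)) rep(0, nvox) else
         pmax(vfrac_max[, 1] - vfrac_min[, 1], 0))
}
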