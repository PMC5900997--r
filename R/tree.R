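#' Branching tree networks
#'
#' A `svi_tree` is a data frame of directed 1D branches (one row per branch)
#' with columns `id`, `parent` (0 for the root), start/end coordinates
#' `x0,y0,z0,x1,y1,z1` (mm), `length_mm`, `radius_mm`, `order` (Strahler),
#' `terminal` (logical) and `lung`. Branches are stored in topological order
#' (every parent precedes its children). The tree kind (`"airway"`,
#' `"artery"` or `"vein"`) is kept in the `kind` attribute.
#'
#' @param branches data frame with at least `id`, `parent`, coordinates and
#'   `radius_mm`; `length_mm`, `order` and `terminal` are derived if absent.
#' @param kind tree kind.
#' @return validated `svi_tree`.
#' @export
svi_tree <- function(branches, kind = c("airway", "artery", "vein")) {
  kind <- match.arg(kind)
  b <- as.data.frame(branches)
  if (is.null(b$length_mm))
    b$length_mm <- sqrt((b$x1 - b$x0)^2 + (b$y1 - b$y0)^2 + (b$z1 - b$z0)^2)
  if (is.null(b$terminal))
    b$terminal <- !(b$id %in% b$parent)
  if (is.null(b$order))
    b$order <- strahler_order(b)
  if (is.null(b$lung)) b$lung <- NA_character_
  attr(b, "kind") <- kind
  class(b) <- c("svi_tree", "data.frame")
  validate_tree(b)
  b
}

#' @export
print.svi_tree <- function(x, ...) {
  cat("<svi_tree:", attr(x, "kind"), "> ", nrow(x), " branches, ",
      sum(x$terminal), " terminals\n", sep = "")
  invisible(x)
}

tree_kind <- function(tree) attr(tree, "kind")

validate_tree <- function(b) {
  if (sum(b$parent == 0) != 1) stop("tree must have a single root")
  if (any(b$length_mm <= 0)) stop("all branch lengths must be positive")
  if (any(b$radius_mm <= 0)) stop("all branch radii must be positive")
  idx <- match(b$parent, b$id)
  if (any(is.na(idx) & b$parent != 0)) stop("dangling parent reference")
  ok <- which(b$parent != 0)
  if (any(idx[ok] >= ok))
    stop("branches must be stored parents-first")
  # connectivity/acyclicity: walking parents must reach the root from
  # every branch without revisiting (guaranteed by parents-first storage)
  invisible(b)
}

strahler_order <- function(b) {
  n <- nrow(b)
  ord <- integer(n)
  children <- split(seq_len(n), factor(b$parent, levels = b$id))
  for (i in rev(seq_len(n))) {
    kids <- children[[as.character(b$id[i])]]
    if (length(kids) == 0) {
      ord[i] <- 1L
    } else {
      m <- max(ord[kids])
      ord[i] <- if (sum(ord[kids] == m) > 1) m + 1L else m
    }
  }
  ord
}

#' Grow a conducting airway tree by volume-filling branching
#'
#' Implements recursive center-of-mass bisection: uniformly seeded target
#' points in each lung are split by a plane through the parent direction,
#' and a daughter branch grows toward each half's center of mass, advancing
#' a configurable fraction of the distance with a branching-angle cap. Each
#' target point ends up with exactly one terminal branch ending on it, so
#' the tree has exactly `n_terminals` terminals, all inside the host.
#'
#' @param host an `svi_host`.
#' @param n_terminals total number of terminal branches (>= 2).
#' @param seed integer seed for the target point clouds.
#' @param config an [svi_config()]; `tree` options used are
#'   `branching_fraction`, `angle_cap_deg`, `min_length_mm`, the airway root
#'   diameter and the per-Strahler-order diameter ratio.
#' @return an `svi_tree` of kind `"airway"`.
#' @export
grow_airway_tree <- function(host, n_terminals, seed = 1L,
                             config = svi_config()) {
  stopifnot(inherits(host, "svi_host"))
  if (n_terminals < 2) stop("n_terminals must be at least 2", call. = FALSE)
  tr <- config$tree
  frac <- tr$branching_fraction
  cap <- tr$angle_cap_deg * pi / 180
  min_len <- tr$min_length_mm

  vols <- vapply(host$lungs, function(l) prod(l$semi), numeric(1))
  n_right <- max(1L, round(n_terminals * vols[["right"]] / sum(vols)))
  if (n_right >= n_terminals) n_right <- n_terminals - 1L
  n_pts <- c(right = n_right, left = n_terminals - n_right)

  env <- new.env()
  env$rows <- vector("list", 4 * n_terminals)
  env$n <- 0L
  add_branch <- function(parent, p0, p1, lung) {
    env$n <- env$n + 1L
    env$rows[[env$n]] <- c(env$n, parent, p0, p1)
    env$n
  }

  clamp_dir <- function(dir, parent_dir, cap) {
    dir <- dir / sqrt(sum(dir^2))
    pd <- parent_dir / sqrt(sum(parent_dir^2))
    ang <- acos(max(-1, min(1, sum(dir * pd))))
    if (ang <= cap) return(dir)
    # rotate dir toward the parent direction until the cap is met
    perp <- dir - sum(dir * pd) * pd
    np <- sqrt(sum(perp^2))
    if (np < 1e-12) return(pd)
    perp <- perp / np
    cos(cap) * pd + sin(cap) * perp
  }

  grow <- function(pts, start, parent_dir, parent_id, lung) {
    if (nrow(pts) == 1) {
      p1 <- pts[1, ]
      if (sqrt(sum((p1 - start)^2)) < 1e-9) p1 <- start + parent_dir * min_len
      add_branch(parent_id, start, p1, lung)
      return(invisible(NULL))
    }
    com <- colMeans(pts)
    spread <- max(apply(pts, 2, function(v) diff(range(v))))
    if (spread < min_len)
      stop("n_terminals exceeds the packing capacity of the host at the ",
           "minimum branch length limit (", min_len, " mm)", call. = FALSE)
    # split plane contains the parent direction; its normal is the dominant
    # spread direction perpendicular to the parent
    cen <- sweep(pts, 2, com)
    proj_par <- cen %*% parent_dir
    resid <- cen - proj_par %*% t(parent_dir)
    sv <- svd(resid, nu = 0, nv = 1)
    nrm <- sv$v[, 1]
    s <- as.numeric(cen %*% nrm)
    ord <- order(s)
    half <- length(s) %/% 2
    groups <- list(ord[seq_len(half)], ord[-seq_len(half)])
    for (g in groups) {
      sub <- pts[g, , drop = FALSE]
      target <- colMeans(sub)
      d <- target - start
      dist <- sqrt(sum(d^2))
      if (length(g) == 1) {
        # terminal branch ends exactly on its seed point
        end <- if (dist < 1e-9) start + parent_dir * min_len else sub[1, ]
        add_branch(parent_id, start, end, lung)
        next
      }
      dir <- if (dist < 1e-12) parent_dir else clamp_dir(d / dist, parent_dir, cap)
      len <- max(frac * dist, min_len)
      end <- start + dir * len
      id <- add_branch(parent_id, start, end, lung)
      grow(sub, end, dir, id, lung)
    }
    invisible(NULL)
  }

  bb <- host_bbox(host)
  z_top <- bb["hi", 3]
  carina <- c(0, 0, z_top - 15)
  add_branch(0L, c(0, 0, z_top + 40), carina, NA_character_)

  clouds <- list(
    right = sample_lung_points(host, "right", n_pts[["right"]], seed,
                               min_sep = 2 * min_len),
    left = sample_lung_points(host, "left", n_pts[["left"]], seed + 1000L,
                              min_sep = 2 * min_len)
  )
  for (lung in c("right", "left")) {
    pts <- clouds[[lung]]
    com <- colMeans(pts)
    d <- com - carina
    dir <- d / sqrt(sum(d^2))
    end <- carina + frac * sqrt(sum(d^2)) * dir
    id <- add_branch(1L, carina, end, lung)
    grow(pts, end, dir, id, lung)
  }

  m <- do.call(rbind, env$rows[seq_len(env$n)])
  b <- data.frame(
    id = as.integer(m[, 1]), parent = as.integer(m[, 2]),
    x0 = m[, 3], y0 = m[, 4], z0 = m[, 5],
    x1 = m[, 6], y1 = m[, 7], z1 = m[, 8]
  )
  b$length_mm <- sqrt((b$x1 - b$x0)^2 + (b$y1 - b$y0)^2 + (b$z1 - b$z0)^2)
  b$terminal <- !(b$id %in% b$parent)
  b$order <- strahler_order(b)
  b$radius_mm <- diameter_by_order(b$order, tr$airway_root_diameter_mm,
                                   tr$airway_diameter_ratio) / 2
  b$lung <- NA_character_
  # tag lungs by walking down from the two main bronchi
  kids_of <- match(b$parent, b$id)
  lung_tag <- rep(NA_character_, nrow(b))
  mains <- which(b$parent == 1L)
  for (i in seq_along(mains))
    lung_tag[mains[i]] <- c("right", "left")[i]
  for (i in seq_len(nrow(b)))
    if (is.na(lung_tag[i]) && !is.na(kids_of[i]))
      lung_tag[i] <- lung_tag[kids_of[i]]
  b$lung <- lung_tag
  svi_tree(b, "airway")
}

diameter_by_order <- function(order, root_diameter, ratio) {
  d <- root_diameter * ratio^(order - max(order))
  if (any(d <= 0)) stop("diameter rule produced non-positive diameter")
  d
}

#' Derive matched arterial and venous trees from the airway tree
#'
#' The vascular trees share the airway centerlines exactly (same topology
#' and x, y, z coordinates) so that all three trees terminate at the same
#' acinus locations; only diameters differ, assigned per tree kind by a
#' Strahler-order geometric ratio, with veins a fixed factor wider than
#' arteries.
#'
#' @param airway an airway `svi_tree`.
#' @param config an [svi_config()] (fields `tree$artery_root_diameter_mm`,
#'   `tree$artery_diameter_ratio`, `tree$vein_artery_ratio`).
#' @return list with elements `artery` and `vein`.
#' @export
derive_vascular_trees <- function(airway, config = svi_config()) {
  stopifnot(inherits(airway, "svi_tree"))
  tr <- config$tree
  artery <- airway
  artery$radius_mm <- diameter_by_order(
    airway$order, tr$artery_root_diameter_mm, tr$artery_diameter_ratio) / 2
  attr(artery, "kind") <- "artery"
  vein <- artery
  vein$radius_mm <- artery$radius_mm * tr$vein_artery_ratio
  if (any(vein$radius_mm <= 0)) stop("diameter rule produced non-positive diameter")
  attr(vein, "kind") <- "vein"
  list(artery = artery, vein = vein)
}

#' Place one acinar unit at each terminal branch
#'
#' Acini sit exactly at the end coordinate of their terminal branch. FRC gas
#' volumes `V0` are initialized uniformly such that the acinar sum plus the
#' anatomical dead space (sum of airway branch cylinder volumes) equals the
#' host FRC volume; compliances share a configured total with optional
#' log-normal unit-to-unit variability. The gravitational rescaling of `V0`
#' is applied afterwards by [apply_gravity()].
#'
#' @param airway an airway `svi_tree`.
#' @param host an `svi_host`.
#' @param config an [svi_config()].
#' @param seed integer seed for compliance variability.
#' @return data frame of class `svi_acini`: `id`, `branch_id`, coordinates,
#'   `V0_mL`, `C_mL_cmH2O`, `Pe_cmH2O`, `vt_mL`, `vb_mL`.
#' @export
place_acini <- function(airway, host, config = svi_config(), seed = 1L) {
  term <- airway[airway$terminal, ]
  n <- nrow(term)
  ds <- dead_space_mL(airway)
  v0 <- (host$frc_mL - ds) / n
  if (v0 <= 0)
    stop("anatomical dead space exceeds the host FRC volume", call. = FALSE)
  set.seed(as.integer(seed) + 7L)
  cv <- config$mechanics$compliance_cv
  cmul <- if (cv > 0) exp(stats::rnorm(n, -cv^2 / 2, cv)) else rep(1, n)
  ctot <- config$mechanics$compliance_total_mL_per_cmH2O
  ac <- data.frame(
    id = seq_len(n),
    branch_id = term$id,
    x = term$x1, y = term$y1, z = term$z1,
    V0_mL = rep(v0, n),
    C_mL_cmH2O = ctot * cmul / sum(cmul),
    Pe_cmH2O = rep(0, n),
    vt_mL = rep(config$gas$tissue_volume_total_mL / n, n),
    vb_mL = rep(config$perfusion$cap_volume_total_mL / n, n),
    lung = term$lung
  )
  attr(ac, "dead_space_mL") <- ds
  class(ac) <- c("svi_acini", "data.frame")
  ac
}

#' Anatomical dead space of a tree (mL): sum of branch cylinder volumes
#' @param tree an `svi_tree`.
#' @export
dead_space_mL <- function(tree) {
  sum(pi * tree$radius_mm^2 * tree$length_mm) / 1000
}

#' @export
print.svi_acini <- function(x, ...) {
  cat("<svi_acini> ", nrow(x), " units, total V0 ",
      round(sum(x$V0_mL), 1), " mL\n", sep = "")
  invisible(x)
}
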