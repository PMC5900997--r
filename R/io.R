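#' Write and read tree networks as edge-list CSV
#'
#' Columns: `branch_id`, `parent_id`, `x0,y0,z0,x1,y1,z1`, `radius_mm`,
#' `kind`.
#'
#' @param tree an `svi_tree`.
#' @param path file path.
#' @return `write_tree_csv` returns `path` invisibly; `read_tree_csv`
#'   returns the `svi_tree`.
#' @export
write_tree_csv <- function(tree, path) {
  df <- data.frame(
    branch_id = tree$id, parent_id = tree$parent,
    x0 = tree$x0, y0 = tree$y0, z0 = tree$z0,
    x1 = tree$x1, y1 = tree$y1, z1 = tree$z1,
    radius_mm = tree$radius_mm, kind = tree_kind(tree)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tree_csv
#' @export
read_tree_csv <- function(path) {
  df <- utils::read.csv(path)
  svi_tree(
    data.frame(id = df$branch_id, parent = df$parent_id,
               x0 = df$x0, y0 = df$y0, z0 = df$z0,
               x1 = df$x1, y1 = df$y1, z1 = df$z1,
               radius_mm = df$radius_mm),
    kind = df$kind[1]
  )
}

#' Export a tree as GraphML
#'
#' Nodes are branch endpoints with coordinates; edges carry length and
#' radius.
#'
#' @param tree an `svi_tree`.
#' @param path file path.
#' @export
write_tree_graphml <- function(tree, path) {
  n_nodes <- nrow(tree) + 1L
  from <- ifelse(tree$parent == 0L, 1L, tree$parent + 1L)
  to <- tree$id + 1L
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  xyz <- rbind(as.matrix(tree[1, c("x0", "y0", "z0")]),
               as.matrix(tree[, c("x1", "y1", "z1")]))
  igraph::V(g)$x <- xyz[, 1]; igraph::V(g)$y <- xyz[, 2]
  igraph::V(g)$z <- xyz[, 3]
  igraph::E(g)$length_mm <- tree$length_mm
  igraph::E(g)$radius_mm <- tree$radius_mm
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write the per-acinus ventilation solution as CSV
#' @param vent `svi_ventilation`.
#' @param path file path.
#' @export
write_acinar_csv <- function(vent, path) {
  utils::write.csv(vent$acini, path, row.names = FALSE)
  invisible(path)
}

#' Write a voxel quantity as NIfTI
#'
#' Fills a 3D array over the full grid (non-lung voxels are NA) with voxel
#' sizes recorded in the header.
#'
#' @param grid `svi_voxel_grid`.
#' @param values per-voxel values, aligned with `grid$voxels`.
#' @param path output `.nii`/`.nii.gz` path.
#' @export
write_svi_nifti <- function(grid, values, path) {
  arr <- array(NA_real_, dim = grid$dims)
  arr[cbind(grid$voxels$ix, grid$voxels$iy, grid$voxels$iz)] <- values
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$voxel_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a machine-readable run summary as JSON
#'
#' @param run an `svi_run`.
#' @param path file path.
#' @export
write_run_summary_json <- function(run, path) {
  s <- list(
    seed = run$seed,
    n_acini = nrow(run$acini),
    n_voxels_retained = sum(run$voxel$retained),
    discard_rate = run$voxel$discard_rate,
    comparison = run$comparison,
    audits = list(
      junction_residual_air = run$audits$ventilation$junction_residual,
      junction_residual_blood = run$audits$perfusion$junction_residual,
      o2_balance_worst = max(run$audits$o2_balance_rel),
      tissue_volume = run$audits$tissue_volume,
      vein_volume = run$audits$vein_volume
    )
  )
  jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
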