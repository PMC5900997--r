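#' Peclet number of a branch
#'
#' `Pe = L u / D`: ratio of advective to diffusive transport over a branch.
#' Branches with `Pe >= 5` are treated as advection-only by the
#' operator-split transport scheme.
#'
#' @param length_mm branch length (mm).
#' @param u_mm_s time-averaged air speed (mm/s).
#' @param D_mm2_s binary gas diffusion coefficient (mm^2/s).
#' @export
peclet <- function(length_mm, u_mm_s, D_mm2_s) {
  if (any(D_mm2_s <= 0)) stop("diffusivity must be positive", call. = FALSE)
  length_mm * abs(u_mm_s) / D_mm2_s
}

#' Discretize a tree into a 1D nodal mesh
#'
#' Nodes are placed along every branch at approximately `spacing_mm`
#' intervals (at least one element per branch); junction nodes are shared
#' between a parent and its children so concentration is continuous across
#' bifurcations. Each node carries a lumped gas volume (sum of adjacent
#' half-element cylinder volumes).
#'
#' @param tree an `svi_tree`.
#' @param spacing_mm target node spacing (mm).
#' @param coarsen_by_radius widen the spacing to the branch radius in the
#'   proximal airways, so CFL sub-stepping is not dominated by needlessly
#'   fine cells in fast, well-mixed branches.
#' @return an `svi_airway_mesh`.
#' @export
discretize_tree <- function(tree, spacing_mm = 3, coarsen_by_radius = TRUE) {
  nb <- nrow(tree)
  end_node <- integer(nb)
  elems <- vector("list", nb)
  n_nodes <- 1L  # node 1: root inlet
  for (b in seq_len(nb)) {
    sn <- if (tree$parent[b] == 0L) 1L else end_node[match(tree$parent[b], tree$id)]
    dx_b <- if (coarsen_by_radius) max(spacing_mm, tree$radius_mm[b]) else spacing_mm
    nel <- max(1L, round(tree$length_mm[b] / dx_b))
    ids <- c(sn, n_nodes + seq_len(nel))
    n_nodes <- n_nodes + nel
    end_node[b] <- ids[length(ids)]
    elems[[b]] <- cbind(i = ids[-length(ids)], j = ids[-1],
                        branch = b,
                        dx = tree$length_mm[b] / nel,
                        area = pi * tree$radius_mm[b]^2)
  }
  el <- do.call(rbind, elems)
  vol <- numeric(n_nodes)
  half <- el[, "area"] * el[, "dx"] / 2
  vol_i <- tapply(c(half, half), c(el[, "i"], el[, "j"]), sum)
  vol[as.integer(names(vol_i))] <- vol_i
  term_rows <- which(tree$terminal)
  mesh <- list(
    n_nodes = n_nodes,
    elem = el,
    volume_mm3 = vol,
    root_node = 1L,
    end_node = end_node,
    term_nodes = end_node[term_rows],
    term_branches = tree$id[term_rows],
    branch_length = tree$length_mm,
    branch_area = pi * tree$radius_mm^2
  )
  class(mesh) <- "svi_airway_mesh"
  mesh
}

# Assemble the finite-volume upwind advection operator for fixed per-branch
# velocities. Returns dc/dt = M c plus boundary metadata; conservative by
# construction (every internal flux appears once as a gain and once as a
# loss).
build_advection <- function(mesh, u_branch, cfl = 0.9) {
  el <- mesh$elem
  Q <- u_branch[el[, "branch"]] * el[, "area"]
  Qp <- pmax(Q, 0)  # flow i -> j
  Qm <- pmax(-Q, 0) # flow j -> i
  V <- mesh$volume_mm3
  i <- el[, "i"]; j <- el[, "j"]
  trip_i <- c(i, j, j, i)
  trip_j <- c(i, i, j, j)
  trip_x <- c(-Qp / V[i], Qp / V[j], -Qm / V[j], Qm / V[i])
  # boundary outflows: terminal nodes into acini (inspiration) and the
  # inlet node to ambient (expiration)
  tn <- mesh$term_nodes
  Q_term <- u_branch[mesh$term_branches] * mesh$branch_area[mesh$term_branches]
  insp_term <- Q_term > 0
  if (any(insp_term)) {
    trip_i <- c(trip_i, tn[insp_term])
    trip_j <- c(trip_j, tn[insp_term])
    trip_x <- c(trip_x, -Q_term[insp_term] / V[tn[insp_term]])
  }
  root_Q <- u_branch[1] * mesh$branch_area[1]
  if (root_Q < 0) {
    trip_i <- c(trip_i, mesh$root_node)
    trip_j <- c(trip_j, mesh$root_node)
    trip_x <- c(trip_x, root_Q / V[mesh$root_node])
  }
  M <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                            dims = c(mesh$n_nodes, mesh$n_nodes))
  # expiration: advective influx from the acini into the terminal nodes
  exp_term <- which(Q_term < 0)
  B <- Matrix::sparseMatrix(
    i = tn[exp_term], j = exp_term,
    x = -Q_term[exp_term] / V[tn[exp_term]],
    dims = c(mesh$n_nodes, length(tn)))
  out_rate <- -Matrix::diag(M)
  dt_cfl <- cfl / max(out_rate, 1e-12)
  list(M = M, B = B, dt_cfl = dt_cfl, Q_term = Q_term, root_Q = root_Q,
       inflow = root_Q > 0)
}

# Assemble and factor the implicit Galerkin linear-element diffusion system
# over the low-Peclet part of the mesh. High-Peclet branches (Pe >= cutoff)
# are excluded entirely, which both implements the functional split and
# keeps the step conservative at the split boundary. Dirichlet rows are
# imposed at the inlet during inspiration and at terminal nodes during
# expiration.
build_diffusion <- function(mesh, u_branch, dt, D_mm2_s, cutoff = 5,
                            dirichlet = TRUE) {
  pe <- peclet(mesh$branch_length, u_branch, D_mm2_s)
  keep <- pe < cutoff
  el <- mesh$elem[keep[mesh$elem[, "branch"]], , drop = FALSE]
  if (nrow(el) == 0) return(NULL)
  nodes <- sort(unique(c(el[, "i"], el[, "j"])))
  idx <- match(seq_len(mesh$n_nodes), nodes)
  n <- length(nodes)
  li <- idx[el[, "i"]]; lj <- idx[el[, "j"]]
  a <- el[, "area"]; dx <- el[, "dx"]
  m_od <- a * dx / 6; m_d <- a * dx / 3
  k_od <- -D_mm2_s * a / dx; k_d <- D_mm2_s * a / dx
  Mfe <- Matrix::sparseMatrix(
    i = c(li, lj, li, lj), j = c(li, lj, lj, li),
    x = c(m_d, m_d, m_od, m_od), dims = c(n, n))
  K <- Matrix::sparseMatrix(
    i = c(li, lj, li, lj), j = c(li, lj, lj, li),
    x = c(k_d, k_d, k_od, k_od), dims = c(n, n))
  A <- Mfe + dt * K
  root_Q <- u_branch[1] * mesh$branch_area[1]
  dir_nodes <- if (!dirichlet) integer(0)
  else if (root_Q >= 0) mesh$root_node else mesh$term_nodes
  dir_local <- idx[dir_nodes]
  dir_local_ok <- dir_local[!is.na(dir_local)]
  dir_global <- dir_nodes[!is.na(dir_local)]
  if (length(dir_local_ok)) {
    A[dir_local_ok, ] <- 0
    A[cbind(dir_local_ok, dir_local_ok)] <- 1
  }
  list(lu = Matrix::lu(A), Mfe = Mfe, nodes = nodes, idx = idx,
       dir_local = dir_local_ok, dir_global = dir_global)
}

#' Create an airway gas-transport state
#'
#' Holds nodal O2 fraction on the mesh together with per-branch air
#' velocities, the breathing phase and the inspired O2 fraction; transport
#' operators are cached and rebuilt when the phase changes.
#'
#' @param mesh an `svi_airway_mesh`.
#' @param c0 initial nodal O2 fraction (scalar or vector).
#' @param u_insp,u_exp signed per-branch air velocities (mm/s) during
#'   inspiration and expiration (positive = root-to-terminal).
#' @param config an [svi_config()] (group `transport` and `gas$D_mm2_s`).
#' @return an `svi_gas_state`.
#' @export
airway_gas_state <- function(mesh, c0, u_insp, u_exp, config = svi_config()) {
  st <- list(
    mesh = mesh,
    c = rep_len(c0, mesh$n_nodes),
    u_insp = u_insp, u_exp = u_exp,
    phase = "inspiration", fio2 = 0.21,
    c_ac = rep(mean(c0), length(mesh$term_nodes)),
    D = config$gas$D_mm2_s,
    cutoff = config$transport$peclet_cutoff,
    cfl = config$transport$cfl,
    dt = config$transport$dt_s,
    diffusion = isTRUE(config$transport$diffusion),
    ops = NULL, diff_ops = NULL
  )
  class(st) <- "svi_gas_state"
  st
}

#' Set phase boundary conditions on a gas state
#'
#' Inspiration: tracheal inlet held at the inspired fraction, zero-flux at
#' the terminal bronchioles. Expiration: terminal nodes follow their
#' acinar concentration, free outflow at the trachea.
#'
#' @param state an `svi_gas_state`.
#' @param phase `"inspiration"` or `"expiration"`.
#' @param fio2 inspired O2 fraction in `[0, 1]`.
#' @return the updated state.
#' @export
apply_boundaries <- function(state, phase = c("inspiration", "expiration"),
                             fio2 = state$fio2) {
  phase <- match.arg(phase)
  if (fio2 < 0 || fio2 > 1) stop("FIO2 must lie in [0, 1]", call. = FALSE)
  state$phase <- phase
  state$fio2 <- fio2
  state$ops <- NULL
  state$diff_ops <- NULL
  if (phase == "inspiration") state$c[state$mesh$root_node] <- fio2
  else state$c[state$mesh$term_nodes] <- state$c_ac
  state
}

ensure_ops <- function(state) {
  if (is.null(state$ops)) {
    u <- if (state$phase == "inspiration") state$u_insp else state$u_exp
    state$ops <- build_advection(state$mesh, u, state$cfl)
    state$diff_ops <- if (state$diffusion)
      build_diffusion(state$mesh, u, state$dt, state$D, state$cutoff)
  }
  state
}

# One conservative upwind advection + implicit Galerkin diffusion step.
# Returns the new nodal field plus the boundary mass fluxes (mm^3 of O2)
# exchanged with the acini and the ambient during the step.
advance_transport <- function(state, dt) {
  state <- ensure_ops(state)
  ops <- state$ops
  mesh <- state$mesh
  n_sub <- max(1L, ceiling(dt / ops$dt_cfl))
  h <- dt / n_sub
  cvec <- state$c
  tn <- mesh$term_nodes
  insp <- ops$inflow
  ac_mass <- numeric(length(tn))
  inlet_in <- 0; inlet_out <- 0
  Qt_pos <- pmax(ops$Q_term, 0)
  Qt_neg <- pmax(-ops$Q_term, 0)
  b_ac <- if (insp) NULL else as.numeric(ops$B %*% state$c_ac)
  for (s in seq_len(n_sub)) {
    if (insp) {
      cvec[mesh$root_node] <- state$fio2
      ac_mass <- ac_mass + Qt_pos * cvec[tn] * h
    } else {
      inlet_out <- inlet_out + abs(ops$root_Q) * cvec[mesh$root_node] * h
      ac_mass <- ac_mass - Qt_neg * state$c_ac * h
    }
    cvec <- cvec + h * as.numeric(ops$M %*% cvec)
    if (!insp) cvec <- cvec + h * b_ac
    if (insp) {
      inlet_in <- inlet_in + abs(ops$root_Q) * state$fio2 * h
      cvec[mesh$root_node] <- state$fio2
    }
  }
  dops <- state$diff_ops
  if (!is.null(dops)) {
    rhs <- as.numeric(dops$Mfe %*% cvec[dops$nodes])
    if (length(dops$dir_local))
      rhs[dops$dir_local] <- cvec[dops$dir_global]
    cvec[dops$nodes] <- as.numeric(Matrix::solve(dops$lu, rhs))
  }
  state$c <- cvec
  state$flux <- list(to_acini_mm3 = ac_mass, inlet_in_mm3 = inlet_in,
                     inlet_out_mm3 = inlet_out)
  state
}

#' Advance the airway O2 field by one operator-split transport step
#'
#' Step 1 advects the nodal field with a conservative finite-volume upwind
#' scheme, sub-stepped to satisfy the CFL bound implied by the fastest
#' node; step 2 applies implicit linear-element Galerkin diffusion seeded
#' with the advected field, on the low-Peclet part of the tree only
#' (branches with `Pe >= 5` are advection-only). Boundary mass exchanged
#' with the acini and the ambient during the step is reported in
#' `state$flux`.
#'
#' @param state an `svi_gas_state` (see [airway_gas_state()],
#'   [apply_boundaries()]).
#' @param dt time step (s).
#' @return the updated state.
#' @export
transport_step <- function(state, dt = state$dt) {
  stopifnot(inherits(state, "svi_gas_state"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  advance_transport(state, dt)
}

#' Total O2 volume held in the airway tree (mL)
#' @param state an `svi_gas_state`.
#' @export
tree_o2_mL <- function(state) {
  sum(state$mesh$volume_mm3 * state$c) / 1000
}
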