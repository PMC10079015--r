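#' Voxel grid for the simulation domain
#'
#' @param dims integer vector `(nx, ny, nz)` of voxel counts along each axis;
#'   the input wall, when present, is the `x = 0` face.
#' @param spacing voxel edge length (simulation length units, default 1);
#'   voxel volume is `spacing^3`.
#' @return Object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, spacing = 1) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 1), spacing > 0)
  structure(list(dims = dims, spacing = spacing, volume = spacing^3),
            class = "voxel_grid")
}

#' Communication parameters for a diffusible molecule
#'
#' Scalar constants of the screened diffusion model, shared by all ESMs: the
#' concentration field of molecule `m` obeys
#' `0 = beta * Laplacian(C) - alpha * C + eta / V_c`, where `eta` per voxel is
#' the secretion rate of the cell occupying it (`eta_basal` when its secreter
#' gene is OFF, `eta_active` when ON). `theta` expresses the receptor
#' activation threshold as a multiple of the basal reference concentration
#' (see [basal_reference_concentration()]); the effective interaction
#' distance `lambda = sqrt(beta / alpha)` is derived.
#'
#' @param alpha degradation rate (1/time), > 0.
#' @param beta diffusion coefficient (length^2/time), > 0.
#' @param eta_basal,eta_active secretion rates (amount/time),
#'   `eta_active >= eta_basal >= 0`.
#' @param theta receptor threshold factor (dimensionless), > 0.
#' @return Object of class `comm_params` with the inputs plus `lambda`.
#' @export
comm_params <- function(alpha = 1 / 45, beta = 5, eta_basal = 1,
                        eta_active = 5, theta = 11.5) {
  stopifnot(alpha > 0, beta > 0, eta_active >= eta_basal, eta_basal >= 0,
            theta > 0)
  structure(list(alpha = alpha, beta = beta, eta_basal = eta_basal,
                 eta_active = eta_active, theta = theta,
                 lambda = effective_interaction_distance(alpha, beta)),
            class = "comm_params")
}

#' Effective interaction distance of a diffusible molecule
#'
#' The length scale `lambda = sqrt(beta / alpha)` over which a secreted
#' molecule remains detectable before degradation outruns diffusion.
#'
#' @param alpha degradation rate (> 0).
#' @param beta diffusion coefficient (> 0).
#' @return `sqrt(beta / alpha)`.
#' @export
effective_interaction_distance <- function(alpha, beta) {
  stopifnot(alpha > 0, beta > 0)
  sqrt(beta / alpha)
}

# Linear index of voxel (x, y, z) in column-major (x fastest) order.
voxel_index <- function(dims, x, y, z) {
  x + (y - 1L) * dims[1] + (z - 1L) * dims[1] * dims[2]
}

# Cached solver for the screened-diffusion steady state on a voxel grid.
# Discretization: 7-point finite-difference Laplacian; Neumann walls by
# ghost-voxel reflection (neighbour term drops out); optional Dirichlet on
# the x = 0 face by fixing the ghost value, which adds beta/h^2 to the
# diagonal of wall-adjacent voxels and beta/h^2 * D to their right-hand side.
# The operator alpha*I - beta*Lap_h is symmetric positive definite for
# alpha > 0, so one sparse Cholesky factorization serves all right-hand
# sides of a run.
diffusion_solver <- function(grid, alpha, beta, dirichlet_wall = FALSE) {
  d <- grid$dims; h <- grid$spacing
  n <- prod(d)
  coef <- beta / h^2
  arr <- array(seq_len(n), dim = d)

  pair_idx <- function(a, b) cbind(as.vector(a), as.vector(b))
  prs <- rbind(
    if (d[1] > 1) pair_idx(arr[-d[1], , , drop = FALSE], arr[-1, , , drop = FALSE]),
    if (d[2] > 1) pair_idx(arr[, -d[2], , drop = FALSE], arr[, -1, , drop = FALSE]),
    if (d[3] > 1) pair_idx(arr[, , -d[3], drop = FALSE], arr[, , -1, drop = FALSE])
  )
  deg <- tabulate(c(prs[, 1], prs[, 2]), nbins = n)
  wall_idx <- as.vector(arr[1, , ])
  diag_vals <- alpha + coef * deg
  if (dirichlet_wall) diag_vals[wall_idx] <- diag_vals[wall_idx] + coef

  A <- Matrix::sparseMatrix(
    i = c(seq_len(n), prs[, 1], prs[, 2]),
    j = c(seq_len(n), prs[, 2], prs[, 1]),
    x = c(diag_vals, rep.int(-coef, 2 * nrow(prs))),
    dims = c(n, n), symmetric = FALSE
  )
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)

  list(
    grid = grid, alpha = alpha, beta = beta, coef = coef,
    dirichlet_wall = dirichlet_wall, wall_idx = wall_idx, n = n,
    solve = function(rhs) Matrix::solve(fac, rhs, system = "A")
  )
}

#' Steady-state concentration field of a diffusible molecule
#'
#' Solves `0 = beta * Laplacian(C) - alpha * C + eta / V_c` on the voxel grid
#' with zero-flux (Neumann) walls; optionally the `x = 0` face is a Dirichlet
#' wall held at `dirichlet_value` (the input-signal source when > 0, a sink
#' when 0). Deterministic given its inputs.
#'
#' @param grid a [voxel_grid()].
#' @param secretion nonnegative per-voxel secretion rates `eta` (array with
#'   `grid$dims`, or vector of length `prod(grid$dims)`).
#' @param params a [comm_params()] (only `alpha` and `beta` are used).
#' @param dirichlet_value optional fixed concentration on the `x = 0` face;
#'   `NULL` (default) keeps all six walls Neumann.
#' @return Nonnegative concentration array with dimensions `grid$dims`.
#' @export
solve_steady_state <- function(grid, secretion, params, dirichlet_value = NULL) {
  sec <- as.vector(secretion)
  stopifnot(length(sec) == prod(grid$dims), all(sec >= 0))
  sol <- diffusion_solver(grid, params$alpha, params$beta,
                          dirichlet_wall = !is.null(dirichlet_value))
  rhs <- sec / grid$volume
  if (!is.null(dirichlet_value)) {
    stopifnot(dirichlet_value >= 0)
    rhs[sol$wall_idx] <- rhs[sol$wall_idx] + sol$coef * dirichlet_value
  }
  array(as.numeric(sol$solve(rhs)), dim = grid$dims)
}

#' Basal reference concentration
#'
#' The steady-state concentration in a cell's own voxel when a single cell at
#' the domain centre secretes at the basal rate, with no other sources and
#' all-Neumann walls. The absolute receptor activation threshold is
#' `theta` times this value; computing it numerically on the same grid as the
#' community makes `theta` a pure (unit-free) factor.
#'
#' @param grid a [voxel_grid()].
#' @param params a [comm_params()].
#' @return Scalar concentration.
#' @export
basal_reference_concentration <- function(grid, params) {
  d <- grid$dims
  sec <- numeric(prod(d))
  ctr <- voxel_index(d, ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2))
  sec[ctr] <- params$eta_basal
  C <- solve_steady_state(grid, sec, params)
  C[[ctr]]
}

#' Calibrate the input-signal threshold for a target penetration depth
#'
#' Solves the input-molecule field with the Dirichlet wall active (value
#' `dirichlet_value`, no interior sources) and returns the absolute threshold
#' such that cells in layers `1..I` (counting voxel layers from the input
#' wall) sense the signal while deeper layers do not. The field decays
#' monotonically with distance from the wall, so any value strictly between
#' the layer-`I` and layer-`I+1` concentrations works; the geometric mean is
#' used to maximise the relative margin on both sides (when `I` equals the
#' community depth, `(1 - 1e-6)` times the layer-`I` value is returned).
#'
#' @param grid a [voxel_grid()].
#' @param params [comm_params()] of the input molecule (same `alpha`, `beta`
#'   as the ESMs).
#' @param I number of layers that must register the signal (`1 <= I <= depth`).
#' @param depth number of cell layers along the input axis.
#' @param dirichlet_value source strength on the input wall (default 100000).
#' @return Scalar absolute threshold; sensing is `concentration >= threshold`.
#' @export
calibrate_input_threshold <- function(grid, params, I, depth,
                                      dirichlet_value = 1e5) {
  stopifnot(I >= 1, I <= depth, depth <= grid$dims[1])
  C <- solve_steady_state(grid, numeric(prod(grid$dims)), params,
                          dirichlet_value = dirichlet_value)
  cy <- ceiling(grid$dims[2] / 2); cz <- ceiling(grid$dims[3] / 2)
  cI <- C[I, cy, cz]
  if (I < depth) sqrt(cI * C[I + 1L, cy, cz]) else (1 - 1e-6) * cI
}
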