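#' Simulation configuration
#'
#' Collects every scalar parameter of one community run. Defaults follow the
#' standard study conditions: `T = 1000` total timesteps of which
#' `T_W = 100` are warm-up, communication constants
#' `alpha = 1/45, beta = 5` (so `lambda = 15`), secretion rates 1 (basal) and
#' 5 (active), receptor threshold factor `theta = 11.5`, and an input-wall
#' Dirichlet source of 100000.
#'
#' @param N_r reservoir genes per cell (>= 1).
#' @param E number of ESMs (>= 0).
#' @param S number of strains (>= 1).
#' @param C number of cells; a perfect cube for `geometry = "cube"`,
#'   `n_layers * side^2` for `geometry = "layered"`.
#' @param L fraction of regulated genes wired to the input gene.
#' @param I input layers (`1..depth`; default: all layers sense the input).
#' @param O output layers counted from the far wall (default: all layers).
#' @param d readout delay in timesteps.
#' @param T,T_W total and warm-up timesteps (`T_W < T`).
#' @param geometry `"cube"` or `"layered"`.
#' @param n_layers layer count for layered geometry.
#' @param margin empty voxels added on every non-input wall. The community's
#'   bounding box is padded so that Neumann walls do not sit flush against
#'   cells and inflate local concentrations; the input wall stays flush.
#' @param comm a [comm_params()] shared by all ESMs and the input molecule.
#' @param dirichlet_value input-wall source strength when the signal bit is 1.
#' @param task a [task_spec()].
#' @param seed master seed; it spawns independent substreams for strain
#'   construction, strain assignment, initial states, the input signal and
#'   the readout split.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(N_r = 24, E = 5, S = 8, C = 125, L = 0.5,
                       I = NULL, O = NULL, d = 0, T = 1000, T_W = 100,
                       geometry = c("cube", "layered"), n_layers = 3,
                       margin = 1, comm = comm_params(),
                       dirichlet_value = 1e5,
                       task = task_spec("parity", 3), seed = 1L) {
  geometry <- match.arg(geometry)
  placement <- place_cells(geometry, C, n_layers)
  depth <- max(placement$layer)
  if (is.null(I)) I <- depth
  if (is.null(O)) O <- depth
  stopifnot(N_r >= 1, E >= 0, S >= 1, L >= 0, L <= 1, d >= 0,
            T_W < T, I >= 1, I <= depth, O >= 1, O <= depth, margin >= 0)
  if (T_W + task$w + d > T) stop("T_W + w + d exceeds T: no readout rows")
  structure(
    list(N_r = as.integer(N_r), E = as.integer(E), S = as.integer(S),
         C = as.integer(C), L = L, I = as.integer(I), O = as.integer(O),
         d = as.integer(d), T = as.integer(T), T_W = as.integer(T_W),
         geometry = geometry, n_layers = as.integer(n_layers),
         margin = as.integer(margin), comm = comm,
         dirichlet_value = dirichlet_value, task = task,
         seed = as.integer(seed), depth = depth),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$geometry, "community of", x$C, "cells (depth",
      x$depth, "),", x$N_r, "reservoir genes,", x$E, "ESMs,", x$S,
      "strains\n  L =", x$L, " I =", x$I, " O =", x$O, " d =", x$d,
      " T =", x$T, "(warm-up", x$T_W, ")  task:", format_task(x$task),
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Deterministic cell placement
#'
#' Cube geometry arranges `C = side^3` cells in a cube whose layers are
#' indexed along the input axis `x`; layered geometry stacks `n_layers`
#' equal square layers perpendicular to `x`. Layer 1 touches the input wall.
#'
#' @param geometry `"cube"` or `"layered"`.
#' @param C cell count.
#' @param n_layers layer count for layered geometry.
#' @return `data.frame` with columns `cell`, `x`, `y`, `z`, `layer`
#'   (`layer == x`), coordinates starting at 1.
#' @export
place_cells <- function(geometry = c("cube", "layered"), C, n_layers = 3) {
  geometry <- match.arg(geometry)
  C <- as.integer(C)
  stopifnot(C >= 1)
  if (geometry == "cube") {
    side <- as.integer(round(C^(1 / 3)))
    if (side^3 != C) stop("cube geometry needs a perfect-cube cell count, got ", C)
    depth <- side
  } else {
    stopifnot(n_layers >= 1, C %% n_layers == 0)
    side <- as.integer(round(sqrt(C / n_layers)))
    if (side^2 * n_layers != C) {
      stop("layered geometry needs C = n_layers * side^2, got ", C)
    }
    depth <- as.integer(n_layers)
  }
  g <- expand.grid(x = seq_len(depth), y = seq_len(side), z = seq_len(side))
  g <- g[order(g$x, g$y, g$z), , drop = FALSE]
  data.frame(cell = seq_len(C), x = g$x, y = g$y, z = g$z, layer = g$x,
             row.names = NULL)
}

#' Precomputed context for stepping a community
#'
#' Builds everything [community_step()] needs: cell placement on the padded
#' voxel grid, the strains and their assignment to cells, the cached
#' steady-state solvers (one all-Neumann operator shared by the ESMs, one
#' Dirichlet-wall operator for the input molecule), the cell-to-cell Green
#' matrix used to evaluate ESM concentrations at cell voxels, the basal
#' reference concentration and the calibrated thresholds.
#'
#' @param config a [sim_config()].
#' @return Object of class `community_context`.
#' @export
community_context <- function(config) {
  placement <- place_cells(config$geometry, config$C, config$n_layers)
  m <- config$margin
  dims <- c(max(placement$x) + m,
            max(placement$y) + 2L * m,
            max(placement$z) + 2L * m)
  grid <- voxel_grid(dims)
  cell_vox <- voxel_index(dims, placement$x, placement$y + m, placement$z + m)
  if (anyDuplicated(cell_vox)) stop("more than one cell per voxel")

  seeds <- derive_seeds(config$seed,
                        c("strains", "assign", "init", "signal", "split"))
  set.seed(seeds[["strains"]])
  strains <- lapply(seq_len(config$S), function(s) {
    build_strain(config$N_r, config$E, config$L, strain_id = s)
  })
  set.seed(seeds[["assign"]])
  assignment <- sample.int(config$S, config$C, replace = TRUE)

  roles <- strains[[1]]$roles
  # 0-based regulator lists for the compiled update kernel
  strains_cpp <- lapply(strains, function(st) {
    list(inputs = lapply(st$inputs[roles$targets], function(v) v - 1L),
         tables = st$tables[roles$targets])
  })

  comm <- config$comm
  basal_ref <- basal_reference_concentration(grid, comm)
  esm_threshold <- comm$theta * basal_ref

  G <- NULL
  if (config$E > 0) {
    sol <- diffusion_solver(grid, comm$alpha, comm$beta)
    src <- Matrix::sparseMatrix(i = cell_vox, j = seq_len(config$C),
                                x = 1 / grid$volume,
                                dims = c(prod(dims), config$C))
    # columns = steady fields of a unit basal source at each cell, evaluated
    # at every cell voxel; superposition then gives all ESM fields per step
    G <- as.matrix(sol$solve(src)[cell_vox, , drop = FALSE])
  }

  input_threshold <- calibrate_input_threshold(grid, comm, config$I,
                                               config$depth,
                                               config$dirichlet_value)
  input_field <- solve_steady_state(grid, numeric(prod(dims)), comm,
                                    dirichlet_value = config$dirichlet_value)
  input_on <- as.vector(input_field)[cell_vox] >= input_threshold

  structure(
    list(config = config, placement = placement, grid = grid,
         cell_vox = cell_vox, strains = strains, strains_cpp = strains_cpp,
         assignment = assignment, roles = roles, seeds = seeds,
         basal_ref = basal_ref, esm_threshold = esm_threshold,
         input_threshold = input_threshold, input_on = input_on, G = G),
    class = "community_context"
  )
}

#' Advance a community by one timestep
#'
#' Applies the per-timestep actions in their fixed order: (1) each ESM's
#' per-cell secretion rate is set to active or basal from the *current*
#' secreter gene states; (2) the input-wall Dirichlet value is set from the
#' current signal bit; (3) all steady-state fields are solved; (4) input and
#' receptor genes are updated by thresholding the concentrations at each
#' cell's own voxel; (5) secreter and reservoir genes are updated from their
#' truth tables, reading the *new* input/receptor values and the *old*
#' secreter/reservoir values.
#'
#' @param ctx a [community_context()].
#' @param states integer `C x N` gene-state matrix at time `t`.
#' @param v_t current input signal bit (0 or 1).
#' @return The `C x N` gene-state matrix at time `t + 1`.
#' @export
community_step <- function(ctx, states, v_t) {
  cfg <- ctx$config
  roles <- ctx$roles
  C <- cfg$C; E <- cfg$E
  sensed <- matrix(0L, C, 1L + E)
  if (v_t == 1) sensed[, 1] <- as.integer(ctx$input_on)
  if (E > 0) {
    eta <- cfg$comm$eta_basal +
      (cfg$comm$eta_active - cfg$comm$eta_basal) *
      states[, roles$secreters, drop = FALSE]
    conc <- ctx$G %*% eta                       # C x E concentrations at cells
    sensed[, -1] <- (conc >= ctx$esm_threshold) + 0L
  }
  rbn_step_cpp(states, sensed, ctx$assignment, ctx$strains_cpp)
}

#' ESM concentration fields of a community state
#'
#' Full per-molecule steady-state fields for inspection/plotting (the fast
#' path in [community_step()] evaluates concentrations only at cell voxels).
#'
#' @param ctx a [community_context()].
#' @param states current `C x N` gene-state matrix.
#' @return List of concentration arrays, one per ESM.
#' @export
esm_fields <- function(ctx, states) {
  cfg <- ctx$config
  lapply(seq_len(cfg$E), function(m) {
    sec <- numeric(prod(ctx$grid$dims))
    on <- states[, ctx$roles$secreters[m]]
    sec[ctx$cell_vox] <- cfg$comm$eta_basal +
      (cfg$comm$eta_active - cfg$comm$eta_basal) * on
    solve_steady_state(ctx$grid, sec, cfg$comm)
  })
}

#' Run a full community simulation
#'
#' Builds the strains, assigns them to cells, generates the input signal
#' (first bit 0), initialises input and receptor genes to 0 and all other
#' genes i.i.d. Bernoulli(0.5), and executes `T` timesteps. Bit-identical
#' traces are produced for identical configurations (the master seed spawns
#' all randomness).
#'
#' @param config a [sim_config()].
#' @param ctx optionally a prebuilt [community_context()] for `config`.
#' @return Object of class `gene_trace`: list with `trace` (integer array
#'   `T x C x N`, states *after* each step), `V` (the input signal),
#'   `init_states`, `config`, `placement`, `seeds`, and the calibrated
#'   thresholds.
#' @export
run_simulation <- function(config, ctx = NULL) {
  if (is.null(ctx)) ctx <- community_context(config)
  cfg <- ctx$config
  N <- ctx$roles$N
  set.seed(ctx$seeds[["init"]])
  init <- matrix(0L, cfg$C, N)
  free <- setdiff(seq_len(N), c(1L, ctx$roles$receptors))
  init[, free] <- as.integer(rbinom(cfg$C * length(free), 1L, 0.5))
  set.seed(ctx$seeds[["signal"]])
  V <- generate_input_signal(cfg$T)

  trace <- array(0L, dim = c(cfg$T, cfg$C, N))
  states <- init
  for (t in seq_len(cfg$T)) {
    states <- community_step(ctx, states, V[t])
    trace[t, , ] <- states
  }
  structure(
    list(trace = trace, V = V, init_states = init, config = cfg,
         placement = ctx$placement, seeds = ctx$seeds,
         input_threshold = ctx$input_threshold,
         esm_threshold = ctx$esm_threshold, basal_ref = ctx$basal_ref),
    class = "gene_trace"
  )
}

#' @export
print.gene_trace <- function(x, ...) {
  d <- dim(x$trace)
  cat("<gene_trace>", d[1], "timesteps x", d[2], "cells x", d[3], "genes\n")
  invisible(x)
}

#' Write / read a gene trace as plain text
#'
#' One header line with the dimensions, then one line of 0/1 characters per
#' timestep (cells varying slowest, genes fastest); round-trips exactly.
#'
#' @param trace a `gene_trace` (or any `T x C x N` 0/1 array for writing).
#' @param path file path.
#' @export
write_gene_trace <- function(trace, path) {
  arr <- if (inherits(trace, "gene_trace")) trace$trace else trace
  d <- dim(arr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("gene_trace %d %d %d", d[1], d[2], d[3]), con)
  for (t in seq_len(d[1])) {
    writeLines(paste(t(arr[t, , ]), collapse = ""), con)
  }
  invisible(path)
}

#' @rdname write_gene_trace
#' @export
read_gene_trace <- function(path) {
  ln <- readLines(path)
  d <- as.integer(strsplit(ln[1], " ")[[1]][-1])
  arr <- array(0L, dim = d)
  for (t in seq_len(d[1])) {
    arr[t, , ] <- matrix(as.integer(strsplit(ln[t + 1L], "")[[1]]),
                         nrow = d[2], ncol = d[3], byrow = TRUE)
  }
  arr
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$comm <- unclass(x$comm)
  x$task <- format_task(config$task)
  x$depth <- NULL
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  comm <- do.call(comm_params, x$comm[c("alpha", "beta", "eta_basal",
                                        "eta_active", "theta")])
  sim_config(N_r = x$N_r, E = x$E, S = x$S, C = x$C, L = x$L, I = x$I,
             O = x$O, d = x$d, T = x$T, T_W = x$T_W, geometry = x$geometry,
             n_layers = x$n_layers, margin = x$margin, comm = comm,
             dirichlet_value = x$dirichlet_value, task = parse_task(x$task),
             seed = x$seed)
}
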