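# Independent oracles, written as plain brute-force code so they share no
# machinery with the package implementations they check.

# Dense direct solve of 0 = beta*Lap(C) - alpha*C + sec/Vc on an
# (nx, ny, nz) grid, unit spacing/volume; Neumann walls via dropped
# neighbours, optional Dirichlet on the x = 0 face via a fixed ghost value.
dense_screened_solve <- function(dims, alpha, beta, secretion,
                                 dirichlet_value = NULL) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  n <- nx * ny * nz
  id <- function(x, y, z) x + (y - 1) * nx + (z - 1) * nx * ny
  A <- matrix(0, n, n)
  b <- as.vector(secretion)
  for (z in seq_len(nz)) for (y in seq_len(ny)) for (x in seq_len(nx)) {
    i <- id(x, y, z)
    A[i, i] <- A[i, i] + alpha
    nbrs <- list(c(x - 1, y, z), c(x + 1, y, z), c(x, y - 1, z),
                 c(x, y + 1, z), c(x, y, z - 1), c(x, y, z + 1))
    for (nb in nbrs) {
      inside <- all(nb >= 1) && nb[1] <= nx && nb[2] <= ny && nb[3] <= nz
      if (inside) {
        A[i, i] <- A[i, i] + beta
        A[i, id(nb[1], nb[2], nb[3])] <- A[i, id(nb[1], nb[2], nb[3])] - beta
      } else if (nb[1] == 0 && !is.null(dirichlet_value)) {
        A[i, i] <- A[i, i] + beta
        b[i] <- b[i] + beta * dirichlet_value
      } # other outside faces: Neumann, neighbour term drops
    }
  }
  array(solve(A, b), dim = dims)
}

# Brute-force synchronous Boolean update of one cell: same contract as
# update_cell but re-derived from the truth-table definition with explicit
# bit arithmetic.
oracle_update_cell <- function(strain, state, sensed) {
  E <- strain$E
  new <- state
  for (j in seq_len(E + 1)) new[j] <- sensed[j]
  for (i in strain$roles$targets) {
    inp <- strain$inputs[[i]]
    idx <- 0
    if (length(inp) > 0) {
      for (j in seq_along(inp)) {
        v <- if (inp[j] <= E + 1) sensed[inp[j]] else state[inp[j]]
        idx <- idx + v * 2^(j - 1)
      }
    }
    new[i] <- strain$tables[[i]][idx + 1]
  }
  new
}

# Straight-line reference simulator for a small community: dense PDE solves
# and per-cell loops, reusing only the *data* (strains, placement,
# assignment, initial states, signal) of a package run.
oracle_simulate <- function(trace) {
  cfg <- trace$config
  pl <- trace$placement
  ctx <- community_context(cfg)          # data source: strains, assignment
  m <- cfg$margin
  dims <- c(max(pl$x) + m, max(pl$y) + 2 * m, max(pl$z) + 2 * m)
  id <- function(x, y, z) x + (y - 1) * dims[1] + (z - 1) * dims[1] * dims[2]
  cell_vox <- id(pl$x, pl$y + m, pl$z + m)
  cm <- cfg$comm

  # independent threshold calibration
  zero <- numeric(prod(dims))
  src <- zero
  src[id(ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2))] <- cm$eta_basal
  basal_ref <- dense_screened_solve(dims, cm$alpha, cm$beta, src)[
    ceiling(dims[1] / 2), ceiling(dims[2] / 2), ceiling(dims[3] / 2)]
  fin <- dense_screened_solve(dims, cm$alpha, cm$beta, zero,
                              dirichlet_value = cfg$dirichlet_value)
  cy <- ceiling(dims[2] / 2); cz <- ceiling(dims[3] / 2)
  th_in <- if (cfg$I < cfg$depth) {
    sqrt(fin[cfg$I, cy, cz] * fin[cfg$I + 1, cy, cz])
  } else {
    (1 - 1e-6) * fin[cfg$I, cy, cz]
  }

  N <- ctx$roles$N
  states <- trace$init_states
  out <- array(0L, dim = c(cfg$T, cfg$C, N))
  for (t in seq_len(cfg$T)) {
    v_t <- trace$V[t]
    # (1) secretion rates from current secreter states, (3) dense solves
    esm_conc <- matrix(0, cfg$C, max(cfg$E, 1))
    for (mm in seq_len(cfg$E)) {
      sec <- zero
      for (c in seq_len(cfg$C)) {
        on <- states[c, ctx$roles$secreters[mm]]
        sec[cell_vox[c]] <- cm$eta_basal + (cm$eta_active - cm$eta_basal) * on
      }
      fld <- dense_screened_solve(dims, cm$alpha, cm$beta, sec)
      esm_conc[, mm] <- as.vector(fld)[cell_vox]
    }
    # (2) input Dirichlet per v_t; field is zero when the wall is a sink
    in_conc <- if (v_t == 1) as.vector(fin)[cell_vox] else numeric(cfg$C)
    # (4) + (5) per-cell updates
    new_states <- states
    for (c in seq_len(cfg$C)) {
      sensed <- c(as.integer(in_conc[c] >= th_in),
                  if (cfg$E > 0) as.integer(esm_conc[c, seq_len(cfg$E)] >=
                                              cm$theta * basal_ref))
      new_states[c, ] <- oracle_update_cell(ctx$strains[[ctx$assignment[c]]],
                                            states[c, ], sensed)
    }
    states <- new_states
    out[t, , ] <- states
  }
  out
}
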