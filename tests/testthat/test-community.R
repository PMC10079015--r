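test_that("cell placement matches the requested geometry", {
  p <- place_cells("cube", 1728)
  expect_equal(nrow(p), 1728)
  expect_equal(max(p$layer), 12)
  expect_equal(as.vector(table(p$layer)), rep(144, 12))

  p1 <- place_cells("cube", 1)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$layer, 1)

  p75 <- place_cells("layered", 75, n_layers = 3)
  expect_equal(max(p75$layer), 3)
  expect_equal(as.vector(table(p75$layer)), rep(25, 3))
  expect_equal(sort(unique(p75$y)), 1:5)

  expect_error(place_cells("cube", 12^3 + 1))
  expect_error(place_cells("layered", 76, n_layers = 3))
})

test_that("a silent signal keeps every input gene off", {
  cfg <- sim_config(C = 8, N_r = 4, E = 0, S = 1, T = 30, T_W = 5,
                    task = task_spec("parity", 3), seed = 31)
  ctx <- community_context(cfg)
  set.seed(1)
  states <- matrix(as.integer(rbinom(8 * ctx$roles$N, 1, 0.5)), 8)
  for (t in 1:10) {
    states <- community_step(ctx, states, 0L)
    expect_true(all(states[, 1] == 0L))
  }
})

test_that("identical configurations give bit-identical traces", {
  cfg <- sim_config(C = 27, N_r = 6, E = 2, S = 3, T = 25, T_W = 5,
                    task = task_spec("parity", 3), seed = 55)
  tr1 <- run_simulation(cfg)
  tr2 <- run_simulation(cfg)
  expect_identical(tr1$trace, tr2$trace)
  expect_identical(tr1$V, tr2$V)
  expect_identical(tr1$V[1], 0L)
  expect_equal(dim(tr1$trace), c(25, 27, 11))
})

test_that("exactly the first I layers sense an active input signal", {
  for (I in c(1, 2, 4)) {
    cfg <- sim_config(C = 64, N_r = 4, E = 0, S = 1, I = I, T = 20, T_W = 5,
                      task = task_spec("parity", 3), seed = 70 + I)
    tr <- run_simulation(cfg)
    on_layers <- lapply(seq_len(cfg$T), function(t) {
      sort(unique(tr$placement$layer[tr$trace[t, , 1] == 1L]))
    })
    active <- tr$V == 1L
    expect_true(all(vapply(on_layers[active],
                           function(l) identical(l, seq_len(I)), TRUE)))
    expect_true(all(lengths(on_layers[!active]) == 0))
  }
})

test_that("equal basal and active rates make communication uninformative", {
  # receptor trajectories must then be independent of secreter dynamics:
  # randomizing the initial secreter states cannot change any receptor state
  base <- sim_config(C = 8, N_r = 5, E = 2, S = 2, T = 20, T_W = 5,
                     comm = comm_params(eta_basal = 2, eta_active = 2),
                     task = task_spec("parity", 3), seed = 81)
  ctx <- community_context(base)
  set.seed(4)
  st1 <- matrix(as.integer(rbinom(8 * ctx$roles$N, 1, 0.5)), 8)
  st2 <- st1
  st2[, ctx$roles$secreters] <- as.integer(rbinom(8 * 2, 1, 0.5))
  rec <- ctx$roles$receptors
  for (t in 1:10) {
    st1 <- community_step(ctx, st1, t %% 2L)
    st2 <- community_step(ctx, st2, t %% 2L)
    expect_identical(st1[, rec], st2[, rec])
  }
})

test_that("a forced secreter activates a neighbouring receptor per the threshold", {
  # two adjacent cells, one ESM; compare against a dense-solver hand oracle
  cfg <- sim_config(C = 8, N_r = 3, E = 1, S = 1, T = 10, T_W = 2,
                    comm = comm_params(alpha = 1, beta = 1, eta_basal = 0.1,
                                       eta_active = 50, theta = 2),
                    task = task_spec("parity", 3), seed = 91)
  ctx <- community_context(cfg)
  sec_gene <- ctx$roles$secreters[1]
  states <- matrix(0L, 8, ctx$roles$N)
  states[1, sec_gene] <- 1L                     # cell 1 secretes actively
  new <- community_step(ctx, states, 0L)

  # oracle: dense field from the same secretion pattern
  m <- cfg$margin; pl <- ctx$placement
  dims <- ctx$grid$dims
  sec <- numeric(prod(dims))
  sec[ctx$cell_vox] <- cfg$comm$eta_basal
  sec[ctx$cell_vox[1]] <- cfg$comm$eta_active
  fld <- dense_screened_solve(dims, 1, 1, sec)
  expected_on <- as.vector(fld)[ctx$cell_vox] >= cfg$comm$theta * ctx$basal_ref
  expect_identical(new[, ctx$roles$receptors[1]], as.integer(expected_on))
  expect_true(any(expected_on))
})

test_that("receptors updated in step (4) feed same-step reservoir updates", {
  # wire one reservoir gene to copy the first receptor; its value at t+1
  # must equal the receptor's *new* value, not the previous one
  cfg <- sim_config(C = 8, N_r = 3, E = 1, S = 1, T = 10, T_W = 2,
                    comm = comm_params(alpha = 1, beta = 1, eta_basal = 0,
                                       eta_active = 100, theta = 0.5),
                    task = task_spec("parity", 3), seed = 92)
  ctx <- community_context(cfg)
  g <- ctx$roles$reservoir[1]
  for (s in seq_along(ctx$strains)) {
    ctx$strains_cpp[[s]]$inputs[[g - (ctx$roles$E + 1L)]] <- ctx$roles$receptors[1] - 1L
    ctx$strains_cpp[[s]]$tables[[g - (ctx$roles$E + 1L)]] <- c(0L, 1L)
  }
  states <- matrix(0L, 8, ctx$roles$N)
  states[, ctx$roles$secreters[1]] <- 1L       # all cells secrete actively
  new <- community_step(ctx, states, 0L)
  expect_true(all(new[, ctx$roles$receptors[1]] == 1L))
  expect_identical(new[, g], new[, ctx$roles$receptors[1]])
})

test_that("the simulator matches an independent dense reference implementation", {
  cfg <- sim_config(C = 27, N_r = 6, E = 2, S = 3, L = 0.5, I = 2, O = 2,
                    T = 50, T_W = 10, task = task_spec("parity", 3),
                    seed = 123)
  tr <- run_simulation(cfg)
  ref <- oracle_simulate(tr)
  expect_identical(tr$trace, ref)
})

test_that("compiled multi-cell stepping agrees with the single-cell update", {
  cfg <- sim_config(C = 27, N_r = 8, E = 3, S = 4, T = 5, T_W = 1,
                    task = task_spec("parity", 3), seed = 131)
  ctx <- community_context(cfg)
  set.seed(9)
  states <- matrix(as.integer(rbinom(27 * ctx$roles$N, 1, 0.5)), 27)
  states[, c(1L, ctx$roles$receptors)] <- 0L
  new <- community_step(ctx, states, 1L)
  # recompute the sensed values independently, then update each cell in R
  flds <- esm_fields(ctx, states)
  for (c in seq_len(27)) {
    conc <- vapply(flds, function(f) as.vector(f)[ctx$cell_vox[c]], 0)
    sensed <- c(as.integer(ctx$input_on[c]),
                as.integer(conc >= ctx$esm_threshold))
    expect_identical(new[c, ],
                     update_cell(ctx$strains[[ctx$assignment[c]]],
                                 states[c, ], sensed))
  }
})

test_that("config and trace round-trip through their text formats", {
  cfg <- sim_config(C = 8, N_r = 4, E = 1, S = 2, T = 12, T_W = 4,
                    task = task_spec("median", 3, recursive = TRUE), seed = 7)
  fc <- tempfile(fileext = ".yaml"); on.exit(unlink(fc), add = TRUE)
  write_sim_config(cfg, fc)
  cfg2 <- read_sim_config(fc)
  expect_identical(unclass(cfg2)[setdiff(names(cfg2), c("comm", "task"))],
                   unclass(cfg)[setdiff(names(cfg), c("comm", "task"))])
  expect_equal(unclass(cfg2$comm), unclass(cfg$comm), tolerance = 1e-12)
  expect_identical(format_task(cfg2$task), format_task(cfg$task))
  tr <- run_simulation(cfg2)
  ft <- tempfile(fileext = ".txt"); on.exit(unlink(ft), add = TRUE)
  write_gene_trace(tr, ft)
  expect_identical(read_gene_trace(ft), tr$trace)
})
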