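test_that("effective interaction distance is sqrt(beta/alpha)", {
  expect_equal(effective_interaction_distance(1 / 45, 5.0), 15.0)
  expect_equal(effective_interaction_distance(2, 2), 1.0)
  expect_equal(effective_interaction_distance(0.04, 1.0), 5.0)
  expect_error(effective_interaction_distance(0, 1))
  expect_error(effective_interaction_distance(1, -1))
})

test_that("zero secretion and no source wall give the zero field", {
  g <- voxel_grid(c(4, 5, 6))
  C <- solve_steady_state(g, numeric(120), comm_params())
  expect_equal(max(abs(C)), 0)
})

test_that("sparse solution matches a dense direct solve", {
  set.seed(12)
  p <- comm_params(alpha = 0.1, beta = 2)
  for (dims in list(c(5, 4, 3), c(8, 8, 8), c(12, 12, 12))) {
    sec <- array(runif(prod(dims)), dim = dims)
    C <- solve_steady_state(voxel_grid(dims), sec, p)
    Cd <- dense_screened_solve(dims, p$alpha, p$beta, sec)
    expect_lt(max(abs(C - Cd)) / max(abs(Cd)), 1e-8)
    expect_true(all(C >= 0))
  }
  # with an active Dirichlet wall too
  dims <- c(6, 5, 5)
  sec <- array(runif(prod(dims)), dim = dims)
  C <- solve_steady_state(voxel_grid(dims), sec, p, dirichlet_value = 50)
  Cd <- dense_screened_solve(dims, p$alpha, p$beta, sec, dirichlet_value = 50)
  expect_lt(max(abs(C - Cd)) / max(abs(Cd)), 1e-8)
})

test_that("a point source decays monotonically with distance", {
  dims <- c(21, 21, 21)
  sec <- array(0, dim = dims)
  sec[11, 11, 11] <- 3
  C <- solve_steady_state(voxel_grid(dims), sec, comm_params(alpha = 0.5, beta = 1))
  along_x <- C[11:21, 11, 11]
  expect_true(all(diff(along_x) < 0))
  expect_equal(which.max(C), which(sec > 0))
})

test_that("the field is linear in the secretion rates", {
  set.seed(4)
  dims <- c(6, 6, 6)
  sec <- array(runif(prod(dims)), dim = dims)
  p <- comm_params()
  C1 <- solve_steady_state(voxel_grid(dims), sec, p)
  C3 <- solve_steady_state(voxel_grid(dims), 3 * sec, p)
  expect_lt(max(abs(C3 - 3 * C1)) / max(C3), 1e-10)
})

test_that("maximum principle bounds a pure Dirichlet solution", {
  dims <- c(10, 6, 6)
  C <- solve_steady_state(voxel_grid(dims), numeric(prod(dims)),
                          comm_params(), dirichlet_value = 100)
  expect_true(all(C >= 0 & C <= 100))
  # monotone decay along the input axis
  prof <- C[, 3, 3]
  expect_true(all(diff(prof) < 0))
})

test_that("the 1D profile approaches exp(-x/lambda) away from the walls", {
  alpha <- 0.01; beta <- 1    # lambda = 10 voxels
  dims <- c(120, 1, 1)
  C <- solve_steady_state(voxel_grid(dims), numeric(120),
                          comm_params(alpha = alpha, beta = beta),
                          dirichlet_value = 1000)
  x <- 5:60                  # away from both boundaries
  r <- cor(log(C[x, 1, 1]), -x / sqrt(beta / alpha))
  expect_gte(r, 0.999)
})

test_that("basal reference equals the general solver at a central source and scales with eta", {
  g <- voxel_grid(c(7, 7, 7))
  p1 <- comm_params(eta_basal = 1)
  p2 <- comm_params(eta_basal = 2.5)
  sec <- array(0, dim = g$dims); sec[4, 4, 4] <- 1
  C <- solve_steady_state(g, sec, p1)
  expect_equal(basal_reference_concentration(g, p1), C[4, 4, 4])
  expect_equal(basal_reference_concentration(g, p2),
               2.5 * basal_reference_concentration(g, p1))
})

test_that("basal reference decreases as lambda decreases", {
  g <- voxel_grid(c(7, 7, 7))
  vals <- sapply(c(0.02, 0.1, 0.5, 2), function(a) {
    basal_reference_concentration(g, comm_params(alpha = a, beta = 1))
  })
  expect_true(all(diff(vals) > 0) || all(diff(vals) < 0))
  # larger alpha (smaller lambda) must not increase the local concentration?
  # verify direction against the dense oracle at the extremes
  d1 <- dense_screened_solve(c(7, 7, 7), 0.02, 1,
                             {s <- array(0, c(7, 7, 7)); s[4, 4, 4] <- 1; s})[4, 4, 4]
  d2 <- dense_screened_solve(c(7, 7, 7), 2, 1,
                             {s <- array(0, c(7, 7, 7)); s[4, 4, 4] <- 1; s})[4, 4, 4]
  expect_equal(vals[1], d1)
  expect_equal(vals[4], d2)
  expect_equal(sign(vals[4] - vals[1]), sign(d2 - d1))
})

test_that("input threshold calibration separates exactly I layers", {
  g <- voxel_grid(c(13, 14, 14))   # 12 cell layers plus margin
  p <- comm_params()
  for (I in c(1, 3, 12)) {
    th <- calibrate_input_threshold(g, p, I = I, depth = 12)
    C <- solve_steady_state(g, numeric(prod(g$dims)), p, dirichlet_value = 1e5)
    sensed_layers <- which(C[1:12, 7, 7] >= th)
    expect_equal(sensed_layers, seq_len(I))
  }
  expect_error(calibrate_input_threshold(g, p, I = 13, depth = 12))
})
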