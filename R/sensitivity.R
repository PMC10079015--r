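#' Parameter ranges for the sensitivity study
#'
#' The eight varied community parameters with their sampling ranges: gene
#' input fraction `L`, reservoir genes `Nr`, cells `C`, strains `S`, input
#' layers `I`, interaction distance `lambda`, ESM count `E` and receptor
#' threshold factor `theta`. Defaults are the full study ranges; the caps
#' let a desk-scale study shrink the community and gene budget.
#'
#' @param C_max,Nr_max,I_max upper bounds for `C`, `Nr` and `I`.
#' @return `data.frame` with columns `name`, `low`, `high`, `integer`.
#' @export
sensitivity_ranges <- function(C_max = 15^3, Nr_max = 500, I_max = 15) {
  data.frame(
    name = c("L", "Nr", "C", "S", "I", "lambda", "E", "theta"),
    low = c(0.1, 10, 1, 1, 1, 2.5, 0, 10),
    high = c(1.0, Nr_max, C_max, 20, I_max, 30, 20, 100),
    integer = c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Latin hypercube sample over parameter ranges
#'
#' Per dimension, the range is divided into `n` equal-width intervals, one
#' point is drawn uniformly inside each interval, and the interval order is
#' shuffled independently per dimension. Integer-flagged parameters are
#' rounded to the nearest integer after sampling. Uses the current RNG
#' state.
#'
#' @param ranges a [sensitivity_ranges()]-style data frame.
#' @param n number of samples.
#' @return `n x k` numeric matrix with the parameter names as column names.
#' @export
lhs_sample <- function(ranges, n) {
  stopifnot(n >= 1, all(ranges$low < ranges$high))
  k <- nrow(ranges)
  u <- lhs::randomLHS(n, k)
  x <- sweep(sweep(u, 2, ranges$high - ranges$low, "*"), 2, ranges$low, "+")
  for (j in which(ranges$integer)) x[, j] <- round(x[, j])
  colnames(x) <- ranges$name
  x
}

#' Snap a cell count to the nearest perfect cube
#'
#' @param C desired cell count (>= 1).
#' @param C_max upper bound the snapped value must respect.
#' @return `m^3` for the integer `m` whose cube is nearest to `C`.
#' @export
snap_to_cube <- function(C, C_max = Inf) {
  m_hi <- max(1, floor((C_max + 1e-9)^(1 / 3)))
  m <- pmin(pmax(round(C^(1 / 3)), 1), m_hi)
  as.integer(m^3)
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every parameter column and the output (average ranks on
#' ties), then for each parameter regresses both its ranks and the output's
#' ranks on all *other* parameters' ranks by ordinary least squares and
#' reports the Pearson correlation of the two residual vectors. This
#' cancels the (monotone, linear-in-ranks) effect of the other parameters,
#' leaving each parameter's own monotone association with the output.
#' Two-sided p-values use the t-statistic with `n - k - 1` degrees of
#' freedom. A rank-deficient regression yields `NA` for that parameter.
#'
#' @param params `n x k` numeric matrix (or data frame) of parameter values.
#' @param y numeric output vector of length `n` (e.g. test accuracy).
#' @return Object of class `prcc_result`: `data.frame` with columns
#'   `parameter`, `rho`, `p_value`, `n`.
#' @export
prcc <- function(params, y) {
  X <- as.matrix(params)
  n <- nrow(X); k <- ncol(X)
  stopifnot(length(y) == n, n > k + 2)
  R <- apply(X, 2, rank)
  ry <- rank(y)
  rho <- p <- rep(NA_real_, k)
  df <- n - k - 1
  for (i in seq_len(k)) {
    Z <- cbind(1, R[, -i, drop = FALSE])
    rx_res <- lm.fit(Z, R[, i])$residuals
    ry_res <- lm.fit(Z, ry)$residuals
    if (sd(rx_res) < 1e-12 || sd(ry_res) < 1e-12) next
    r <- cor(rx_res, ry_res)
    rho[i] <- r
    tstat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
    p[i] <- max(2 * pt(-abs(tstat), df), .Machine$double.xmin)
  }
  structure(
    data.frame(parameter = colnames(X), rho = rho, p_value = p, n = n,
               stringsAsFactors = FALSE),
    class = c("prcc_result", "data.frame")
  )
}

#' Run an LHS + PRCC sensitivity study
#'
#' Draws `n_samples` Latin-hypercube parameter sets over `ranges`, maps each
#' to a cube-community configuration (cell counts snapped to the nearest
#' perfect cube, input layers clamped to the community depth, `lambda`
#' converted to a degradation rate at fixed `beta`), simulates each set
#' `replicates` times recording the readout test accuracy, and computes the
#' PRCC of every parameter against accuracy. Replicate accuracies enter the
#' PRCC as separate rows by default; `average_replicates = TRUE` averages
#' them first.
#'
#' @param n_samples number of LHS parameter sets.
#' @param ranges parameter ranges, see [sensitivity_ranges()].
#' @param task objective function (default parity with window 7).
#' @param T,T_W simulation length and warm-up per run.
#' @param replicates simulations per parameter set.
#' @param average_replicates average replicate accuracies before the PRCC.
#' @param beta fixed diffusion coefficient; the sampled `lambda` sets
#'   `alpha = beta / lambda^2`.
#' @param eta_basal,eta_active fixed secretion rates.
#' @param seed master seed for sampling and all simulations.
#' @param verbose print one progress line per run to stderr.
#' @return List with `params` (the simulated, post-snap values, one row per
#'   accuracy), `accuracy`, `prcc` (a [prcc()] result) and `sampled` (the
#'   raw LHS draw).
#' @export
run_sensitivity_study <- function(n_samples = 150,
                                  ranges = sensitivity_ranges(),
                                  task = task_spec("parity", 7),
                                  T = 1000, T_W = 100, replicates = 1,
                                  average_replicates = FALSE,
                                  beta = 5, eta_basal = 1, eta_active = 5,
                                  seed = 1, verbose = FALSE) {
  seeds <- derive_seeds(seed, c("lhs", "runs"))
  set.seed(seeds[["lhs"]])
  sampled <- lhs_sample(ranges, n_samples)
  C_max <- ranges$high[ranges$name == "C"]
  run_seeds <- derive_seeds(seeds[["runs"]], seq_len(n_samples * replicates))

  rows <- vector("list", n_samples * replicates)
  acc <- numeric(n_samples * replicates)
  r <- 0L
  for (i in seq_len(n_samples)) {
    p <- sampled[i, ]
    C <- snap_to_cube(p[["C"]], C_max)
    depth <- as.integer(round(C^(1 / 3)))
    I <- as.integer(min(p[["I"]], depth))
    alpha <- beta / p[["lambda"]]^2
    for (rep in seq_len(replicates)) {
      r <- r + 1L
      cfg <- sim_config(
        N_r = p[["Nr"]], E = p[["E"]], S = p[["S"]], C = C, L = p[["L"]],
        I = I, O = depth, d = 0, T = T, T_W = T_W, geometry = "cube",
        comm = comm_params(alpha = alpha, beta = beta,
                           eta_basal = eta_basal, eta_active = eta_active,
                           theta = p[["theta"]]),
        task = task, seed = run_seeds[[r]]
      )
      res <- run_single(cfg)
      acc[r] <- res$accuracy
      rows[[r]] <- c(L = p[["L"]], Nr = p[["Nr"]], C = as.numeric(C),
                     S = p[["S"]], I = as.numeric(I),
                     lambda = p[["lambda"]], E = p[["E"]],
                     theta = p[["theta"]])
      if (verbose) {
        message(sprintf("run %d/%d: C=%d Nr=%d E=%d -> accuracy %.3f",
                        r, n_samples * replicates, C, as.integer(p[["Nr"]]),
                        as.integer(p[["E"]]), acc[r]))
      }
    }
  }
  params <- do.call(rbind, rows)
  if (average_replicates && replicates > 1) {
    grp <- rep(seq_len(n_samples), each = replicates)
    acc <- as.numeric(tapply(acc, grp, mean))
    params <- params[seq(1, nrow(params), by = replicates), , drop = FALSE]
  }
  list(params = params, accuracy = acc, prcc = prcc(params, acc),
       sampled = sampled, average_replicates = average_replicates)
}
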