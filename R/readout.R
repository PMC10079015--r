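#' Build the regression dataset from a gene trace
#'
#' The covariates are the reservoir-gene states of all cells belonging to the
#' `O` output layers (the layers farthest from the input wall), read at time
#' `t + d`; the targets are the objective-function outputs on the window
#' ending at `t`. Concretely, row `i` pairs the covariate snapshot at
#' timestep `T_W + w + d + i - 1` with the ground truth of the window ending
#' at `T_W + w + i - 1`, for `i = 1 .. T - (T_W + w + d) + 1`: the warm-up
#' `T_W` discards transients and the delay `d` lets the signal propagate
#' through the layers before it is read.
#'
#' @param trace a [run_simulation()] result.
#' @param task a [task_spec()]; defaults to the task in the trace's config.
#' @param T_W,d warm-up and delay; default from the config.
#' @param output_layers integer layer indices used for readout; default the
#'   last `O` layers of the config.
#' @param covariates `"reservoir"` (default) restricts the columns to
#'   reservoir genes; `"all"` also includes input, receptor and secreter
#'   genes.
#' @return Object of class `readout_dataset`: list with binary matrix `X`,
#'   binary vector `Y`, and the timestep vectors `t_X`, `t_Y` of each row.
#' @export
build_dataset <- function(trace, task = NULL, T_W = NULL, d = NULL,
                          output_layers = NULL,
                          covariates = c("reservoir", "all")) {
  covariates <- match.arg(covariates)
  cfg <- trace$config
  if (is.null(task)) task <- cfg$task
  if (is.null(T_W)) T_W <- cfg$T_W
  if (is.null(d)) d <- cfg$d
  if (is.null(output_layers)) {
    output_layers <- seq.int(cfg$depth - cfg$O + 1L, cfg$depth)
  }
  T_W <- as.integer(T_W); d <- as.integer(d)
  Tn <- dim(trace$trace)[1]
  w <- task$w
  t_X <- seq.int(T_W + w + d, Tn)
  if (length(t_X) < 1 || t_X[1] > Tn) stop("warm-up + window + delay exhaust the trace")
  t_Y <- t_X - d
  cells <- trace$placement$cell[trace$placement$layer %in% output_layers]
  if (!length(cells)) stop("no cells in the requested output layers")
  roles <- gene_roles(cfg$N_r, cfg$E)
  genes <- if (covariates == "reservoir") roles$reservoir else seq_len(roles$N)
  X <- trace$trace[t_X, cells, genes, drop = FALSE]
  dim(X) <- c(length(t_X), length(cells) * length(genes))
  Yfull <- ground_truth(trace$V, task)
  Y <- Yfull[t_Y - w + 1L]
  structure(list(X = X, Y = Y, t_X = t_X, t_Y = t_Y, task = task),
            class = "readout_dataset")
}

#' Train and evaluate the lasso readout
#'
#' Splits the rows randomly into 75% training and 25% test (test size
#' `floor(n/4)`, no class stratification), fits an L1-penalised linear
#' regression of the binary targets on the binary covariates with the
#' penalty weight chosen by k-fold cross-validation on the training rows,
#' binarises the continuous test predictions at 0.5, and reports the
#' fraction of correctly predicted test rows. A constant target (or a
#' degenerate fit) falls back to the trivial constant model. Uses the
#' current RNG state for the split and the fold assignment.
#'
#' @param ds a [build_dataset()] result (or any list with matrix `X` and
#'   0/1 vector `Y`).
#' @param nfolds cross-validation folds (default 5).
#' @param thresh coordinate-descent convergence threshold passed to the
#'   lasso path; kept loose for speed on wide binary designs.
#' @return Object of class `readout_result`: `accuracy` on the held-out
#'   rows, selected penalty `lambda`, sparse `coefficients`, and the
#'   `train_idx` / `test_idx` row sets.
#' @export
train_readout <- function(ds, nfolds = 5, thresh = 1e-4) {
  X <- ds$X; Y <- as.numeric(ds$Y)
  n <- nrow(X)
  if (n < 8) stop("need at least 8 rows to train and test the readout")
  n_test <- floor(n / 4)
  test_idx <- sort(sample.int(n, n_test))
  train_idx <- setdiff(seq_len(n), test_idx)
  Xtr <- X[train_idx, , drop = FALSE]; Ytr <- Y[train_idx]
  Xte <- X[test_idx, , drop = FALSE];  Yte <- Y[test_idx]

  if (ncol(Xtr) < 2) {  # glmnet needs >= 2 columns; pad with a null column
    Xtr <- cbind(Xtr, 0); Xte <- cbind(Xte, 0)
  }
  fit <- NULL
  if (var(Ytr) > 0) {
    fit <- tryCatch(
      glmnet::cv.glmnet(Xtr, Ytr, alpha = 1, family = "gaussian",
                        nfolds = min(nfolds, length(train_idx)),
                        standardize = FALSE, thresh = thresh),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    pred <- rep(mean(Ytr), length(test_idx))
    lambda <- NA_real_
    coefs <- NULL
  } else {
    pred <- as.numeric(predict(fit, Xte, s = "lambda.min"))
    lambda <- fit$lambda.min
    coefs <- coef(fit, s = "lambda.min")
  }
  accuracy <- mean((pred >= 0.5) == (Yte == 1))
  structure(list(accuracy = accuracy, lambda = lambda,
                 coefficients = coefs, train_idx = train_idx,
                 test_idx = test_idx, n = n),
            class = "readout_result")
}

#' @export
print.readout_result <- function(x, ...) {
  cat(sprintf("<readout_result> accuracy %.3f on %d test rows (n = %d, lambda = %s)\n",
              x$accuracy, length(x$test_idx), x$n,
              format(x$lambda, digits = 4)))
  invisible(x)
}
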