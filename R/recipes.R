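#' Run one simulation plus readout
#'
#' Executes [run_simulation()], builds the readout dataset and trains the
#' lasso readout (split/fold randomness taken from the configuration's
#' readout substream), and returns a one-row results table. Optionally
#' writes the results row, a manifest (resolved config, seed, calibrated
#' thresholds) and the gene trace to `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @param save_trace also write the full gene trace (text; can be large).
#' @return `data.frame` with one row: task, window, geometry and parameter
#'   columns, the held-out `accuracy`, selected `lambda` and the seed.
#' @export
run_single <- function(config, out_dir = NULL, save_trace = FALSE) {
  trace <- run_simulation(config)
  ds <- build_dataset(trace)
  set.seed(trace$seeds[["split"]])
  res <- train_readout(ds)
  row <- data.frame(
    task = format_task(config$task), w = config$task$w,
    geometry = config$geometry, C = config$C, N_r = config$N_r,
    E = config$E, S = config$S, L = config$L, I = config$I, O = config$O,
    d = config$d, T = config$T, T_W = config$T_W,
    accuracy = res$accuracy, lambda = res$lambda, seed = config$seed,
    stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(row, file.path(out_dir, "result.csv"), row.names = FALSE)
    write_sim_config(config, file.path(out_dir, "config.yaml"))
    manifest <- c(
      sprintf("seed %d", config$seed),
      sprintf("input_threshold %s", format(trace$input_threshold, digits = 17)),
      sprintf("esm_threshold %s", format(trace$esm_threshold, digits = 17)),
      sprintf("basal_reference %s", format(trace$basal_ref, digits = 17))
    )
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
    if (save_trace) write_gene_trace(trace, file.path(out_dir, "trace.txt"))
  }
  attr(row, "trace") <- if (save_trace) trace else NULL
  row
}

#' Experiment recipes at configurable scale
#'
#' Reproduces the package's three studies, scaled down from their full-size
#' protocols by `scale`:
#' \describe{
#'   \item{`proof_of_concept`}{median and parity at window sizes 3, 5, 7, 9
#'     for a unicellular (1 cell) and a multicellular cube community where
#'     every layer senses the input and every layer is read out;
#'     `round(100 * scale)` replicates per condition (full protocol: 100).}
#'   \item{`layered_community`}{three stacked square layers, input sensed
#'     only by the first layer, readout from the last layer with delay
#'     `d = 2`; one-at-a-time sweeps of reservoir genes, cells, strains and
#'     ESM count around a fixed base configuration, parity window 3.}
#'   \item{`sensitivity`}{LHS + PRCC over the eight varied parameters
#'     (full protocol: 10000 parameter sets, 5 replicates each;
#'     at `scale` the set count is `round(10000 * scale)` with 1
#'     replicate).}
#' }
#'
#' @param name recipe name.
#' @param scale scale factor on replicate / sample counts (default 0.1).
#' @param seed master seed.
#' @param out_dir optional directory for the results CSV.
#' @param side cube side for the multicellular proof-of-concept community
#'   (desk default 5; the full-size study uses 12).
#' @param T timesteps per simulation (desk default 600 for proof-of-concept
#'   conditions, 400 for sensitivity runs).
#' @param verbose print per-run progress to stderr.
#' @return For `proof_of_concept` / `layered_community`: `data.frame` of
#'   per-run rows (and a `summary` attribute of per-condition means). For
#'   `sensitivity`: the [run_sensitivity_study()] result.
#' @export
run_recipe <- function(name = c("proof_of_concept", "layered_community",
                                "sensitivity"),
                       scale = 0.1, seed = 1, out_dir = NULL, side = 5,
                       T = NULL, verbose = FALSE) {
  name <- match.arg(name)
  if (name == "sensitivity") {
    n <- max(20L, as.integer(round(10000 * scale)))
    out <- run_sensitivity_study(
      n_samples = n, ranges = sensitivity_ranges(C_max = 6^3, Nr_max = 100,
                                                 I_max = 6),
      T = if (is.null(T)) 1000 else T, seed = seed, verbose = verbose
    )
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write.csv(cbind(as.data.frame(out$params), accuracy = out$accuracy),
                file.path(out_dir, "sensitivity_runs.csv"), row.names = FALSE)
      write.csv(as.data.frame(out$prcc), file.path(out_dir, "prcc.csv"),
                row.names = FALSE)
    }
    return(out)
  }

  reps <- max(1L, as.integer(round(100 * scale)))
  if (is.null(T)) T <- 600
  conds <- if (name == "proof_of_concept") {
    expand.grid(kind = c("median", "parity"), w = c(3, 5, 7, 9),
                system = c("unicellular", "multicellular"),
                stringsAsFactors = FALSE)
  } else {
    base <- list(N_r = 50, C = 75, S = 8, E = 2)
    sweeps <- list(N_r = c(10, 50, 100, 300), C = 3 * c(2, 4, 6, 8)^2,
                   S = c(1, 4, 8, 16), E = c(1, 2, 4, 8))
    do.call(rbind, lapply(names(sweeps), function(p) {
      do.call(rbind, lapply(sweeps[[p]], function(v) {
        b <- base; b[[p]] <- v
        data.frame(kind = "parity", w = 3, system = "layered",
                   varied = p, N_r = b$N_r, C = b$C, S = b$S, E = b$E,
                   stringsAsFactors = FALSE)
      }))
    }))
  }

  seeds <- derive_seeds(seed, seq_len(nrow(conds) * reps))
  rows <- vector("list", nrow(conds) * reps)
  r <- 0L
  for (i in seq_len(nrow(conds))) {
    cd <- conds[i, ]
    for (rep in seq_len(reps)) {
      r <- r + 1L
      cfg <- if (name == "proof_of_concept") {
        sim_config(C = if (cd$system == "unicellular") 1 else side^3,
                   task = task_spec(cd$kind, cd$w), T = T, seed = seeds[[r]])
      } else {
        sim_config(N_r = cd$N_r, E = cd$E, S = cd$S, C = cd$C,
                   geometry = "layered", n_layers = 3, I = 1, O = 1, d = 2,
                   task = task_spec(cd$kind, cd$w), T = T, seed = seeds[[r]])
      }
      row <- run_single(cfg)
      row$system <- cd$system
      if (!is.null(cd$varied)) row$varied <- cd$varied
      rows[[r]] <- row
      if (verbose) {
        message(sprintf("%s run %d/%d: %s w=%d %s -> %.3f", name, r,
                        nrow(conds) * reps, cd$kind, cd$w, cd$system,
                        row$accuracy))
      }
    }
  }
  runs <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ task + system, data = runs, FUN = mean)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(runs, file.path(out_dir, paste0(name, "_runs.csv")),
              row.names = FALSE)
    write.csv(agg, file.path(out_dir, paste0(name, "_summary.csv")),
              row.names = FALSE)
  }
  attr(runs, "summary") <- agg
  runs
}
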