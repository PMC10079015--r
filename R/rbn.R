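#' Gene role indexing for a cell
#'
#' Every cell carries `N = 1 + 2E + N_r` genes with fixed roles and a fixed
#' index layout shared by all strains of a simulation: gene 1 is the input
#' signal gene, genes `2..(E+1)` are the ESM receptor genes, genes
#' `(E+2)..(2E+1)` the ESM secreter genes, and the remaining `N_r` genes are
#' reservoir genes (the internal state of the cell).
#'
#' @param N_r number of reservoir genes (>= 1).
#' @param E number of extracellular signalling molecules (>= 0); each ESM
#'   contributes one receptor and one secreter gene.
#' @return A list with the total gene count `N` and integer index vectors
#'   `input`, `receptors`, `secreters`, `reservoir`, plus the derived sets
#'   `targets` (genes that may receive edges: secreters + reservoir) and
#'   `sources` (genes that may emit edges: everything except secreters).
#' @export
gene_roles <- function(N_r, E) {
  stopifnot(N_r >= 1, E >= 0)
  N_r <- as.integer(N_r); E <- as.integer(E)
  N <- 1L + 2L * E + N_r
  receptors <- if (E > 0) seq.int(2L, E + 1L) else integer(0)
  secreters <- if (E > 0) seq.int(E + 2L, 2L * E + 1L) else integer(0)
  reservoir <- seq.int(2L * E + 2L, N)
  list(
    N = N, N_r = N_r, E = E,
    input = 1L, receptors = receptors, secreters = secreters,
    reservoir = reservoir,
    targets = c(secreters, reservoir),
    sources = setdiff(seq_len(N), secreters)
  )
}

#' Construct a random Boolean network strain
#'
#' Builds one strain's regulatory topology and truth tables under the wiring
#' constraints of the community model: the input gene and receptor genes have
#' no incoming edges, secreter genes have no outgoing edges, and the network
#' carries exactly `2 * (N - 1 - E)` edges so that the mean in-degree over the
#' regulated (secreter + reservoir) genes is exactly 2 — the critical regime
#' for Boolean-network computation. A fraction `L` of the regulated genes is
#' wired to the input gene: `round(L * (E + N_r))` edges (round-half-to-even)
#' originate at gene 1, each to a distinct target; the remaining edges draw
#' their source uniformly from the non-secreter genes other than the input
#' gene and their target uniformly from the regulated genes, resampling on
#' duplicate (source, target) pairs. Truth-table outputs are i.i.d.
#' Bernoulli(0.5). Genes that end up with in-degree 0 get a constant random
#' value. Uses the current RNG state; seed with [set.seed()] for
#' reproducibility.
#'
#' @param N_r,E gene counts, see [gene_roles()].
#' @param L fraction in `[0, 1]` of regulated genes receiving an edge from
#'   the input gene.
#' @param strain_id integer label stored on the strain.
#' @return An object of class `strain_network`: list with `strain_id`, `N`,
#'   `N_r`, `E`, `L`, `roles`, `edges` (two-column integer matrix,
#'   source/target), `inputs` (per-gene ordered regulator lists) and `tables`
#'   (per-gene truth tables of length `2^k_i`; entry `j` is the output for
#'   regulator configuration `j - 1`, first-listed regulator = least
#'   significant bit).
#' @export
build_strain <- function(N_r, E, L, strain_id = 1L) {
  stopifnot(N_r >= 1, E >= 0, is.finite(L), L >= 0, L <= 1)
  roles <- gene_roles(N_r, E)
  N <- roles$N
  n_edges <- 2L * (N - 1L - roles$E)
  targets <- roles$targets

  n_in <- as.integer(round(L * length(targets)))
  if (n_in > length(targets)) {
    stop("L * (E + N_r) exceeds the number of available target genes")
  }
  in_tgt <- resample(targets, n_in)
  edges <- cbind(rep.int(1L, n_in), in_tgt)

  n_rest <- n_edges - n_in
  src_pool <- setdiff(roles$sources, 1L)
  if (n_rest > length(src_pool) * length(targets)) {
    stop("cannot place ", n_rest, " distinct non-input edges")
  }
  seen <- integer(0)
  while (n_rest > 0L) {
    src <- resample(src_pool, n_rest, replace = TRUE)
    tgt <- resample(targets, n_rest, replace = TRUE)
    key <- (src - 1L) * N + tgt
    ok <- !duplicated(key) & !(key %in% seen)
    if (any(ok)) {
      edges <- rbind(edges, cbind(src[ok], tgt[ok]))
      seen <- c(seen, key[ok])
      n_rest <- n_rest - sum(ok)
    }
  }
  dimnames(edges) <- list(NULL, c("source", "target"))

  inputs <- vector("list", N)
  tables <- vector("list", N)
  for (i in targets) {
    inp <- edges[edges[, "target"] == i, "source"]
    if (length(inp) > 25L) stop("in-degree ", length(inp), " too large for truth-table storage")
    inputs[[i]] <- as.integer(inp)
    tables[[i]] <- as.integer(rbinom(2^length(inp), 1L, 0.5))
  }

  structure(
    list(strain_id = as.integer(strain_id), N = N, N_r = roles$N_r,
         E = roles$E, L = L, roles = roles, edges = edges,
         inputs = inputs, tables = tables),
    class = "strain_network"
  )
}

#' @export
print.strain_network <- function(x, ...) {
  cat("<strain_network> id", x$strain_id, "-", x$N, "genes (",
      x$N_r, "reservoir,", x$E, "ESM ),", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Synchronous single-cell gene update
#'
#' Advances the secreter and reservoir genes of one cell by one timestep.
#' The environment-facing genes (input signal gene and ESM receptors) are not
#' computed here: they are handed in as `sensed`, already updated for the new
#' timestep, and regulated genes that read them use these *new* values, while
#' regulators that are themselves secreter or reservoir genes contribute
#' their *old* (time `t`) values.
#'
#' @param strain a [build_strain()] object.
#' @param state integer 0/1 vector of length `N`, the cell state at time `t`.
#' @param sensed integer 0/1 vector of length `1 + E`: the new input-gene
#'   value followed by the new receptor values.
#' @return The cell state at time `t + 1` (integer 0/1 vector of length `N`).
#' @export
update_cell <- function(strain, state, sensed) {
  roles <- strain$roles
  stopifnot(length(state) == strain$N, length(sensed) == strain$E + 1L,
            all(state %in% 0:1), all(sensed %in% 0:1))
  new <- as.integer(state)
  new[seq_len(strain$E + 1L)] <- as.integer(sensed)
  for (i in roles$targets) {
    inp <- strain$inputs[[i]]
    if (length(inp)) {
      if (any(inp > strain$N)) stop("regulator index out of range for gene ", i)
      vals <- ifelse(inp <= strain$E + 1L, new[inp], state[inp])
      idx <- sum(vals * 2^(seq_along(inp) - 1L))
    } else {
      idx <- 0L
    }
    new[i] <- strain$tables[[i]][idx + 1L]
  }
  new
}

#' Write / read a strain to a structured text file
#'
#' Plain-text serialization (edges as integer pairs, truth tables as
#' bitstrings) that round-trips bit-exactly, for archiving the reservoirs a
#' result was produced with.
#'
#' @param strain a `strain_network`.
#' @param path file path.
#' @return `write_strain` invisibly returns `path`; `read_strain` returns the
#'   reconstructed `strain_network`.
#' @export
write_strain <- function(strain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("strain %d", strain$strain_id), con)
  writeLines(sprintf("Nr %d E %d L %s", strain$N_r, strain$E,
                     format(strain$L, digits = 17)), con)
  writeLines(sprintf("edges %d", nrow(strain$edges)), con)
  writeLines(sprintf("%d %d", strain$edges[, 1], strain$edges[, 2]), con)
  for (i in strain$roles$targets) {
    writeLines(sprintf("gene %d inputs %s table %s", i,
                       paste(strain$inputs[[i]], collapse = ","),
                       paste(strain$tables[[i]], collapse = "")), con)
  }
  invisible(path)
}

#' @rdname write_strain
#' @export
read_strain <- function(path) {
  ln <- readLines(path)
  id <- as.integer(strsplit(ln[1], " ")[[1]][2])
  hdr <- strsplit(ln[2], " ")[[1]]
  N_r <- as.integer(hdr[2]); E <- as.integer(hdr[4]); L <- as.numeric(hdr[6])
  roles <- gene_roles(N_r, E)
  n_edges <- as.integer(strsplit(ln[3], " ")[[1]][2])
  em <- do.call(rbind, lapply(ln[3 + seq_len(n_edges)], function(s) {
    as.integer(strsplit(s, " ")[[1]])
  }))
  dimnames(em) <- list(NULL, c("source", "target"))
  inputs <- vector("list", roles$N)
  tables <- vector("list", roles$N)
  for (s in ln[-seq_len(3 + n_edges)]) {
    f <- strsplit(s, " ")[[1]]
    i <- as.integer(f[2])
    inputs[[i]] <- if (nzchar(f[4])) as.integer(strsplit(f[4], ",")[[1]]) else integer(0)
    tables[[i]] <- as.integer(strsplit(f[6], "")[[1]])
    if (any(inputs[[i]] > roles$N)) stop("regulator index out of range in ", path)
  }
  structure(
    list(strain_id = id, N = roles$N, N_r = N_r, E = E, L = L,
         roles = roles, edges = em, inputs = inputs, tables = tables),
    class = "strain_network"
  )
}
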