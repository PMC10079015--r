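#' Random binary input signal
#'
#' Generates the driving sequence `V = (v_1, ..., v_T)`: the first value is
#' always 0 (the community starts from a silent input) and the remaining
#' entries are i.i.d. Bernoulli(0.5). Uses the current RNG state.
#'
#' @param T signal length (>= 1).
#' @return Integer 0/1 vector of length `T`.
#' @export
generate_input_signal <- function(T) {
  stopifnot(T >= 1)
  c(0L, as.integer(rbinom(T - 1L, 1L, 0.5)))
}

#' Specification of a windowed Boolean objective function
#'
#' The objective `f` maps each `w`-bit window `(v_{t-w+1}, ..., v_t)` of the
#' input signal to one output bit. `median` outputs 1 iff the window holds a
#' strict majority of 1s (ties on even `w` give 0), `parity` outputs 1 iff
#' the window holds an odd number of 1s, and `table` uses an arbitrary
#' `2^w`-entry truth table. With `recursive = TRUE` the least recent window
#' bit is replaced by the function's previous output:
#' `Y_t = f(Y_{t-1}, v_{t-w+2}, ..., v_t)`, with the first output (at
#' `t = w`) computed from the plain window.
#'
#' Truth-table indexing convention: the most recent bit is the least
#' significant index bit, so window `(v_{t-w+1}, ..., v_t)` selects entry
#' `1 + sum_j v_{t-j+1} * 2^(j-1)` of `table`.
#'
#' @param kind one of `"median"`, `"parity"`, `"table"`.
#' @param w window size (>= 1).
#' @param table 0/1 vector of length `2^w` (required for `kind = "table"`).
#' @param recursive logical flag for the recursive variant.
#' @return Object of class `task_spec`.
#' @export
task_spec <- function(kind = c("parity", "median", "table"), w,
                      table = NULL, recursive = FALSE) {
  kind <- match.arg(kind)
  stopifnot(w >= 1)
  if (kind == "table") {
    stopifnot(!is.null(table), length(table) == 2^w, all(table %in% 0:1))
    table <- as.integer(table)
  } else {
    table <- NULL
  }
  structure(list(kind = kind, w = as.integer(w), table = table,
                 recursive = isTRUE(recursive)),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec>", format_task(x), "\n")
  invisible(x)
}

# Evaluate the task on a single window (oldest bit first).
eval_window <- function(task, window) {
  w <- task$w
  switch(task$kind,
    median = as.integer(sum(window) > w / 2),
    parity = as.integer(sum(window) %% 2L),
    table = task$table[[sum(window * 2^(w - seq_len(w))) + 1L]]
  )
}

#' Ground truth of a windowed Boolean objective on a signal
#'
#' @param V 0/1 input signal of length `T >= w`.
#' @param task a [task_spec()].
#' @return Integer 0/1 vector `Y` of length `T - w + 1`; `Y[i]` is the output
#'   for the window ending at timestep `t = w + i - 1`.
#' @export
ground_truth <- function(V, task) {
  V <- as.integer(V)
  w <- task$w
  if (length(V) < w) stop("signal shorter than the task window")
  if (task$recursive) {
    Tn <- length(V)
    Y <- integer(Tn - w + 1L)
    Y[1] <- eval_window(task, V[seq_len(w)])
    if (Tn > w) {
      for (t in seq.int(w + 1L, Tn)) {
        Y[t - w + 1L] <- eval_window(task, c(Y[t - w], V[(t - w + 2L):t]))
      }
    }
    return(Y)
  }
  # stats::filter(x, f, sides = 1)[t] = sum_j f[j] * x[t - j + 1]
  if (task$kind == "table") {
    idx <- stats::filter(V, 2^(0:(w - 1L)), sides = 1)
    as.integer(task$table[as.integer(idx[w:length(V)]) + 1L])
  } else {
    s <- as.integer(stats::filter(V, rep(1L, w), sides = 1)[w:length(V)])
    if (task$kind == "median") as.integer(s > w / 2) else s %% 2L
  }
}

#' Enumerate or sample Boolean objective functions of a given window size
#'
#' For small windows (`2^(2^w)` enumerable, e.g. `w = 3` giving all 256
#' functions) and `n_samples = NULL`, returns every truth table; otherwise
#' samples `n_samples` distinct tables uniformly without replacement.
#'
#' @param w window size.
#' @param n_samples number of tables to sample, or `NULL` for exhaustive
#'   enumeration (only allowed for `w <= 4`).
#' @param recursive propagate the recursive flag to the generated specs.
#' @return List of [task_spec()] objects of kind `"table"`.
#' @export
enumerate_tasks <- function(w, n_samples = NULL, recursive = FALSE) {
  stopifnot(w >= 1)
  n_tables <- 2^(2^w)
  if (is.null(n_samples)) {
    if (w > 4) stop("exhaustive enumeration only supported for w <= 4; give n_samples")
    tabs <- lapply(seq_len(n_tables) - 1, function(v) {
      as.integer(intToBits(v)[seq_len(2^w)])
    })
  } else {
    if (n_samples > n_tables) stop("n_samples exceeds the number of distinct tables")
    seen <- character(0)
    tabs <- list()
    while (length(tabs) < n_samples) {
      tb <- as.integer(rbinom(2^w, 1L, 0.5))
      key <- paste(tb, collapse = "")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        tabs[[length(tabs) + 1L]] <- tb
      }
    }
  }
  lapply(tabs, function(tb) task_spec("table", w, table = tb, recursive = recursive))
}

#' Compact text form of a task specification
#'
#' `"parity:7"`, `"median:3"`, `"table:w=3:0x96"`, with a `"recursive:"`
#' prefix for recursive variants; [parse_task()] inverts it.
#'
#' @param task a [task_spec()].
#' @param text a string produced by `format_task`.
#' @return A string / a `task_spec`.
#' @export
format_task <- function(task) {
  body <- if (task$kind == "table") {
    bits <- task$table
    pad <- (4 - length(bits) %% 4) %% 4
    bits <- c(bits, integer(pad))              # high-order zero padding
    nyb <- vapply(seq_len(length(bits) / 4), function(i) {
      sum(bits[(4 * i - 3):(4 * i)] * c(1L, 2L, 4L, 8L))
    }, integer(1))
    sprintf("table:w=%d:0x%s", task$w,
            paste(rev(sprintf("%x", nyb)), collapse = ""))
  } else {
    sprintf("%s:%d", task$kind, task$w)
  }
  if (task$recursive) paste0("recursive:", body) else body
}

#' @rdname format_task
#' @export
parse_task <- function(text) {
  recursive <- startsWith(text, "recursive:")
  if (recursive) text <- sub("^recursive:", "", text)
  parts <- strsplit(text, ":", fixed = TRUE)[[1]]
  if (parts[1] == "table") {
    w <- as.integer(sub("^w=", "", parts[2]))
    hex <- sub("^0x", "", parts[3])
    nyb <- rev(strtoi(strsplit(hex, "")[[1]], base = 16L))
    bits <- as.vector(vapply(nyb, function(v) as.integer(intToBits(v)[1:4]),
                             integer(4)))
    task_spec("table", w, table = bits[seq_len(2^w)], recursive = recursive)
  } else {
    task_spec(parts[1], as.integer(parts[2]), recursive = recursive)
  }
}
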