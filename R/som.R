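#' Choose a rectangular SOM grid for a requested node count
#'
#' Returns the factor pair `(rows, cols)` of `k` with `rows <= cols` that
#' minimizes `cols - rows`. If `k` is prime and greater than 20 (where a
#' `1 x k` grid would degenerate the topology), the smallest non-prime
#' `k' >= k` is factorized instead and the effective node count reported.
#'
#' @param k requested number of SOM nodes, at least 4.
#' @return A list with `rows`, `cols` and `k` (the effective node count,
#'   `rows * cols`).
#' @export
grid_from_k <- function(k) {
  if (!is.numeric(k) || length(k) != 1 || k < 4 || k != round(k))
    stop("k must be an integer >= 4")
  k <- as.integer(k)
  is_prime <- function(x) {
    if (x < 2) return(FALSE)
    if (x < 4) return(TRUE)
    if (x %% 2 == 0) return(FALSE)
    if (x < 9) return(TRUE)
    d <- seq(3, floor(sqrt(x)), by = 2)
    all(x %% d != 0)
  }
  keff <- k
  if (k > 20 && is_prime(k)) {
    keff <- k + 1L
    while (is_prime(keff)) keff <- keff + 1L
    message("k = ", k, " is prime; using effective k = ", keff)
  }
  divs <- seq_len(floor(sqrt(keff)))
  divs <- divs[keff %% divs == 0]
  r <- max(divs)
  list(rows = as.integer(r), cols = as.integer(keff / r), k = keff)
}

#' Train a self-organizing map over the expression matrix
#'
#' Online SOM training in the FlowSOM style: the codebook is initialized by
#' sampling `rows * cols` distinct events, then every event is presented
#' `epochs` times in seeded random order; each presentation moves the
#' best-matching node and all grid neighbours within the current radius toward
#' the event. The neighbourhood radius decays linearly from the 2/3 quantile
#' of pairwise node-to-node grid distances down to 0, and the learning rate
#' from 0.05 to 0.01. Runs are bit-reproducible for a given seed.
#'
#' @param matrix an [expression_matrix()] restricted to the clustering markers.
#' @param rows,cols grid dimensions; see [grid_from_k()].
#' @param epochs full passes over the data.
#' @param seed integer seed controlling initialization and presentation order.
#' @param alpha learning-rate range, decaying linearly across presentations.
#' @return An object of class `som_model` with elements `codebook`
#'   (`rows * cols` x markers), `rows`, `cols`, `k`, `epochs`, `seed`,
#'   `marker_names`.
#' @export
train_som <- function(matrix, rows, cols, epochs = 10, seed = 1L,
                      alpha = c(0.05, 0.01)) {
  stopifnot(inherits(matrix, "expression_matrix"))
  k <- as.integer(rows) * as.integer(cols)
  n <- matrix$n_events
  if (n < k) stop("need at least as many events (", n, ") as SOM nodes (", k, ")")
  if (!all(is.finite(matrix$values))) stop("non-finite expression values")

  gr <- (seq_len(k) - 1) %% rows
  gc <- (seq_len(k) - 1) %/% rows
  gd <- sqrt(outer(gr, gr, "-")^2 + outer(gc, gc, "-")^2)
  radius0 <- stats::quantile(gd[lower.tri(gd)], 2 / 3, names = FALSE)

  rng <- with_seed(seed, {
    init_idx <- sample.int(n, k)
    order <- as.integer(unlist(lapply(seq_len(epochs),
                                      function(e) sample.int(n, n))))
    list(init_idx = init_idx, order = order)
  })
  codebook <- .som_train_cpp(matrix$values,
                             matrix$values[rng$init_idx, , drop = FALSE],
                             as.integer(rows), as.integer(cols), rng$order,
                             radius0, alpha[1], alpha[2])
  colnames(codebook) <- matrix$marker_names
  structure(list(codebook = codebook, rows = as.integer(rows),
                 cols = as.integer(cols), k = k, epochs = as.integer(epochs),
                 seed = as.integer(seed), marker_names = matrix$marker_names,
                 init_idx = rng$init_idx),
            class = "som_model")
}

#' @export
print.som_model <- function(x, ...) {
  cat(sprintf("som_model: %d x %d grid (%d nodes), %d markers, seed %d\n",
              x$rows, x$cols, x$k, length(x$marker_names), x$seed))
  invisible(x)
}

#' Assign events to their best-matching SOM node
#'
#' Nearest codebook row in Euclidean distance; ties resolve to the lowest node
#' index. Empty nodes are permitted.
#'
#' @param model a `som_model` from [train_som()].
#' @param matrix an [expression_matrix()] over the same markers.
#' @return An object of class `node_assignment`: `node_of_event` (1-based node
#'   per event), `node_sizes` (length `k`, summing to the event count), and
#'   `quantization_error` (mean event-to-node distance).
#' @export
assign_events <- function(model, matrix) {
  stopifnot(inherits(model, "som_model"), inherits(matrix, "expression_matrix"))
  if (!identical(model$marker_names, matrix$marker_names))
    stop("marker sets of model and matrix differ")
  res <- .som_assign_cpp(model$codebook, matrix$values)
  sizes <- tabulate(res$node, nbins = model$k)
  structure(list(node_of_event = res$node, node_sizes = sizes,
                 quantization_error = mean(res$dist)),
            class = "node_assignment")
}

#' Export a SOM summary table
#'
#' One row per node: id, size, and per-marker medians of assigned events.
#'
#' @param model a `som_model`.
#' @param assignment a `node_assignment` for the same model.
#' @param matrix the [expression_matrix()] the assignment was computed on.
#' @return A data frame.
#' @export
som_summary <- function(model, assignment, matrix) {
  meds <- matrix(NA_real_, model$k, length(model$marker_names),
                 dimnames = list(NULL, model$marker_names))
  for (g in seq_len(model$k)) {
    idx <- which(assignment$node_of_event == g)
    if (length(idx))
      meds[g, ] <- apply(matrix$values[idx, , drop = FALSE], 2, stats::median)
  }
  data.frame(node = seq_len(model$k), size = assignment$node_sizes, meds,
             check.names = FALSE)
}
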