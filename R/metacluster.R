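#' Build a schedule of metacluster targets
#'
#' The default schedule evaluates every count from 5 to 50, then steps of 5 up
#' to 150, then steps of 10 (targets grow sparser where successive
#' metaclusterings change less). Targets are capped at `k` for the
#' hierarchical backend and at `floor(0.9 * k)` for the consensus backend,
#' whose item resampling needs spare nodes.
#'
#' @param k number of SOM nodes the targets will partition.
#' @param max_m largest target to consider (before capping).
#' @param backend `"hierarchical"` or `"consensus"`.
#' @param explicit optional explicit integer targets; sorted and deduplicated,
#'   overriding the default ladder.
#' @return An object of class `target_schedule`: `targets`, `cap`, `backend`.
#' @export
build_schedule <- function(k, max_m = k, backend = c("hierarchical", "consensus"),
                           explicit = NULL) {
  backend <- match.arg(backend)
  if (max_m < 5) stop("max_m must be at least 5")
  cap <- if (backend == "consensus") floor(0.9 * k) else as.integer(k)
  if (!is.null(explicit)) {
    targets <- sort(unique(as.integer(explicit)))
    if (any(targets < 2)) stop("metacluster targets must be >= 2")
    if (any(targets > cap))
      stop("target(s) ", paste(targets[targets > cap], collapse = ", "),
           " exceed the cap of ", cap,
           if (backend == "consensus")
             " (consensus metaclustering cannot exceed 90% of the SOM node count)"
           else " (cannot exceed the SOM node count)")
  } else {
    hi <- min(max_m, cap)
    targets <- c(seq(5, min(50, hi)),
                 if (hi > 50) seq(55, min(150, hi), by = 5),
                 if (hi > 150) seq(160, hi, by = 10))
    targets <- as.integer(targets[targets <= hi])
  }
  structure(list(targets = targets, cap = as.integer(cap), backend = backend),
            class = "target_schedule")
}

#' @export
print.target_schedule <- function(x, ...) {
  cat(sprintf("target_schedule (%s): %d targets in [%d, %d], cap %d\n",
              x$backend, length(x$targets), min(x$targets), max(x$targets),
              x$cap))
  invisible(x)
}

# single dendrogram over codebook rows; cuts for all m are nested
codebook_dendrogram <- function(model, minkowski_order = 2) {
  if (minkowski_order != 2)
    message("Ward linkage on squared Minkowski (order ", minkowski_order,
            ") distances is a heuristic extension of classical Ward")
  d <- stats::dist(model$codebook, method = "minkowski", p = minkowski_order)
  stats::hclust(d, method = "ward.D2")
}

#' Metacluster SOM nodes by hierarchical clustering
#'
#' Agglomerates the `k` codebook vectors with Ward linkage on Minkowski
#' distances (squared inside the Lance-Williams update, i.e. classical Ward
#' for order 2) and cuts the single dendrogram at `m` clusters. Cuts at
#' different `m` from the same model are nested.
#'
#' @param model a `som_model`.
#' @param m target number of metaclusters, in `[1, k]`.
#' @param minkowski_order Minkowski exponent; 2 (Euclidean) is the classical
#'   Ward setting and the default.
#' @param dendrogram optionally a precomputed [stats::hclust()] tree over the
#'   codebook (to reuse across a schedule).
#' @return An object of class `metacluster_result`: `m_target`,
#'   `metacluster_of_node` (1..m per node), `backend`, `linkage`,
#'   `minkowski_order`.
#' @export
hierarchical_metacluster <- function(model, m, minkowski_order = 2,
                                     dendrogram = NULL) {
  stopifnot(inherits(model, "som_model"))
  if (m < 1 || m > model$k) stop("m must be in [1, ", model$k, "]")
  if (is.null(dendrogram))
    dendrogram <- codebook_dendrogram(model, minkowski_order)
  cl <- stats::cutree(dendrogram, k = m)
  structure(list(m_target = as.integer(m),
                 metacluster_of_node = as.integer(unname(cl)),
                 backend = "hierarchical", linkage = "ward.D2",
                 minkowski_order = minkowski_order, seed = NA_integer_),
            class = "metacluster_result")
}

#' Metacluster SOM nodes by consensus (Monti) resampling
#'
#' For each of `reps` resamples, a fraction of the nodes is drawn without
#' replacement and clustered into `m` groups (Ward on Euclidean distance).
#' The consensus matrix records, per node pair, the fraction of co-drawn
#' resamples in which the pair co-clustered. The final partition is the
#' `m`-cluster cut of average-linkage clustering on `1 - consensus`.
#' Requires `m <= floor(0.9 * k)` so every resample retains more items than
#' clusters.
#'
#' @param model a `som_model`.
#' @param m target number of metaclusters.
#' @param reps number of resamples (>= 2).
#' @param item_fraction fraction of nodes drawn per resample, in (0, 1).
#' @param seed integer seed; the full procedure is deterministic given it.
#' @return A list with `result` (a `metacluster_result`) and `consensus`
#'   (a `consensus_matrix`: `values`, `reps`, `item_fraction`, `seed`).
#' @export
consensus_metacluster <- function(model, m, reps = 100, item_fraction = 0.8,
                                  seed = 1L) {
  stopifnot(inherits(model, "som_model"))
  k <- model$k
  cap <- floor(0.9 * k)
  if (m > cap)
    stop("m = ", m, " exceeds ", cap,
         ": consensus metaclustering cannot exceed 90% of the SOM node count")
  if (reps < 2) stop("reps must be >= 2")
  n_draw <- floor(item_fraction * k)
  if (n_draw <= m) stop("item_fraction draws too few nodes for m clusters")

  co <- matrix(0, k, k)     # co-clustered counts
  drawn <- matrix(0, k, k)  # co-drawn counts
  with_seed(seed, {
    for (r in seq_len(reps)) {
      idx <- sort(sample.int(k, n_draw))
      d <- stats::dist(model$codebook[idx, , drop = FALSE])
      cl <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = m)
      drawn[idx, idx] <- drawn[idx, idx] + 1
      for (g in seq_len(m)) {
        members <- idx[cl == g]
        co[members, members] <- co[members, members] + 1
      }
    }
  })
  consensus <- matrix(0, k, k)
  pos <- drawn > 0
  consensus[pos] <- co[pos] / drawn[pos]
  never <- sum(!pos[upper.tri(pos)])
  if (never > 0)
    warning(never, " node pair(s) never co-drawn across resamples; their ",
            "consensus is 0 (consider raising reps)")
  diag(consensus) <- 1

  final <- stats::cutree(stats::hclust(stats::as.dist(1 - consensus),
                                       method = "average"), k = m)
  result <- structure(list(m_target = as.integer(m),
                           metacluster_of_node = as.integer(unname(final)),
                           backend = "consensus", linkage = "average",
                           minkowski_order = 2, seed = as.integer(seed)),
                      class = "metacluster_result")
  cons <- structure(list(values = consensus, reps = as.integer(reps),
                         item_fraction = item_fraction, seed = as.integer(seed)),
                    class = "consensus_matrix")
  list(result = result, consensus = cons)
}

#' Compose node and metacluster maps into a per-event partition
#'
#' @param result a `metacluster_result`.
#' @param assignment a `node_assignment` over the same SOM.
#' @return Integer vector: metacluster id of every event.
#' @export
metacluster_of_events <- function(result, assignment) {
  stopifnot(inherits(result, "metacluster_result"),
            inherits(assignment, "node_assignment"))
  if (max(assignment$node_of_event) > length(result$metacluster_of_node))
    stop("node assignment refers to nodes absent from the metacluster map")
  result$metacluster_of_node[assignment$node_of_event]
}

#' Per-metacluster event index lists
#'
#' @param result a `metacluster_result`.
#' @param assignment a `node_assignment`.
#' @return A list of length `m_target`; element `c` holds the (1-based) event
#'   indices of metacluster `c`. The lists partition all events.
#' @export
events_per_metacluster <- function(result, assignment) {
  part <- metacluster_of_events(result, assignment)
  lapply(seq_len(result$m_target), function(c) which(part == c))
}
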