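#' Interquartile-range check
#'
#' Quartiles use linear interpolation of order statistics (position
#' `p * (n - 1) + 1`, the common statistical default). A distribution passes
#' if its IQR on the transformed scale does not exceed the threshold; a
#' boundary IQR equal to the threshold passes.
#'
#' @param sample numeric vector, non-empty.
#' @param threshold IQR limit on the arcsinh scale; the mass-cytometry default
#'   is 2.
#' @return A list with `iqr` and `pass`.
#' @export
iqr_check <- function(sample, threshold = 2) {
  if (length(sample) < 1) stop("empty sample")
  q <- stats::quantile(sample, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  list(iqr = iqr, pass = iqr <= threshold)
}

#' Score one metaclustering endpoint
#'
#' For every metacluster and every QC marker, the marker's distribution over
#' the metacluster's events is tested for unimodality (dip test at level
#' `alpha`) and for spread (IQR at most `iqr_threshold`). A cell passes when
#' the dip p-value is at least `alpha` AND the IQR is within the threshold.
#' Cells with fewer than `min_events` events are counted as passes and flagged
#' (the dip test cannot reject on tiny samples). The unimodality fraction `U`
#' is the fraction of passing cells over realized (non-empty) metaclusters.
#'
#' @param matrix an [expression_matrix()].
#' @param partition integer vector of per-event metacluster ids (contiguous
#'   from 1; empty ids are permitted and excluded from `U`).
#' @param qc_markers markers to evaluate (default: all markers of `matrix`).
#' @param alpha dip-test significance level.
#' @param iqr_threshold IQR limit on the transformed scale.
#' @param min_events cells smaller than this are flagged and counted as pass.
#' @param pvalue_method passed to [dip_pvalue()].
#' @param seed seed for Monte-Carlo p-values (ignored in table mode).
#' @return An object of class `qc_matrix` with matrices `pass`, `dip_p`,
#'   `iqr`, `cell_n`, `flagged` (metaclusters x markers), logical `realized`
#'   per metacluster, scalars `m`, `n_markers`, `U`, and the thresholds used.
#' @export
evaluate_metaclustering <- function(matrix, partition, qc_markers = NULL,
                                    alpha = 0.05, iqr_threshold = 2,
                                    min_events = 5,
                                    pvalue_method = c("table", "montecarlo"),
                                    seed = 1L) {
  stopifnot(inherits(matrix, "expression_matrix"))
  pvalue_method <- match.arg(pvalue_method)
  partition <- as.integer(partition)
  if (length(partition) != matrix$n_events)
    stop("partition must assign every event")
  if (is.null(qc_markers)) qc_markers <- matrix$marker_names
  missing <- setdiff(qc_markers, matrix$marker_names)
  if (length(missing)) stop("unknown QC marker(s): ",
                            paste(missing, collapse = ", "))
  m <- max(partition)
  sizes <- tabulate(partition, nbins = m)
  realized <- sizes > 0
  if (!any(realized)) stop("no non-empty metacluster in partition")
  nj <- length(qc_markers)
  cols <- match(qc_markers, matrix$marker_names)

  dims <- list(metacluster = seq_len(m), marker = qc_markers)
  dip_p <- iqr <- matrix(NA_real_, m, nj, dimnames = dims)
  cell_n <- matrix(0L, m, nj, dimnames = dims)
  pass <- flagged <- matrix(NA, m, nj, dimnames = dims)

  idx_by_cluster <- split(seq_along(partition), factor(partition,
                                                       levels = seq_len(m)))
  for (c in which(realized)) {
    idx <- idx_by_cluster[[c]]
    for (j in seq_len(nj)) {
      x <- matrix$values[idx, cols[j]]
      cell_n[c, j] <- length(x)
      ic <- iqr_check(x, iqr_threshold)
      iqr[c, j] <- ic$iqr
      if (length(x) < min_events) {
        flagged[c, j] <- TRUE
        pass[c, j] <- TRUE
      } else {
        flagged[c, j] <- FALSE
        D <- dip_statistic(x)
        dip_p[c, j] <- dip_pvalue(D, length(x), method = pvalue_method,
                                  seed = seed)
        pass[c, j] <- (dip_p[c, j] >= alpha) && ic$pass
      }
    }
  }
  U <- mean(pass[realized, , drop = FALSE])
  structure(list(pass = pass, dip_p = dip_p, iqr = iqr, cell_n = cell_n,
                 flagged = flagged, realized = realized, m = m,
                 m_realized = sum(realized), n_markers = nj, U = U,
                 alpha = alpha, iqr_threshold = iqr_threshold,
                 min_events = min_events, markers = qc_markers),
            class = "qc_matrix")
}

#' @export
print.qc_matrix <- function(x, ...) {
  cat(sprintf("qc_matrix: %d metaclusters (%d realized) x %d markers, U = %.4f\n",
              x$m, x$m_realized, x$n_markers, x$U))
  invisible(x)
}

#' Unimodality fraction of a QC matrix
#'
#' `U` = passing cells / counted cells, counting only realized (non-empty)
#' metaclusters. Equals the mean over markers of per-marker pass fractions.
#'
#' @param qc a `qc_matrix`.
#' @return A number in `[0, 1]`.
#' @export
unimodality_fraction <- function(qc) {
  stopifnot(inherits(qc, "qc_matrix"))
  mean(qc$pass[qc$realized, , drop = FALSE])
}

#' Assemble the unimodality set
#'
#' Orders `(m_i, U_i)` pairs across the evaluated schedule into the set the
#' knee detection consumes.
#'
#' @param qcs list of `qc_matrix` objects (or any list with `m` and `U`
#'   fields), one per evaluated target; targets must be distinct.
#' @param m_targets optional integer targets overriding the `m` fields (use
#'   when a target realized fewer metaclusters than requested).
#' @return An object of class `unimodality_set`: a data frame with columns
#'   `m` and `U`, sorted by `m`.
#' @export
assemble_unimodality_set <- function(qcs, m_targets = NULL) {
  if (length(qcs) == 0) stop("no QC matrices supplied")
  ms <- if (!is.null(m_targets)) as.integer(m_targets)
        else vapply(qcs, function(q) as.integer(q$m), integer(1))
  Us <- vapply(qcs, function(q) q$U, numeric(1))
  if (anyDuplicated(ms)) stop("duplicate metacluster targets: ",
                              paste(ms[duplicated(ms)], collapse = ", "))
  o <- order(ms)
  structure(data.frame(m = ms[o], U = Us[o]),
            class = c("unimodality_set", "data.frame"))
}

#' Per-marker QC performance across the schedule
#'
#' For one marker, the fraction of realized metaclusters whose distribution
#' passed both checks, per evaluated target. Averaging these curves over all
#' markers reproduces the unimodality set.
#'
#' @param qcs list of `qc_matrix` objects keyed by target.
#' @param marker marker name, present in all QC matrices.
#' @return Data frame with columns `m` and `fraction`.
#' @export
marker_performance <- function(qcs, marker) {
  if (length(qcs) == 0) stop("no QC matrices supplied")
  rows <- lapply(qcs, function(q) {
    if (!marker %in% q$markers) stop("marker '", marker,
                                     "' absent from a QC matrix")
    data.frame(m = q$m,
               fraction = mean(q$pass[q$realized, marker]))
  })
  out <- do.call(rbind, rows)
  out[order(out$m), , drop = FALSE]
}
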