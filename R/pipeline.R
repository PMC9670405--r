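`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' Every knob of the pipeline with its documented default. A single global
#' `seed` fans out deterministically to the stages (subsampling, SOM
#' initialization and presentation order, consensus resampling, Monte-Carlo
#' p-values), so one integer reproduces a run bit-for-bit.
#'
#' @param markers clustering markers (NULL: all channels of the input).
#' @param qc_markers markers for the unimodality/IQR QC (NULL: the clustering
#'   markers).
#' @param label_column optional label column of delimited input.
#' @param cofactor arcsinh cofactor (mass-cytometry convention: 5).
#' @param som_k requested SOM node count; around 200 is a sensible default so
#'   the smallest subsets are still overclustered. Ignored when
#'   `som_rows`/`som_cols` are given.
#' @param som_rows,som_cols explicit grid shape (optional).
#' @param som_epochs training passes over the events.
#' @param backend `"hierarchical"` (Ward on Minkowski distances) or
#'   `"consensus"` (Monti resampling).
#' @param minkowski_order Minkowski exponent for the hierarchical backend.
#' @param reps,item_fraction consensus resampling parameters.
#' @param schedule explicit metacluster targets (NULL: the default ladder of
#'   [build_schedule()]).
#' @param max_m largest target for the default ladder (NULL: the backend cap).
#' @param alpha dip-test significance level.
#' @param iqr_threshold IQR limit on the transformed scale.
#' @param min_events cells smaller than this count as pass and are flagged.
#' @param pvalue_method `"table"` or `"montecarlo"` (see [dip_pvalue()]).
#' @param knee_mode `"fitted"` or `"raw"` (see [find_inflection()]).
#' @param robustness_fraction,robustness_R defaults for
#'   [replicate_robustness()].
#' @param subsample_fraction optional event subsampling applied at ingestion.
#' @param seed global integer seed.
#' @param threads evaluate schedule targets concurrently when > 1; results
#'   are identical to serial execution.
#' @return A list of class `inflect_config`.
#' @export
inflect_config <- function(markers = NULL, qc_markers = NULL,
                           label_column = NULL, cofactor = 5,
                           som_k = 200L, som_rows = NULL, som_cols = NULL,
                           som_epochs = 10L,
                           backend = c("hierarchical", "consensus"),
                           minkowski_order = 2, reps = 100L,
                           item_fraction = 0.8, schedule = NULL, max_m = NULL,
                           alpha = 0.05, iqr_threshold = 2, min_events = 5L,
                           pvalue_method = "table",
                           knee_mode = c("fitted", "raw"),
                           robustness_fraction = 0.9, robustness_R = 15L,
                           subsample_fraction = 1, seed = 1L, threads = 1L) {
  cfg <- list(markers = markers, qc_markers = qc_markers,
              label_column = label_column, cofactor = cofactor,
              som_k = som_k, som_rows = som_rows, som_cols = som_cols,
              som_epochs = som_epochs, backend = match.arg(backend),
              minkowski_order = minkowski_order, reps = reps,
              item_fraction = item_fraction, schedule = schedule,
              max_m = max_m, alpha = alpha, iqr_threshold = iqr_threshold,
              min_events = min_events, pvalue_method = pvalue_method,
              knee_mode = match.arg(knee_mode),
              robustness_fraction = robustness_fraction,
              robustness_R = robustness_R,
              subsample_fraction = subsample_fraction,
              seed = as.integer(seed), threads = as.integer(threads))
  class(cfg) <- "inflect_config"
  cfg
}

#' Compute the unimodality curve for an expression matrix
#'
#' The computational core shared by [run_pipeline()] and
#' [replicate_robustness()]: trains the SOM (seed `seed + 1`), assigns
#' events, builds the target schedule, metaclusters and QC-scores every
#' target (per-target seeds are functions of the target, so evaluation order
#' and concurrency cannot change results), and assembles the unimodality set.
#'
#' @param matrix an [expression_matrix()] restricted to clustering markers.
#' @param config an [inflect_config()].
#' @return A list: `som`, `assignment`, `schedule`, `results` (per-target
#'   `metacluster_result`s), `qcs` (per-target `qc_matrix`), `uset`.
#' @export
pipeline_curve <- function(matrix, config = inflect_config()) {
  stopifnot(inherits(matrix, "expression_matrix"),
            inherits(config, "inflect_config"))
  grid <- if (!is.null(config$som_rows) && !is.null(config$som_cols))
    list(rows = as.integer(config$som_rows), cols = as.integer(config$som_cols),
         k = as.integer(config$som_rows) * as.integer(config$som_cols))
  else grid_from_k(config$som_k)
  som <- train_som(matrix, grid$rows, grid$cols, epochs = config$som_epochs,
                   seed = config$seed + 1L)
  assignment <- assign_events(som, matrix)
  sched <- build_schedule(som$k, max_m = config$max_m %||% som$k,
                          backend = config$backend,
                          explicit = config$schedule)
  dend <- if (config$backend == "hierarchical")
    codebook_dendrogram(som, config$minkowski_order) else NULL

  eval_target <- function(m) {
    res <- if (config$backend == "hierarchical")
      hierarchical_metacluster(som, m, config$minkowski_order, dendrogram = dend)
    else
      consensus_metacluster(som, m, reps = config$reps,
                            item_fraction = config$item_fraction,
                            seed = config$seed + 2L + m)$result
    part <- metacluster_of_events(res, assignment)
    qc <- evaluate_metaclustering(matrix, part,
                                  qc_markers = config$qc_markers,
                                  alpha = config$alpha,
                                  iqr_threshold = config$iqr_threshold,
                                  min_events = config$min_events,
                                  pvalue_method = config$pvalue_method,
                                  seed = config$seed + 10000L + m)
    list(m = m, result = res, qc = qc)
  }
  evaluated <- if (config$threads > 1 &&
                   .Platform$OS.type == "unix")
    parallel::mclapply(sched$targets, eval_target,
                       mc.cores = config$threads, mc.preschedule = TRUE)
  else lapply(sched$targets, eval_target)

  qcs <- lapply(evaluated, `[[`, "qc")
  uset <- assemble_unimodality_set(qcs, m_targets = sched$targets)
  list(som = som, assignment = assignment, schedule = sched,
       results = lapply(evaluated, `[[`, "result"), qcs = qcs, uset = uset)
}

#' Run the full pipeline and write a run directory
#'
#' Read -> arcsinh transform -> SOM overclustering -> metaclustering + QC per
#' scheduled target -> unimodality set -> knee. Writes, under `output_dir`:
#' `unimodality_set.csv`, per-target `qc/qc_m*.csv` (one row per realized
#' metacluster-marker cell), `nodes_at_knee.csv` (node, metacluster at the
#' knee, size), `fit_parameters.csv`, `error_profile.csv`,
#' `knee_summary.csv`, `matching_matrix.csv` (when labels are present),
#' `config.yaml` (the resolved configuration, verbatim), and `log.txt`.
#' Identical config and seed reproduce the outputs byte for byte.
#'
#' @param input a path (FCS or delimited), an [event_table()], or an
#'   [expression_matrix()] (already transformed).
#' @param config an [inflect_config()].
#' @param output_dir run directory; created if missing.
#' @return Invisibly, a list with `curve` (see [pipeline_curve()]),
#'   `inflection`, and `output_dir`.
#' @export
run_pipeline <- function(input, config = inflect_config(),
                         output_dir = tempfile("inflect_run_")) {
  t0 <- Sys.time()
  log_lines <- character()
  log <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
    message(msg)
  }
  mat <- if (inherits(input, "expression_matrix")) {
    log("stage ingest: expression matrix with %d events", input$n_events)
    if (!is.null(config$markers)) {
      keep <- match(config$markers, input$marker_names)
      if (anyNA(keep)) stop("stage ingest: unknown clustering marker(s)")
      expression_matrix(input$values[, keep, drop = FALSE], config$markers,
                        input$cofactor, input$labels)
    } else input
  } else {
    tab <- if (inherits(input, "event_table")) input
    else {
      log("stage ingest: reading %s", input)
      read_events(input, label_column = config$label_column)
    }
    transform_arcsinh(tab, cofactor = config$cofactor,
                      markers = config$markers)
  }
  if (config$subsample_fraction < 1) {
    mat <- subsample(mat, config$subsample_fraction, seed = config$seed)
    log("stage subsample: kept %d events", mat$n_events)
  }

  log("stage som: training on %d events x %d markers", mat$n_events,
      length(mat$marker_names))
  curve <- tryCatch(pipeline_curve(mat, config), error = function(e)
    stop("stage clustering/qc failed: ", conditionMessage(e)))
  log("stage schedule: evaluated %d targets on a %d-node SOM",
      length(curve$schedule$targets), curve$som$k)
  inflection <- tryCatch(find_inflection(curve$uset, mode = config$knee_mode),
                         error = function(e)
                           stop("stage knee failed: ", conditionMessage(e)))
  log("stage knee: m = %d (U = %.4f, %s mode)", inflection$knee_m,
      inflection$U_at_knee, inflection$mode)

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(output_dir, "qc"), showWarnings = FALSE)
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(output_dir, name), row.names = FALSE)

  wcsv(data.frame(m = curve$uset$m, U = curve$uset$U), "unimodality_set.csv")
  for (i in seq_along(curve$qcs)) {
    qc <- curve$qcs[[i]]
    m <- curve$schedule$targets[i]
    rows <- which(qc$realized)
    long <- do.call(rbind, lapply(rows, function(c) data.frame(
      metacluster = c, marker = qc$markers, n = qc$cell_n[c, ],
      iqr = qc$iqr[c, ], dip_p = qc$dip_p[c, ], flagged = qc$flagged[c, ],
      pass = qc$pass[c, ])))
    utils::write.csv(long, file.path(output_dir, "qc",
                                     sprintf("qc_m%03d.csv", m)),
                     row.names = FALSE)
  }
  knee_idx <- match(inflection$knee_m, curve$schedule$targets)
  if (is.na(knee_idx)) # fitted-mode knee may fall between evaluated targets
    knee_idx <- which.min(abs(curve$schedule$targets - inflection$knee_m))
  knee_res <- curve$results[[knee_idx]]
  nodes <- som_summary(curve$som, curve$assignment, mat)
  nodes <- cbind(nodes[, c("node", "size")],
                 metacluster = knee_res$metacluster_of_node,
                 nodes[, curve$som$marker_names, drop = FALSE])
  wcsv(nodes, "nodes_at_knee.csv")
  fit <- inflection$fit
  wcsv(data.frame(A = fit$A %||% NA, K = fit$K %||% NA, M = fit$M %||% NA,
                  B = fit$B %||% NA, rmse = fit$rmse %||% NA,
                  converged = !is.null(fit) && fit$converged),
       "fit_parameters.csv")
  wcsv(inflection$error_profile, "error_profile.csv")
  wcsv(data.frame(knee_m = inflection$knee_m, U_at_knee = inflection$U_at_knee,
                  mode = inflection$mode, evaluated_target =
                    curve$schedule$targets[knee_idx],
                  backend = config$backend, som_k = curve$som$k,
                  ward_variant = "ward.D2",
                  knee_grid = "dense integer grid over evaluated range",
                  U_denominator = "realized metaclusters only"),
       "knee_summary.csv")
  if (!is.null(mat$labels) && any(nzchar(mat$labels))) {
    mm <- matching_matrix(mat$labels,
                          metacluster_of_events(knee_res, curve$assignment))
    utils::write.csv(as.data.frame(mm), file.path(output_dir,
                                                  "matching_matrix.csv"))
  }
  yaml::write_yaml(unclass(config), file.path(output_dir, "config.yaml"))
  log("run complete in %.1f s; outputs in %s",
      as.numeric(difftime(Sys.time(), t0, units = "secs")), output_dir)
  writeLines(log_lines, file.path(output_dir, "log.txt"))
  invisible(list(curve = curve, inflection = inflection,
                 output_dir = output_dir))
}

#' Label-versus-metacluster matching matrix
#'
#' Contingency counts of published (or synthetic) per-event labels against
#' discovered metaclusters. By default only labeled events are considered;
#' `""` and `NA` mark unlabeled events.
#'
#' @param labels per-event label strings.
#' @param partition per-event metacluster ids.
#' @param labeled_only drop unlabeled events (default TRUE).
#' @return An object of class `matching_matrix` wrapping the counts matrix
#'   (labels x metaclusters); `as.data.frame()` gives the table.
#' @export
matching_matrix <- function(labels, partition, labeled_only = TRUE) {
  if (length(labels) != length(partition))
    stop("labels and partition must have equal length")
  labels <- as.character(labels)
  labels[is.na(labels)] <- ""
  keep <- if (labeled_only) nzchar(labels) else rep(TRUE, length(labels))
  counts <- table(label = labels[keep],
                  metacluster = factor(partition[keep],
                                       levels = sort(unique(partition))))
  counts <- unclass(counts)
  structure(list(counts = counts, label_names = rownames(counts),
                 metacluster_ids = colnames(counts),
                 labeled_only = labeled_only),
            class = "matching_matrix")
}

#' @export
as.data.frame.matching_matrix <- function(x, ...) {
  as.data.frame.matrix(x$counts)
}

#' @export
print.matching_matrix <- function(x, ...) {
  cat(sprintf("matching_matrix: %d labels x %d metaclusters (%d events%s)\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              if (x$labeled_only) ", labeled only" else ""))
  invisible(x)
}

#' Read a unimodality set from a U-vs-m CSV
#'
#' @param path CSV with columns `m` and `U` (as written by [run_pipeline()]).
#' @return A `unimodality_set`.
#' @export
read_unimodality_set <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("m", "U") %in% names(df))) stop("expected columns m and U")
  df <- df[order(df$m), c("m", "U")]
  structure(df, class = c("unimodality_set", "data.frame"))
}
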