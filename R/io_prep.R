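#' Event-level cytometry table
#'
#' Lightweight container for raw (untransformed) event-level data: an
#' events-by-channels matrix of non-negative intensities, unique channel
#' names, and optional per-event phenotype labels.
#'
#' @param values numeric matrix, events in rows, channels in columns.
#' @param channel_names character vector of unique channel names.
#' @param labels optional character vector, one entry per event; `""` marks an
#'   unlabeled event.
#' @param sample_id identifier carried through to outputs.
#' @return An object of class `event_table`.
#' @export
event_table <- function(values, channel_names, labels = NULL, sample_id = "sample") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (length(channel_names) != ncol(values))
    stop("channel_names must have one entry per column")
  if (anyDuplicated(channel_names))
    stop("duplicate channel names: ",
         paste(unique(channel_names[duplicated(channel_names)]), collapse = ", "))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(values))
      stop("labels must have one entry per event")
  }
  colnames(values) <- channel_names
  structure(list(values = values, channel_names = as.character(channel_names),
                 labels = labels, sample_id = sample_id),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event_table '%s': %d events x %d channels%s\n", x$sample_id,
              nrow(x$values), ncol(x$values),
              if (is.null(x$labels)) "" else sprintf(" (%d labeled)",
                                                     sum(nzchar(x$labels)))))
  invisible(x)
}

#' Transformed expression matrix
#'
#' Events-by-markers values on the arcsinh scale, the universe consumed by the
#' clustering and QC stages.
#'
#' @param values numeric matrix on the transformed scale.
#' @param marker_names unique marker names.
#' @param cofactor positive cofactor used in `arcsinh(x / cofactor)`.
#' @param labels optional per-event labels.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, marker_names = colnames(values),
                              cofactor = 5, labels = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(marker_names)) marker_names <- paste0("M", seq_len(ncol(values)))
  if (length(marker_names) != ncol(values) || anyDuplicated(marker_names))
    stop("marker_names must be unique, one per column")
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (!is.null(labels) && length(labels) != nrow(values))
    stop("labels must have one entry per event")
  colnames(values) <- marker_names
  structure(list(values = values, marker_names = as.character(marker_names),
                 cofactor = cofactor, n_events = nrow(values),
                 labels = if (is.null(labels)) NULL else as.character(labels)),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d events x %d markers (cofactor %g)\n",
              x$n_events, length(x$marker_names), x$cofactor))
  invisible(x)
}

#' Read event-level cytometry data
#'
#' Reads an FCS file or a delimited text table (comma or tab, header row) into
#' an [event_table()]. For delimited input a label column may be split off into
#' per-event phenotype labels.
#'
#' @param path file to read.
#' @param format `"fcs"`, `"csv"` or `"tsv"`; `"auto"` guesses from the file
#'   extension.
#' @param label_column optional name of a column holding phenotype labels; it
#'   is removed from the channels and stored as `labels`.
#' @param sample_id identifier; defaults to the file name.
#' @return An [event_table()].
#' @export
read_events <- function(path, format = c("auto", "fcs", "csv", "tsv"),
                        label_column = NULL, sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, fcs = "fcs", tsv = "tsv", txt = "tsv", "csv")
  }
  if (is.null(sample_id)) sample_id <- basename(path)
  if (format == "fcs") {
    fcs <- read_fcs(path)
    values <- fcs$values
    channels <- fcs$channel_names
    labels <- NULL
    if (!is.null(label_column)) {
      if (!label_column %in% channels) stop("label column '", label_column,
                                            "' not present in FCS channels")
      labels <- as.character(values[, match(label_column, channels)])
      keep <- channels != label_column
      values <- values[, keep, drop = FALSE]
      channels <- channels[keep]
    }
    return(event_table(values, channels, labels, sample_id))
  }
  sep <- if (format == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  channels <- names(df)
  if (anyDuplicated(channels))
    stop("duplicate channel names in '", path, "': ",
         paste(unique(channels[duplicated(channels)]), collapse = ", "))
  labels <- NULL
  if (!is.null(label_column)) {
    if (!label_column %in% channels)
      stop("label column '", label_column, "' not found")
    labels <- as.character(df[[label_column]])
    labels[is.na(labels)] <- ""
    df <- df[channels != label_column]
    channels <- names(df)
  }
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1]
      stop(sprintf("non-numeric value in column '%s', row %d", channels[j],
                   if (is.na(bad)) 1L else bad))
    }
  }
  event_table(as.matrix(df), channels, labels, sample_id)
}

#' Arcsinh-transform an event table
#'
#' Applies the mass-cytometry variance-stabilizing transform
#' `arcsinh(x / cofactor)` and restricts to the requested markers. The
#' transform is applied exactly once, at ingestion; all downstream thresholds
#' (notably the IQR limit) are interpreted on this scale.
#'
#' @param table an [event_table()].
#' @param cofactor positive real; the mass-cytometry convention is 5.
#' @param markers optional subset of channel names to keep (default: all).
#' @return An [expression_matrix()]; labels are carried through unchanged.
#' @export
transform_arcsinh <- function(table, cofactor = 5, markers = NULL) {
  stopifnot(inherits(table, "event_table"))
  if (!is.numeric(cofactor) || length(cofactor) != 1 || cofactor <= 0)
    stop("cofactor must be a positive number")
  if (is.null(markers)) markers <- table$channel_names
  missing <- setdiff(markers, table$channel_names)
  if (length(missing))
    stop("unknown marker(s): ", paste(missing, collapse = ", "))
  raw <- table$values[, match(markers, table$channel_names), drop = FALSE]
  if (any(raw < 0))
    warning("negative raw intensities present; transformed as-is ",
            "(distributions straddling zero can confound the unimodality QC)")
  expression_matrix(asinh(raw / cofactor), markers, cofactor, table$labels)
}

#' Subsample events uniformly without replacement
#'
#' @param matrix an [expression_matrix()].
#' @param fraction fraction of events to keep, in (0, 1].
#' @param seed integer seed; the same seed always selects the same events.
#' @return An [expression_matrix()] with `round(fraction * n_events)` events in
#'   their original order; labels are subsampled in lockstep.
#' @export
subsample <- function(matrix, fraction, seed) {
  stopifnot(inherits(matrix, "expression_matrix"))
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  if (fraction == 1) return(matrix)
  n <- matrix$n_events
  m <- round(fraction * n)
  keep <- sort(with_seed(seed, sample.int(n, m)))
  expression_matrix(matrix$values[keep, , drop = FALSE], matrix$marker_names,
                    matrix$cofactor,
                    if (is.null(matrix$labels)) NULL else matrix$labels[keep])
}

#' Back-transform an expression matrix to raw-scale counts
#'
#' Inverse of [transform_arcsinh()]: `sinh(x) * cofactor`. Used to emit
#' raw-scale fixtures that exercise the ingestion path.
#'
#' @param matrix an [expression_matrix()].
#' @return An [event_table()] on the raw intensity scale.
#' @export
as_raw_counts <- function(matrix) {
  stopifnot(inherits(matrix, "expression_matrix"))
  event_table(sinh(matrix$values) * matrix$cofactor, matrix$marker_names,
              matrix$labels)
}

# run expr under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
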