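#' Read an FCS 3.0/3.1 file
#'
#' Minimal reader for list-mode FCS files: parses the header and TEXT segment,
#' then decodes the DATA segment for `$DATATYPE` F (float), D (double) or I
#' (unsigned integer, 8/16/32 bit) in either byte order. Channel names prefer
#' the stain name `$PnS` and fall back to the short name `$PnN`.
#'
#' @param path file to read.
#' @return A list with `values` (events x channels matrix), `channel_names`,
#'   and `keywords` (the parsed TEXT segment).
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  if (nchar(header) < 58) stop("'", path, "' is too short to be an FCS file")
  version <- substr(header, 1, 6)
  if (!grepl("^FCS3\\.", version) && !grepl("^FCS2\\.", version))
    stop("'", path, "' does not look like an FCS file (version '", version, "')")
  off <- function(a, b) suppressWarnings(as.numeric(trimws(substr(header, a, b))))
  text_beg <- off(11, 18); text_end <- off(19, 26)
  data_beg <- off(27, 34); data_end <- off(35, 42)
  if (is.na(text_beg) || is.na(text_end) || text_end <= text_beg)
    stop("invalid TEXT segment offsets in '", path, "'")

  seek(con, text_beg)
  text <- readChar(con, text_end - text_beg + 1, useBytes = TRUE)
  delim <- substr(text, 1, 1)
  parts <- strsplit(substring(text, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- as.list(parts[seq(2, length(parts), by = 2)])
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))

  need <- function(key) {
    if (is.null(kw[[key]])) stop("FCS file lacks required keyword ", key)
    kw[[key]]
  }
  p <- as.integer(need("$PAR"))
  n <- as.integer(need("$TOT"))
  dtype <- toupper(trimws(need("$DATATYPE")))
  mode <- toupper(trimws(need("$MODE")))
  if (mode != "L") stop("only list-mode ($MODE L) FCS data is supported")
  byteord <- trimws(need("$BYTEORD"))
  endian <- if (substr(byteord, 1, 1) == "1") "little" else "big"
  if (is.na(data_beg) || data_beg == 0) data_beg <- as.numeric(need("$BEGINDATA"))
  if (is.na(data_end) || data_end == 0) data_end <- as.numeric(need("$ENDDATA"))

  bits <- vapply(seq_len(p), function(j) as.integer(kw[[paste0("$P", j, "B")]]),
                 integer(1))
  what <- switch(dtype, F = "numeric", D = "numeric", I = "integer",
                 stop("unsupported $DATATYPE '", dtype, "'"))
  size <- switch(dtype, F = 4L, D = 8L, I = bits[1] / 8L)
  if (dtype %in% c("F", "D") || length(unique(bits)) == 1) {
    seek(con, data_beg)
    vals <- readBin(con, what, n = n * p, size = size, endian = endian,
                    signed = size > 2)
    if (length(vals) < n * p) stop("truncated DATA segment in '", path, "'")
    values <- matrix(as.numeric(vals), nrow = n, ncol = p, byrow = TRUE)
  } else {
    stop("mixed-width integer FCS data is not supported")
  }

  channel_names <- vapply(seq_len(p), function(j) {
    s <- kw[[paste0("$P", j, "S")]]
    if (!is.null(s) && nzchar(trimws(s))) trimws(s)
    else {
      nm <- kw[[paste0("$P", j, "N")]]
      if (is.null(nm) || !nzchar(trimws(nm))) paste0("P", j) else trimws(nm)
    }
  }, character(1))
  colnames(values) <- channel_names
  list(values = values, channel_names = channel_names, keywords = kw)
}

#' Write an FCS 3.1 file
#'
#' Emits list-mode single-precision float data, little-endian, one data set.
#' Intended for fixtures and for exporting synthetic data; raw intensities
#' should be written (the reader/transform pipeline applies arcsinh itself).
#'
#' @param table an [event_table()] or a numeric matrix with column names.
#' @param path output file.
#' @param stain_names optional `$PnS` stain names, one per channel (readers
#'   prefer them over the short `$PnN` names).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(table, path, stain_names = NULL) {
  if (inherits(table, "event_table")) {
    values <- table$values
    channels <- table$channel_names
  } else {
    values <- as.matrix(table)
    channels <- colnames(values)
    if (is.null(channels)) channels <- paste0("P", seq_len(ncol(values)))
  }
  n <- nrow(values); p <- ncol(values)
  d <- "/"
  rng <- function(x) format(max(1, ceiling(max(x, na.rm = TRUE) + 1)),
                            scientific = FALSE)
  build_text <- function(data_beg, data_end) {
    # fixed 8-digit data offsets keep the TEXT length independent of the values
    kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
            "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
            "$BEGINDATA", sprintf("%08d", data_beg),
            "$ENDDATA", sprintf("%08d", data_end),
            "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
            "$NEXTDATA", "0", "$PAR", as.character(p), "$TOT", as.character(n))
    for (j in seq_len(p)) {
      kw <- c(kw, paste0("$P", j, "B"), "32",
              paste0("$P", j, "E"), "0,0",
              paste0("$P", j, "N"), channels[j],
              paste0("$P", j, "R"), rng(values[, j]))
      if (!is.null(stain_names))
        kw <- c(kw, paste0("$P", j, "S"), stain_names[j])
    }
    paste0(d, paste0(kw, collapse = d), d)
  }
  header_len <- 58L
  text_beg <- header_len
  text_end <- text_beg + nchar(build_text(0, 0), type = "bytes") - 1L
  data_beg <- text_end + 1L
  data_end <- data_beg + 4L * n * p - 1L
  if (data_end > 99999999) stop("dataset too large for this FCS writer")
  text <- build_text(data_beg, data_end)

  fmt8 <- function(x) formatC(x, width = 8, flag = " ")
  header <- paste0("FCS3.1    ", fmt8(text_beg), fmt8(text_end),
                   fmt8(data_beg), fmt8(data_end), fmt8(0), fmt8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  writeBin(as.numeric(t(values)), con, size = 4L, endian = "little")
  invisible(path)
}
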