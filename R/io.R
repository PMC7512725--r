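#' Read a univariate signal from a text file
#'
#' Accepts plain text or CSV with one sample per row (an optional single
#' header line is skipped automatically when it is not numeric).  Non-numeric
#' or missing entries are rejected with the offending line number.
#'
#' @param path file path.
#' @param column column index for multi-column CSV (default 1).
#' @param sep field separator (default \code{","}; whitespace-separated files
#'   work for single-column input).
#' @return numeric vector of samples.
#' @export
read_signal <- function(path, column = 1L, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty input file: ", path, call. = FALSE)
  cell <- function(line) {
    parts <- trimws(strsplit(line, sep, fixed = TRUE)[[1]])
    if (column > length(parts)) NA_character_ else parts[column]
  }
  cells <- vapply(lines, cell, character(1), USE.NAMES = FALSE)
  vals <- suppressWarnings(as.numeric(cells))
  start <- 1L
  if (is.na(vals[1]) && length(vals) > 1L) start <- 2L  # header line
  bad <- which(is.na(vals[start:length(vals)])) + start - 1L
  if (length(bad) > 0L)
    stop(sprintf("non-numeric value %s at line %d of %s",
                 dQuote(cells[bad[1]]), bad[1], path), call. = FALSE)
  x <- vals[start:length(vals)]
  if (length(x) == 0L) stop("empty input file: ", path, call. = FALSE)
  .check_signal(x)
  x
}

#' Write an entropy estimate or experiment table to CSV/TSV
#'
#' Numeric values are written with 6 significant digits; undefined entropy
#' values are serialized as the token \code{"undefined"}, never as a number.
#' An \code{"entropy_estimate"} becomes a one-row table of its method,
#' parameters and values; data frames are written as-is.
#'
#' @param x an \code{"entropy_estimate"} or a data frame.
#' @param path output path.
#' @param format \code{"csv"} or \code{"tsv"}.
#' @return the written data frame, invisibly.
#' @export
write_result <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (inherits(x, "entropy_estimate")) {
    x <- data.frame(
      estimator = x$method,
      params = paste(names(x$params),
                     vapply(x$params, function(p) base::format(p), character(1)),
                     sep = "=", collapse = ";"),
      raw = if (isTRUE(x$undefined)) NA_real_ else x$raw,
      normalized = if (isTRUE(x$undefined)) NA_real_ else x$normalized,
      undefined = isTRUE(x$undefined),
      reason = if (isTRUE(x$undefined)) x$reason else "",
      stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) stop("nothing writable: need a data frame", call. = FALSE)
  out <- x
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) {
      v <- signif(out[[j]], 6)
      v <- as.character(v)
      v[is.na(out[[j]])] <- "undefined"
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(x)
}
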