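# Binary sample-by-event matrices: ingestion, validation, mu-filtering.

#' Construct a binary event matrix
#'
#' An `event_matrix` is the universal input of the package: a binary
#' table with one row per sample (patient) and one column per genomic
#' driver event. A cell value of 1 records the presence of the event in
#' that sample.
#'
#' @param values matrix coercible to integer 0/1, samples in rows.
#' @param sample_ids character vector of unique sample identifiers.
#' @param event_names character vector of unique event (column) names.
#' @return An `event_matrix`: an integer matrix with `sample_ids` as row
#'   names and `event_names` as column names.
#' @export
event_matrix <- function(values, sample_ids = rownames(values),
                         event_names = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%d", seq_len(nrow(values)))
  if (is.null(event_names)) stop("event names are required")
  sample_ids <- as.character(sample_ids)
  event_names <- as.character(event_names)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(event_names))
    stop("duplicate event names: ",
         paste(unique(event_names[duplicated(event_names)]), collapse = ", "))
  if (length(sample_ids) != nrow(values) || length(event_names) != ncol(values))
    stop("dimension mismatch between values and names")
  if (anyNA(values))
    stop("missing cells in event matrix")
  storage.mode(values) <- "integer"
  bad <- which(!(values == 0L | values == 1L), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-binary cell at sample '%s', event '%s'",
                 sample_ids[bad[1, 1]], event_names[bad[1, 2]]))
  dimnames(values) <- list(sample_ids, event_names)
  class(values) <- c("event_matrix", class(values))
  values
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("event_matrix: %d samples x %d events, %d event calls\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Sample identifiers of an event matrix
#' @param m an `event_matrix`.
#' @return Character vector of sample ids (row names).
#' @export
sample_ids <- function(m) rownames(m)

#' Event names of an event matrix
#' @param m an `event_matrix`.
#' @return Character vector of event names (column names).
#' @export
event_names <- function(m) colnames(m)

normalize_cell_tokens <- function(x) {
  # accepts 0/1 and TRUE/FALSE (any case); anything else left for the
  # constructor to reject with cell coordinates
  x <- trimws(as.character(x))
  up <- toupper(x)
  x[up %in% c("TRUE", "T")] <- "1"
  x[up %in% c("FALSE", "F")] <- "0"
  suppressWarnings(as.numeric(x))
}

#' Read a binary event matrix from delimited text
#'
#' Expects a header row and the sample identifier in the first column:
#' `sample_id<delim>EVENT1<delim>EVENT2...`, one row per sample. Cells
#' may be coded 0/1 or TRUE/FALSE (case-insensitive); logical tokens are
#' normalised to 0/1.
#'
#' @param path path to a TSV/CSV file.
#' @param delimiter field separator, default tab.
#' @param na_policy `"reject"` (default) errors on missing cells;
#'   `"as_zero"` recodes them as event absence.
#' @return An [event_matrix()].
#' @export
read_event_matrix <- function(path, delimiter = "\t",
                              na_policy = c("reject", "as_zero")) {
  na_policy <- match.arg(na_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2) stop("expected a sample-id column plus >=1 event column")
  ids <- df[[1]]
  ev <- colnames(df)[-1]
  vals <- vapply(df[-1], normalize_cell_tokens, numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, ev))
  blank <- df[-1] == "" | toupper(as.matrix(df[-1])) %in% c("NA", "")
  vals[blank] <- NA
  if (anyNA(vals)) {
    nas <- which(is.na(vals), arr.ind = TRUE)
    if (na_policy == "reject") {
      # distinguish unparseable tokens from genuinely missing cells
      raw <- as.matrix(df[-1])[nas[1, , drop = FALSE]]
      if (!is.na(raw) && raw != "" && toupper(raw) != "NA")
        stop(sprintf("non-binary cell '%s' at sample '%s', event '%s'",
                     raw, ids[nas[1, 1]], ev[nas[1, 2]]))
      stop(sprintf("missing cell at sample '%s', event '%s' (na_policy = 'reject')",
                   ids[nas[1, 1]], ev[nas[1, 2]]))
    }
    # as_zero only fills genuinely missing cells, never bad tokens
    raw <- as.matrix(df[-1])
    missing_ok <- is.na(vals) & (raw == "" | toupper(raw) == "NA" | is.na(raw))
    bad <- is.na(vals) & !missing_ok
    if (any(bad)) {
      b <- which(bad, arr.ind = TRUE)
      stop(sprintf("non-binary cell '%s' at sample '%s', event '%s'",
                   raw[b[1, , drop = FALSE]], ids[b[1, 1]], ev[b[1, 2]]))
    }
    vals[missing_ok] <- 0
  }
  m <- event_matrix(vals, sample_ids = ids, event_names = ev)
  message(sprintf("read %d samples x %d events from %s", nrow(m), ncol(m),
                  basename(path)))
  m
}

#' Write an event matrix in the same delimited dialect
#'
#' @param m an `event_matrix`.
#' @param path output path.
#' @param delimiter field separator, default tab.
#' @param id_column name used for the first (sample id) header field.
#' @return `path`, invisibly.
#' @export
write_event_matrix <- function(m, path, delimiter = "\t",
                               id_column = "sample_id") {
  header <- paste(c(id_column, colnames(m)), collapse = delimiter)
  writeLines(header, path)
  if (nrow(m) > 0) {
    df <- data.frame(id = rownames(m), unclass(m)[, , drop = FALSE],
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = delimiter, quote = FALSE,
                       row.names = FALSE, col.names = FALSE,
                       append = TRUE)
  }
  invisible(path)
}

#' Per-event counts of samples carrying the event
#'
#' @param m an `event_matrix`.
#' @return Named integer vector, one count per event, in column order.
#' @export
event_counts <- function(m) {
  counts <- colSums(unclass(m))
  storage.mode(counts) <- "integer"
  counts
}

#' Remove events rarer than a minimum count mu
#'
#' The first of the two tuning knobs of the workflow: an event present
#' in fewer than `mu` samples is dropped before structure learning.
#' Events with count exactly `mu` are kept. Column order of retained
#' events is preserved.
#'
#' @param m an `event_matrix`.
#' @param mu non-negative integer minimum event count.
#' @return A list with `matrix` (the filtered `event_matrix`) and
#'   `report` (a `filter_report`: `mu`, `kept`, and a data frame
#'   `removed` of dropped events with their counts).
#' @export
filter_by_mu <- function(m, mu) {
  if (length(mu) != 1 || is.na(mu) || mu < 0 || mu != floor(mu))
    stop("mu must be a single non-negative integer")
  counts <- event_counts(m)
  keep <- counts >= mu
  if (!any(keep))
    stop(sprintf("empty model: mu = %d removes all %d events (max count %d)",
                 as.integer(mu), length(counts), max(counts)))
  report <- structure(list(
    mu = as.integer(mu),
    kept = event_names(m)[keep],
    removed = data.frame(event = event_names(m)[!keep],
                         count = unname(counts[!keep]),
                         stringsAsFactors = FALSE)
  ), class = "filter_report")
  filtered <- unclass(m)[, keep, drop = FALSE]
  list(matrix = event_matrix(filtered), report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("mu = %d: kept %d events, removed %d\n",
              x$mu, length(x$kept), nrow(x$removed)))
  invisible(x)
}

#' Write a filter report as a provenance table
#'
#' Two-column text table (event, count) of the removed events, headed by
#' the mu value and the kept events, so a run can be audited later.
#'
#' @param report a `filter_report` from [filter_by_mu()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mu\t%d", report$mu), con)
  writeLines(sprintf("# kept\t%s", paste(report$kept, collapse = ",")), con)
  writeLines("event\tcount", con)
  if (nrow(report$removed) > 0)
    writeLines(sprintf("%s\t%d", report$removed$event, report$removed$count),
               con)
  invisible(path)
}
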