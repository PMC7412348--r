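#' Write a gait record as delimited text
#'
#' Three tab-separated columns (time, left force, right force), full double
#' precision so that write/read round-trips are exact.
#'
#' @param record a [gait_record()].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_gait_record <- function(record, path) {
  stopifnot(inherits(record, "gait_record"))
  lines <- sprintf("%.17g\t%.17g\t%.17g",
                   record$time, record$left, record$right)
  writeLines(lines, path)
  invisible(path)
}

#' Read a vGRF record from text
#'
#' Supported dialects:
#' \describe{
#'   \item{`three-column`}{time, left force, right force.}
#'   \item{`two-column`}{left force, right force; the time grid is
#'     synthesized from `fs`, which is then required.}
#'   \item{`wfdb-like`}{a WFDB-style *text* pair: `path` is a header file
#'     whose first line is `<name> <fs> <n>`, with the two-column signal in
#'     `<name>.txt` next to it. This is a plain-text stand-in, not binary
#'     WFDB.}
#' }
#' Fields may be separated by whitespace or commas (autodetected). Ragged
#' rows and non-numeric cells raise an error naming the offending line.
#'
#' @param path input file.
#' @param dialect one of `"three-column"`, `"two-column"`, `"wfdb-like"`.
#' @param fs sampling rate in Hz; required for `two-column`, validated
#'   against the time column for `three-column` (inferred from it when
#'   `NULL`).
#' @param subject_id record id; defaults to the file stem.
#' @param label class label (default `"unknown"`).
#' @return a [gait_record()].
#' @export
read_gait_record <- function(path,
                             dialect = c("three-column", "two-column",
                                         "wfdb-like"),
                             fs = NULL, subject_id = NULL,
                             label = "unknown") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  subject_id <- subject_id %||%
    sub("\\.[^.]*$", "", basename(path))

  if (dialect == "wfdb-like") {
    hdr <- strsplit(trimws(readLines(path, n = 1)), "[[:space:]]+")[[1]]
    if (length(hdr) < 2)
      stop_invalid("wfdb-like header must read '<name> <fs> [<n>]': %s", path)
    fs <- as.numeric(hdr[2])
    if (!is.finite(fs) || fs <= 0)
      stop_invalid("wfdb-like header has invalid fs '%s'", hdr[2])
    sig <- file.path(dirname(path), paste0(hdr[1], ".txt"))
    return(read_gait_record(sig, "two-column", fs = fs,
                            subject_id = subject_id, label = label))
  }

  want <- if (dialect == "three-column") 3L else 2L
  cells <- parse_numeric_table(path, want)
  if (dialect == "two-column") {
    if (is.null(fs)) stop_invalid("two-column dialect requires fs")
    time <- (seq_len(nrow(cells)) - 1) / fs
    return(gait_record(subject_id, label, fs, time,
                       cells[, 1], cells[, 2]))
  }
  time <- cells[, 1]
  if (is.null(fs)) {
    if (nrow(cells) < 2) stop_invalid("cannot infer fs from %d row(s)",
                                      nrow(cells))
    fs <- 1 / stats::median(diff(time))
  }
  gait_record(subject_id, label, fs, time, cells[, 2], cells[, 3])
}

# Strict numeric table parser with line-level diagnostics (the base readers
# cannot report which row is ragged or non-numeric).
parse_numeric_table <- function(path, n_cols) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  rows <- which(keep)
  if (length(rows) == 0) stop_invalid("no data rows in %s", path)
  sep <- if (grepl(",", lines[rows[1]], fixed = TRUE)) "," else "[[:space:]]+"
  out <- matrix(NA_real_, length(rows), n_cols)
  for (k in seq_along(rows)) {
    ln <- rows[k]
    fields <- strsplit(trimws(lines[ln]), sep)[[1]]
    fields <- fields[nzchar(fields)]
    if (length(fields) != n_cols)
      stop_invalid("format error in %s: line %d has %d field(s), expected %d",
                   path, ln, length(fields), n_cols)
    vals <- suppressWarnings(as.numeric(fields))
    bad <- which(is.na(vals) & fields != "NA")
    if (length(bad) > 0)
      stop_invalid("format error in %s: non-numeric value '%s' at line %d, column %d",
                   path, fields[bad[1]], ln, bad[1])
    out[k, ] <- vals
  }
  out
}

#' Write a gray-level image as plain-text PGM
#'
#' 8-bit export (`value = round(255 * pixel)`) in the portable graymap P2
#' format, which keeps the whole deliverable plain text. The lossless array
#' path used by the classifier never passes through this quantization.
#'
#' @param image numeric matrix with values in `[0, 1]`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_pgm <- function(image, path) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (min(image) < 0 || max(image) > 1)
    stop_invalid("image values must lie in [0, 1]")
  q <- round(255 * image)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(q), nrow(q)), "255"), con)
  writeLines(apply(q, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read a plain-text PGM image back to a `[0, 1]` matrix
#'
#' @param path a P2 PGM file written by [write_pgm()].
#' @return numeric matrix in `[0, 1]`.
#' @export
read_pgm <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  if (lines[1] != "P2") stop_invalid("%s is not a plain (P2) PGM file", path)
  dims <- as.integer(strsplit(trimws(lines[2]), "[[:space:]]+")[[1]])
  maxval <- as.numeric(lines[3])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-(1:3)]), "[[:space:]]+")))
  matrix(vals, nrow = dims[2], ncol = dims[1], byrow = TRUE) / maxval
}
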