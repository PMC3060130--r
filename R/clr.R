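# Classification Results (CLR) tables: per-event fuzzy class memberships.
#
# Dialect: plain CSV (RFC 4180 quoting).  An optional leading comment line
# "#source=<file>" names the FCS file whose event order the rows follow;
# the first non-comment row holds the class labels; each following row is
# one event's membership probabilities.  Values are serialized with 17
# significant digits so every finite probability round-trips exactly, and
# any generic CSV reader (or spreadsheet) can open the file.

#' Construct a CLR table
#'
#' @param memberships numeric matrix, `n_events x n_classes`, values in
#'   `[0, 1]`.
#' @param class_labels character vector of unique non-empty class labels;
#'   defaults to `colnames(memberships)`.
#' @param source_ref optional identifier of the FCS file the rows index.
#' @param strict when `TRUE`, additionally require each row to sum to at
#'   most 1 (classes then form a fuzzy partition).  Default `FALSE`
#'   because classes may legitimately overlap.
#' @return object of class `clr_table`.
#' @export
clr_table <- function(memberships, class_labels = colnames(memberships),
                      source_ref = NULL, strict = FALSE) {
  memberships <- as.matrix(memberships)
  storage.mode(memberships) <- "double"
  m <- ncol(memberships)
  if (is.null(class_labels)) class_labels <- paste0("class", seq_len(m))
  class_labels <- as.character(class_labels)
  if (length(class_labels) != m) {
    cyto_error("clr_validation_error", sprintf(
      "%d labels for %d membership columns", length(class_labels), m
    ))
  }
  if (anyDuplicated(class_labels) || any(!nzchar(class_labels))) {
    cyto_error("clr_validation_error", "class labels must be unique and non-empty")
  }
  bad <- which(!is.finite(memberships) | memberships < 0 | memberships > 1)
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(memberships))
    cyto_error("clr_validation_error", sprintf(
      "(%d, %d): %s ∉ [0,1]", i[1], i[2],
      format(memberships[bad[1]])
    ))
  }
  if (strict) .check_row_sums(memberships)
  colnames(memberships) <- class_labels
  structure(
    list(
      class_labels = class_labels,
      memberships = memberships,
      source_ref = source_ref
    ),
    class = "clr_table"
  )
}

.check_row_sums <- function(memberships) {
  rs <- rowSums(memberships)
  bad <- which(rs > 1 + 1e-9)
  if (length(bad)) {
    cyto_error("clr_validation_error", sprintf(
      "strict mode: row %d sums to %.12g > 1", bad[1], rs[bad[1]]
    ))
  }
  invisible(TRUE)
}

#' @export
print.clr_table <- function(x, ...) {
  cat(sprintf(
    "<clr_table> %d events x %d classes%s\n",
    nrow(x$memberships), length(x$class_labels),
    if (is.null(x$source_ref)) "" else paste0(" (source ", x$source_ref, ")")
  ))
  cat("  classes:", paste(x$class_labels, collapse = ", "), "\n")
  invisible(x)
}

.csv_escape <- function(x) {
  # quote on the RFC 4180 specials plus edge whitespace, which bare CSV
  # parsers would otherwise strip from header fields
  needs <- grepl('[",\n\r]|^[ \t]|[ \t]$', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Write a CLR table as CSV
#'
#' @param table a [clr_table()].
#' @param path optional output path; when `NULL` the CSV text is returned.
#' @return CSV text (invisibly when `path` is given).
#' @export
write_clr <- function(table, path = NULL) {
  stopifnot(inherits(table, "clr_table"))
  lines <- character(0)
  if (!is.null(table$source_ref)) {
    lines <- paste0("#source=", table$source_ref)
  }
  lines <- c(lines, paste(.csv_escape(table$class_labels), collapse = ","))
  if (nrow(table$memberships) > 0) {
    vals <- matrix(sprintf("%.17g", table$memberships), nrow = nrow(table$memberships))
    lines <- c(lines, apply(vals, 1, paste, collapse = ","))
  }
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' Read a CLR CSV file
#'
#' @param text_or_path CSV text (anything containing a newline or comma) or
#'   a file path.
#' @param strict enforce row sums `<= 1` (see [clr_table()]).
#' @return a [clr_table()].
#' @export
read_clr <- function(text_or_path, strict = FALSE) {
  txt <- if (grepl("[\n,]", text_or_path)) text_or_path else {
    paste(readLines(text_or_path, warn = FALSE), collapse = "\n")
  }
  lines <- strsplit(txt, "\r?\n")[[1]]
  source_ref <- NULL
  if (length(lines) && startsWith(lines[1], "#")) {
    if (startsWith(lines[1], "#source=")) {
      source_ref <- sub("^#source=", "", lines[1])
    }
    lines <- lines[-1]
  }
  if (!length(lines)) cyto_error("clr_format_error", "CLR file has no header row")
  df <- utils::read.csv(
    text = paste(lines, collapse = "\n"),
    header = TRUE, check.names = FALSE, colClasses = "character"
  )
  labels <- colnames(df)
  if (nrow(df) > 0) {
    vals <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
    if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L)
    if (anyNA(vals)) {
      i <- which(is.na(vals), arr.ind = TRUE)[1, ]
      cyto_error("clr_format_error", sprintf(
        "non-numeric value at row %d, column %d", i[1], i[2]
      ))
    }
  } else {
    vals <- matrix(numeric(0), nrow = 0, ncol = length(labels))
  }
  clr_table(vals, labels, source_ref = source_ref, strict = strict)
}

#' Derive hard assignments from a CLR table
#'
#' Each event is assigned the class with the largest membership when that
#' membership reaches the threshold, and `"unclassified"` otherwise.
#'
#' @param table a [clr_table()].
#' @param threshold minimum membership in `[0, 1]` (default 0.5).
#' @param tie_rule `"first"` (default: first label in column order wins) or
#'   `"unclassified"` (ties are not assigned).
#' @return character vector of length `n_events`.
#' @export
hard_assignment <- function(table, threshold = 0.5,
                            tie_rule = c("first", "unclassified")) {
  stopifnot(inherits(table, "clr_table"), threshold >= 0, threshold <= 1)
  tie_rule <- match.arg(tie_rule)
  p <- table$memberships
  if (nrow(p) == 0) {
    return(character(0))
  }
  best <- max.col(p, ties.method = "first")
  bestval <- p[cbind(seq_len(nrow(p)), best)]
  out <- table$class_labels[best]
  out[bestval < threshold] <- "unclassified"
  if (tie_rule == "unclassified") {
    nties <- rowSums(p == bestval)
    out[nties > 1] <- "unclassified"
  }
  out
}

#' Build a CLR table from Boolean gate memberships
#'
#' Represents (manual) gating results in the CLR format as 0/1
#' probabilities.
#'
#' @param memberships list of logical vectors of equal length (one per
#'   class), e.g. the `membership` element of [evaluate_all()].
#' @param labels character vector of class labels, one per vector.
#' @param source_ref,strict passed to [clr_table()]; `strict = TRUE`
#'   rejects overlapping gates.
#' @return a [clr_table()].
#' @export
clr_from_memberships <- function(memberships, labels = names(memberships),
                                 source_ref = NULL, strict = FALSE) {
  if (length(labels) != length(memberships)) {
    cyto_error("clr_validation_error", sprintf(
      "%d labels for %d membership vectors", length(labels), length(memberships)
    ))
  }
  n <- unique(lengths(memberships))
  if (length(n) > 1) {
    cyto_error("clr_validation_error", "membership vectors must have equal length")
  }
  mat <- vapply(memberships, as.numeric, numeric(if (length(n)) n else 0))
  if (length(memberships) == 1L) mat <- matrix(mat, ncol = 1L)
  if (!is.matrix(mat)) mat <- matrix(mat, ncol = length(memberships))
  clr_table(mat, labels, source_ref = source_ref, strict = strict)
}
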