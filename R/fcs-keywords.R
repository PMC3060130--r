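# FCS TEXT-segment keyword handling.
#
# A keyword map is an ordered named character vector.  Standard keywords
# (names starting with "$") are case-insensitive and normalized to upper
# case; user keywords keep their case.  FCS forbids empty values, and the
# delimiter byte is escaped inside values by doubling it.

REQUIRED_KEYWORDS <- c("$MODE", "$DATATYPE", "$BYTEORD", "$PAR", "$TOT")

normalize_keyword_names <- function(nms) {
  std <- startsWith(nms, "$")
  nms[std] <- toupper(nms[std])
  nms
}

#' Parse an FCS TEXT segment into a keyword map
#'
#' The first byte of the segment is the delimiter; the rest alternates
#' keyword and value, each terminated by the delimiter.  A doubled delimiter
#' inside a token is unescaped to one literal delimiter.
#'
#' @param segment raw vector or character scalar holding the full TEXT
#'   segment, including the leading delimiter.
#' @return named character vector (ordered keyword map) with attribute
#'   `delimiter`.
#' @export
parse_text_segment <- function(segment) {
  if (is.raw(segment)) {
    s <- rawToChar(segment)
    s2 <- iconv(s, from = "UTF-8", to = "UTF-8")
    if (is.na(s2)) {
      cyto_warn("TEXT segment is not valid UTF-8; falling back to Latin-1")
      s <- iconv(s, from = "latin1", to = "UTF-8")
    } else {
      s <- s2
    }
  } else {
    s <- segment
  }
  if (nchar(s) < 2L) cyto_error("fcs_format_error", "TEXT segment too short")
  delim <- substr(s, 1L, 1L)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  p <- which(chars == delim)
  if (length(p) < 2L) {
    cyto_error("fcs_format_error", "TEXT segment has no terminated tokens")
  }
  tokens <- character(0)
  cur <- ""
  piece_start <- p[1L] + 1L
  j <- 2L
  np <- length(p)
  while (j <= np) {
    if (j < np && p[j + 1L] == p[j] + 1L) {
      # doubled delimiter: literal delimiter inside the token
      cur <- paste0(cur, substr(s, piece_start, p[j] - 1L), delim)
      piece_start <- p[j + 1L] + 1L
      j <- j + 2L
    } else {
      tokens <- c(tokens, paste0(cur, substr(s, piece_start, p[j] - 1L)))
      cur <- ""
      piece_start <- p[j] + 1L
      j <- j + 1L
    }
  }
  trailing <- substr(s, p[np] + 1L, nchar(s))
  if (nzchar(gsub("[[:space:]\\0]", "", trailing))) {
    cyto_error("fcs_format_error", "TEXT segment has content after the final delimiter")
  }
  if (length(tokens) %% 2L != 0L) {
    cyto_error(
      "fcs_format_error",
      sprintf("TEXT segment has an odd number of tokens (%d)", length(tokens))
    )
  }
  idx <- seq_len(length(tokens) / 2L)
  nms <- normalize_keyword_names(tokens[2L * idx - 1L])
  vals <- tokens[2L * idx]
  dup <- nms[startsWith(nms, "$") & duplicated(nms)]
  if (length(dup)) {
    cyto_error(
      "fcs_format_error",
      paste0("duplicate standard keyword(s): ", paste(unique(dup), collapse = ", "))
    )
  }
  kw <- stats::setNames(vals, nms)
  attr(kw, "delimiter") <- delim
  kw
}

#' Serialize a keyword map to an FCS TEXT segment
#'
#' Delimiters inside tokens are escaped by doubling.  Because a doubled
#' delimiter at a token boundary is ambiguous (a well-known limitation of
#' the delimited TEXT layout), keyword names and values must not *begin*
#' with the delimiter; trailing delimiters are unambiguous under the
#' reader's greedy left-to-right pairing and are allowed.
#'
#' @param keywords named character vector.
#' @param delimiter single character, default `/`.
#' @return character scalar starting and ending with the delimiter.
#' @export
serialize_text_segment <- function(keywords, delimiter = "/") {
  stopifnot(nchar(delimiter) == 1L)
  nms <- names(keywords)
  vals <- as.character(keywords)
  if (is.null(nms) || any(!nzchar(nms))) {
    cyto_error("fcs_validation_error", "keyword names must be non-empty")
  }
  if (any(!nzchar(vals))) {
    cyto_error(
      "fcs_validation_error",
      paste0(
        "FCS forbids empty keyword values; offending keyword(s): ",
        paste(nms[!nzchar(vals)], collapse = ", ")
      )
    )
  }
  leading <- startsWith(nms, delimiter) | startsWith(vals, delimiter)
  if (any(leading)) {
    cyto_error(
      "fcs_validation_error",
      paste0(
        "keyword names and values must not begin with the delimiter; offending keyword(s): ",
        paste(nms[leading], collapse = ", ")
      )
    )
  }
  esc <- function(x) gsub(delimiter, paste0(delimiter, delimiter), x, fixed = TRUE)
  paste0(delimiter, paste0(esc(nms), delimiter, esc(vals), delimiter, collapse = ""))
}

# Case-insensitive lookup for "$" keywords; exact for user keywords.
kw_get <- function(keywords, name, default = NULL) {
  name <- normalize_keyword_names(name)
  if (name %in% names(keywords)) unname(keywords[[name]]) else default
}

kw_num <- function(keywords, name, default = NULL) {
  v <- kw_get(keywords, name)
  if (is.null(v)) {
    return(default)
  }
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) {
    cyto_error("fcs_format_error", sprintf("keyword %s has non-numeric value '%s'", name, v))
  }
  out
}
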