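# Binary reading and writing of FCS files.
#
# Layout: a 58-byte ASCII HEADER (version tag + six 8-character offset
# fields), a delimited TEXT segment of keyword/value pairs, a binary DATA
# segment, and an optional ANALYSIS segment.  Offsets in the header are
# byte positions from the start of the file, inclusive on both ends; a 0
# means "absent" (or, for DATA in large files, "see $BEGINDATA/$ENDDATA
# in TEXT").  The written dialect is FCS 3.1, single dataset per file;
# reading accepts FCS 2.0/3.0/3.1 and follows $NEXTDATA chains on request.

FCS_HEADER_LEN <- 58L

#' Parse the 58-byte FCS header
#'
#' @param raw_bytes raw vector, at least 58 bytes.
#' @return list of class `fcs_segment_offsets` with `version_string` and the
#'   six segment offsets (`text_begin`, `text_end`, `data_begin`,
#'   `data_end`, `analysis_begin`, `analysis_end`).
#' @export
parse_fcs_header <- function(raw_bytes) {
  if (length(raw_bytes) < FCS_HEADER_LEN) {
    cyto_error("fcs_format_error", sprintf(
      "file too short for an FCS header: %d bytes (need >= %d)",
      length(raw_bytes), FCS_HEADER_LEN
    ))
  }
  version <- rawToChar(raw_bytes[1:6])
  if (!startsWith(version, "FCS")) {
    cyto_error("fcs_format_error", sprintf(
      "not an FCS file: first 6 bytes are '%s'", version
    ))
  }
  fields <- vapply(0:5, function(i) {
    rawToChar(raw_bytes[(11L + 8L * i):(18L + 8L * i)])
  }, character(1))
  vals <- vapply(seq_along(fields), function(i) {
    f <- gsub("[[:space:]]", "", fields[i])
    if (!nzchar(f)) {
      return(0)
    }
    v <- suppressWarnings(as.numeric(f))
    if (is.na(v)) {
      cyto_error("fcs_format_error", sprintf(
        "non-numeric header offset field '%s' at bytes %d-%d",
        fields[i], 10L + 8L * (i - 1L), 17L + 8L * (i - 1L)
      ))
    }
    v
  }, numeric(1))
  structure(
    list(
      version_string = version,
      text_begin = vals[1], text_end = vals[2],
      data_begin = vals[3], data_end = vals[4],
      analysis_begin = vals[5], analysis_end = vals[6]
    ),
    class = "fcs_segment_offsets"
  )
}

.byte_order <- function(byteord) {
  b <- gsub("[[:space:]]", "", byteord)
  if (b %in% c("1,2,3,4", "1,2", "1,2,3,4,5,6,7,8")) {
    return("little")
  }
  if (b %in% c("4,3,2,1", "2,1", "8,7,6,5,4,3,2,1")) {
    return("big")
  }
  cyto_error("fcs_format_error", sprintf(
    "unsupported $BYTEORD '%s' (need little- or big-endian order)", byteord
  ))
}

# Unsigned integer columns of possibly mixed byte widths, decoded from the
# raw DATA segment without assuming a uniform record layout.
.decode_uint_columns <- function(data_raw, tot, nbytes_per_param, endian) {
  rec_len <- sum(nbytes_per_param)
  offs <- c(0L, cumsum(nbytes_per_param))
  out <- matrix(0, nrow = tot, ncol = length(nbytes_per_param))
  base <- (seq_len(tot) - 1L) * rec_len
  for (j in seq_along(nbytes_per_param)) {
    nb <- nbytes_per_param[j]
    weights <- if (endian == "little") 256^(seq_len(nb) - 1L) else 256^(rev(seq_len(nb)) - 1L)
    acc <- numeric(tot)
    for (t in seq_len(nb)) {
      acc <- acc + as.double(data_raw[base + offs[j] + t]) * weights[t]
    }
    out[, j] <- acc
  }
  out
}

.encode_uint_columns <- function(events, nbytes_per_param) {
  tot <- nrow(events)
  rec_len <- sum(nbytes_per_param)
  out <- raw(tot * rec_len)
  offs <- c(0L, cumsum(nbytes_per_param))
  base <- (seq_len(tot) - 1L) * rec_len
  for (j in seq_along(nbytes_per_param)) {
    nb <- nbytes_per_param[j]
    v <- events[, j]
    for (t in seq_len(nb)) { # little-endian
      out[base + offs[j] + t] <- as.raw(v %% 256)
      v <- v %/% 256
    }
  }
  out
}

.mask_integer_columns <- function(mat, ranges) {
  for (j in seq_along(ranges)) {
    bits <- max(1, ceiling(log2(ranges[j])))
    mat[, j] <- mat[, j] %% 2^bits
  }
  mat
}

.read_parameters <- function(kw, par) {
  getp <- function(n, suffix, default = NULL) {
    kw_get(kw, sprintf("$P%d%s", n, suffix), default)
  }
  rows <- lapply(seq_len(par), function(n) {
    bits <- getp(n, "B")
    rng <- getp(n, "R")
    nm <- getp(n, "N")
    amp <- getp(n, "E", "0,0")
    for (req in list(c("B", bits), c("R", rng), c("N", nm))) {
      if (is.null(req[[2]])) {
        cyto_error("fcs_format_error", sprintf(
          "required keyword $P%d%s is missing", n, req[[1]]
        ))
      }
    }
    ev <- suppressWarnings(as.numeric(strsplit(amp, ",")[[1]]))
    if (length(ev) != 2L || anyNA(ev)) {
      cyto_error("fcs_format_error", sprintf("malformed $P%dE value '%s'", n, amp))
    }
    data.frame(
      index = n, name = nm, stain = getp(n, "S", NA_character_),
      bits = as.integer(bits), e_decades = ev[1], e_offset = ev[2],
      range = as.numeric(rng), display = getp(n, "D", NA_character_),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Read an FCS file
#'
#' Decodes the HEADER, TEXT and DATA segments of an FCS 2.0/3.0/3.1 file
#' into an [fcs_dataset()].  Only list-mode (`$MODE L`) files with
#' `$DATATYPE` `F` (32-bit float), `D` (64-bit float) or `I` (unsigned
#' integer) are supported; integer values are masked to the significant
#' bits implied by `$PnR`, as the standard requires.
#'
#' @param path_or_bytes file path or raw vector.
#' @param dataset 1-based index into the `$NEXTDATA` chain for files
#'   holding several datasets; the default reads the first.
#' @return an `fcs_dataset`.
#' @export
read_fcs <- function(path_or_bytes, dataset = 1L) {
  raw_bytes <- if (is.raw(path_or_bytes)) {
    path_or_bytes
  } else {
    readBin(path_or_bytes, "raw", n = file.info(path_or_bytes)$size)
  }
  base <- 0
  hdr <- parse_fcs_header(raw_bytes)
  if (dataset > 1L) {
    for (i in seq_len(dataset - 1L)) {
      kw <- parse_text_segment(raw_bytes[(base + hdr$text_begin + 1):(base + hdr$text_end + 1)])
      nxt <- kw_num(kw, "$NEXTDATA", 0)
      if (nxt == 0) {
        cyto_error("fcs_format_error", sprintf(
          "dataset %d requested but the $NEXTDATA chain ends at dataset %d",
          dataset, i
        ))
      }
      base <- base + nxt
      hdr <- parse_fcs_header(raw_bytes[(base + 1):length(raw_bytes)])
    }
  }
  kw <- parse_text_segment(raw_bytes[(base + hdr$text_begin + 1):(base + hdr$text_end + 1)])

  missing <- setdiff(REQUIRED_KEYWORDS, names(kw))
  if (length(missing)) {
    cyto_error("fcs_format_error", paste0(
      "required keyword(s) missing from TEXT: ", paste(missing, collapse = ", ")
    ))
  }
  mode <- kw_get(kw, "$MODE")
  if (!identical(mode, "L")) {
    cyto_error("fcs_unsupported_mode", sprintf(
      "only list mode ($MODE L) is supported; file declares $MODE %s", mode
    ))
  }
  datatype <- kw_get(kw, "$DATATYPE")
  if (identical(datatype, "A")) {
    cyto_error("fcs_unsupported_datatype", "$DATATYPE A (ASCII) is deprecated in FCS 3.1 and not supported")
  }
  if (!datatype %in% c("F", "D", "I")) {
    cyto_error("fcs_unsupported_datatype", sprintf("unsupported $DATATYPE '%s'", datatype))
  }
  endian <- .byte_order(kw_get(kw, "$BYTEORD"))
  par <- as.integer(kw_num(kw, "$PAR"))
  tot <- as.integer(kw_num(kw, "$TOT"))
  params <- .read_parameters(kw, par)

  data_begin <- hdr$data_begin
  data_end <- hdr$data_end
  if (data_begin == 0 || data_end == 0) {
    data_begin <- kw_num(kw, "$BEGINDATA", 0)
    data_end <- kw_num(kw, "$ENDDATA", 0)
  }
  expected <- tot * sum(params$bits) / 8
  if (tot > 0) {
    avail <- min(data_end - data_begin + 1, length(raw_bytes) - base - data_begin)
    if (data_begin == 0 || avail < expected) {
      cyto_error("fcs_truncation_error", sprintf(
        "DATA segment holds %s bytes but $TOT x Sum($PnB)/8 = %s bytes are required",
        format(max(avail, 0), scientific = FALSE), format(expected, scientific = FALSE)
      ))
    }
    data_raw <- raw_bytes[(base + data_begin + 1):(base + data_begin + expected)]
  } else {
    data_raw <- raw(0)
  }

  events <- if (tot == 0) {
    matrix(numeric(0), nrow = 0, ncol = par)
  } else if (datatype == "F") {
    if (any(params$bits != 32L)) {
      cyto_error("fcs_format_error", "$DATATYPE F requires $PnB 32 for every parameter")
    }
    matrix(readBin(data_raw, "double", n = tot * par, size = 4L, endian = endian),
      ncol = par, byrow = TRUE
    )
  } else if (datatype == "D") {
    if (any(params$bits != 64L)) {
      cyto_error("fcs_format_error", "$DATATYPE D requires $PnB 64 for every parameter")
    }
    matrix(readBin(data_raw, "double", n = tot * par, size = 8L, endian = endian),
      ncol = par, byrow = TRUE
    )
  } else { # I
    if (any(params$bits %% 8L != 0L | params$bits > 64L)) {
      cyto_error("fcs_format_error", "$DATATYPE I requires byte-aligned $PnB <= 64")
    }
    m <- .decode_uint_columns(data_raw, tot, params$bits %/% 8L, endian)
    .mask_integer_columns(m, params$range)
  }
  colnames(events) <- params$name

  structure(
    list(
      version = hdr$version_string,
      keywords = kw,
      parameters = params,
      events = events
    ),
    class = "fcs_dataset"
  )
}

.fmt_num <- function(x) {
  # shortest decimal that survives a double round-trip
  vapply(x, function(v) {
    if (is.finite(v) && v == round(v) && abs(v) < 1e15) {
      format(v, scientific = FALSE)
    } else {
      sprintf("%.17g", v)
    }
  }, character(1))
}

#' Write an FCS 3.1 file
#'
#' Serializes a dataset as a single-dataset FCS 3.1 file.  `$BEGINDATA` /
#' `$ENDDATA` are always present in TEXT; the corresponding header fields
#' carry the same offsets when they fit in the 8-digit header fields and 0
#' otherwise, as the standard prescribes for large files.
#'
#' @param dataset an [fcs_dataset()].
#' @param path optional output file path; when `NULL` the bytes are
#'   returned only.
#' @param datatype `"F"` (32-bit float, default), `"D"` (double) or `"I"`
#'   (unsigned integer; event values are rounded and clipped to
#'   `[0, 2^$PnB - 1]`).
#' @param nextdata byte offset written to `$NEXTDATA` (0 = no further
#'   dataset).  Only needed when concatenating several datasets into one
#'   file; the written value is fixed-width, so the file length does not
#'   depend on it.
#' @return raw vector of file bytes, invisibly when `path` is given.
#' @export
write_fcs <- function(dataset, path = NULL, datatype = c("F", "D", "I"),
                      nextdata = 0) {
  datatype <- match.arg(datatype)
  stopifnot(inherits(dataset, "fcs_dataset"))
  params <- dataset$parameters
  events <- dataset$events
  par <- ncol(events)
  tot <- nrow(events)
  if (nrow(params) != par) {
    cyto_error("fcs_validation_error", sprintf(
      "parameter count mismatch: %d descriptors for %d event columns", nrow(params), par
    ))
  }

  bits <- switch(datatype,
    F = rep(32L, par),
    D = rep(64L, par),
    I = ifelse(params$bits %in% c(8L, 16L, 32L), params$bits, 32L)
  )

  # DATA payload (little-endian)
  data_raw <- if (tot == 0) {
    raw(0)
  } else if (datatype == "F") {
    writeBin(as.vector(t(events)), raw(), size = 4L, endian = "little")
  } else if (datatype == "D") {
    writeBin(as.vector(t(events)), raw(), size = 8L, endian = "little")
  } else {
    ev <- round(events)
    ev <- pmax(ev, 0)
    ev <- pmin(ev, matrix(2^bits - 1, tot, par, byrow = TRUE))
    .encode_uint_columns(ev, bits %/% 8L)
  }

  kw <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BEGINDATA" = sprintf("%010d", 0L), "$ENDDATA" = sprintf("%010d", 0L),
    "$NEXTDATA" = sprintf("%010d", as.integer(nextdata)),
    "$MODE" = "L", "$DATATYPE" = datatype,
    "$BYTEORD" = "1,2,3,4",
    "$PAR" = as.character(par), "$TOT" = as.character(tot)
  )
  for (n in seq_len(par)) {
    kw[sprintf("$P%dB", n)] <- as.character(bits[n])
    kw[sprintf("$P%dE", n)] <- paste0(.fmt_num(params$e_decades[n]), ",", .fmt_num(params$e_offset[n]))
    kw[sprintf("$P%dR", n)] <- .fmt_num(params$range[n])
    kw[sprintf("$P%dN", n)] <- params$name[n]
    if (!is.na(params$stain[n])) kw[sprintf("$P%dS", n)] <- params$stain[n]
    if (!is.na(params$display[n])) kw[sprintf("$P%dD", n)] <- params$display[n]
  }
  extra <- dataset$keywords
  extra <- extra[setdiff(names(extra), names(kw))]
  kw <- c(kw, extra)

  # TEXT length is invariant to the actual offsets (fixed-width fields)
  text_template <- serialize_text_segment(kw)
  text_begin <- FCS_HEADER_LEN
  text_end <- text_begin + nchar(text_template, type = "bytes") - 1L
  if (tot > 0) {
    data_begin <- text_end + 1
    data_end <- data_begin + length(data_raw) - 1
  } else {
    data_begin <- 0
    data_end <- 0
  }
  kw["$BEGINDATA"] <- sprintf("%010d", data_begin)
  kw["$ENDDATA"] <- sprintf("%010d", data_end)
  text <- serialize_text_segment(kw)
  stopifnot(nchar(text, type = "bytes") == nchar(text_template, type = "bytes"))

  hdr_field <- function(v) {
    if (v <= 99999999) sprintf("%8d", as.integer(v)) else sprintf("%8d", 0L)
  }
  header <- paste0(
    "FCS3.1", "    ",
    hdr_field(text_begin), hdr_field(text_end),
    hdr_field(data_begin), hdr_field(data_end),
    hdr_field(0), hdr_field(0)
  )
  out <- c(charToRaw(header), charToRaw(enc2utf8(text)), data_raw)
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(out))
  }
  out
}
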