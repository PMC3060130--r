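# In-memory model of an FCS list-mode dataset.

#' Construct an FCS dataset
#'
#' Bundles an event matrix (rows = events, columns = parameters) with
#' parameter descriptors and a keyword map into an object that [write_fcs()]
#' can serialize as FCS 3.1 and [read_fcs()] returns.
#'
#' @param events numeric matrix, `n_events x n_parameters`.
#' @param channels character vector of short parameter names (`$PnN`);
#'   defaults to `colnames(events)`.
#' @param stains optional character vector of stain names (`$PnS`); `NA`
#'   entries are omitted.
#' @param ranges numeric vector of parameter ranges (`$PnR`); recycled.
#'   Defaults to 262144 (a typical 18-bit digitizer top of scale).
#' @param bits integer vector of `$PnB` bit widths used when writing integer
#'   data; recycled.  Must be 8, 16, 32 or 64.
#' @param displays optional character vector of `$PnD` preferred-display
#'   strings (e.g. `"Logarithmic,4,0.1"`); `NA` entries are omitted.
#' @param keywords named character vector of additional keywords (e.g.
#'   `$SPILLOVER`, `$VOL`, `$ORIGINALITY`, `$PLATEID`, `$WELLID` or user
#'   keywords).  Structural keywords (`$PAR`, `$TOT`, offsets, per-parameter
#'   descriptors) are derived from the data and may not be supplied here.
#' @return object of class `fcs_dataset` with fields `version`, `keywords`,
#'   `parameters` (a data frame) and `events`.
#' @export
#' @examples
#' d <- fcs_dataset(matrix(rnorm(20, 100, 5), 10, 2,
#'   dimnames = list(NULL, c("FSC-A", "SSC-A"))
#' ))
#' d$parameters$name
fcs_dataset <- function(events, channels = colnames(events), stains = NULL,
                        ranges = 262144, bits = 32L, displays = NULL,
                        keywords = character()) {
  events <- as.matrix(events)
  storage.mode(events) <- "double"
  p <- ncol(events)
  if (p < 1L) cyto_error("fcs_validation_error", "dataset needs at least one parameter")
  if (is.null(channels)) channels <- paste0("P", seq_len(p))
  if (length(channels) != p) {
    cyto_error("fcs_validation_error", sprintf(
      "got %d channel names for %d parameters", length(channels), p
    ))
  }
  ranges <- rep_len(as.numeric(ranges), p)
  bits <- rep_len(as.integer(bits), p)
  if (any(!bits %in% c(8L, 16L, 32L, 64L))) {
    cyto_error("fcs_validation_error", "$PnB must be 8, 16, 32 or 64 for written files")
  }
  if (any(ranges <= 0)) cyto_error("fcs_validation_error", "$PnR must be > 0")
  params <- data.frame(
    index = seq_len(p),
    name = as.character(channels),
    stain = if (is.null(stains)) NA_character_ else rep_len(as.character(stains), p),
    bits = bits,
    e_decades = 0,
    e_offset = 0,
    range = ranges,
    display = if (is.null(displays)) NA_character_ else rep_len(as.character(displays), p),
    stringsAsFactors = FALSE
  )
  if (length(keywords)) {
    names(keywords) <- normalize_keyword_names(names(keywords))
    derived <- c(
      "$MODE", "$DATATYPE", "$BYTEORD", "$PAR", "$TOT", "$NEXTDATA",
      "$BEGINDATA", "$ENDDATA", "$BEGINANALYSIS", "$ENDANALYSIS",
      "$BEGINSTEXT", "$ENDSTEXT"
    )
    bad <- intersect(names(keywords), derived)
    bad <- c(bad, grep("^\\$P[0-9]+[BENRSD]$", names(keywords), value = TRUE))
    if (length(bad)) {
      cyto_error("fcs_validation_error", paste0(
        "derived keyword(s) may not be supplied directly: ",
        paste(bad, collapse = ", ")
      ))
    }
  }
  colnames(events) <- params$name
  structure(
    list(
      version = "FCS3.1",
      keywords = keywords,
      parameters = params,
      events = events
    ),
    class = "fcs_dataset"
  )
}

#' @export
print.fcs_dataset <- function(x, ...) {
  cat(sprintf(
    "<fcs_dataset> %s: %d events x %d parameters\n",
    x$version, nrow(x$events), ncol(x$events)
  ))
  cat("  channels:", paste(x$parameters$name, collapse = ", "), "\n")
  extra <- setdiff(names(x$keywords), character(0))
  if (length(extra)) cat("  keywords:", length(extra), "additional\n")
  invisible(x)
}

#' @export
dim.fcs_dataset <- function(x) dim(x$events)

n_events <- function(dataset) nrow(dataset$events)

channel_index <- function(dataset, channels) {
  idx <- match(channels, dataset$parameters$name)
  if (anyNA(idx)) {
    cyto_error("channel_error", sprintf(
      "channel(s) not present: %s; available $PnN values: %s",
      paste(channels[is.na(idx)], collapse = ", "),
      paste(dataset$parameters$name, collapse = ", ")
    ))
  }
  idx
}

# Keep only the given event rows, rederiving $TOT at write time.
subset_events <- function(dataset, rows = NULL, channels = NULL) {
  ev <- dataset$events
  if (!is.null(rows)) ev <- ev[rows, , drop = FALSE]
  params <- dataset$parameters
  if (!is.null(channels)) {
    idx <- channel_index(dataset, channels)
    ev <- ev[, idx, drop = FALSE]
    params <- params[idx, , drop = FALSE]
    params$index <- seq_len(nrow(params))
    rownames(params) <- NULL
  }
  out <- dataset
  out$events <- ev
  out$parameters <- params
  out
}
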