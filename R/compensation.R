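# Spillover matrices and fluorescence compensation.
#
# Convention (matching the FCS 3.1 $SPILLOVER definition): rows of S are
# fluorochromes and columns are detectors, so with events as row vectors
# observed = true %*% S, and compensation multiplies by solve(S) on the
# right.  Vendor tools disagree on this orientation; it is pinned here.

#' Construct a spillover matrix
#'
#' @param S numeric k x k matrix; `S[i, j]` is the fraction of fluorochrome
#'   i's signal detected in detector j.  A non-unit diagonal is normalized
#'   away (each row divided by its diagonal entry) with a warning.
#' @param detectors character vector of k detector names (matching `$PnN`).
#' @param id optional identifier (used by gate files).
#' @return object of class `spillover_matrix`.
#' @export
spillover_matrix <- function(S, detectors = colnames(S), id = NULL) {
  S <- as.matrix(S)
  k <- nrow(S)
  if (k < 1L || ncol(S) != k) {
    cyto_error("spillover_error", "spillover matrix must be square with k >= 1")
  }
  if (is.null(detectors) || length(detectors) != k) {
    cyto_error("spillover_error", "need one detector name per matrix row")
  }
  dg <- diag(S)
  if (any(dg == 0)) cyto_error("spillover_error", "zero diagonal entry in spillover matrix")
  if (any(abs(dg - 1) > 1e-12)) {
    cyto_warn("spillover matrix diagonal is not 1; normalizing each row by its diagonal")
    S <- S / dg
  }
  dimnames(S) <- list(detectors, detectors)
  structure(
    list(detectors = as.character(detectors), S = S, id = id),
    class = "spillover_matrix"
  )
}

#' @export
print.spillover_matrix <- function(x, ...) {
  cat(sprintf(
    "<spillover_matrix> %d detectors (condition number %.3g)\n",
    length(x$detectors), kappa(x$S, exact = TRUE)
  ))
  print(round(x$S, 4))
  invisible(x)
}

#' Parse an FCS 3.1 `$SPILLOVER` keyword value
#'
#' Layout: `k,name1,...,namek,v11,v12,...,vkk` (matrix entries row-major).
#'
#' @param value keyword string.
#' @return a [spillover_matrix()].
#' @export
#' @examples
#' parse_spillover_keyword("2,FL1,FL2,1,0.1,0.05,1")
parse_spillover_keyword <- function(value) {
  toks <- strsplit(value, ",", fixed = TRUE)[[1]]
  k <- suppressWarnings(as.integer(toks[1]))
  if (is.na(k) || k < 1L) {
    cyto_error("spillover_format_error", sprintf(
      "first $SPILLOVER token must be a positive integer, got '%s'", toks[1]
    ))
  }
  need <- 1L + k + k * k
  if (length(toks) != need) {
    cyto_error("spillover_format_error", sprintf(
      "$SPILLOVER with k=%d needs %d tokens, got %d", k, need, length(toks)
    ))
  }
  detectors <- toks[2:(k + 1L)]
  vals <- suppressWarnings(as.numeric(toks[(k + 2L):need]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1] + k + 1L
    cyto_error("spillover_format_error", sprintf(
      "non-numeric $SPILLOVER matrix entry at token %d: '%s'", bad, toks[bad]
    ))
  }
  spillover_matrix(matrix(vals, nrow = k, byrow = TRUE), detectors)
}

#' Serialize a spillover matrix as a `$SPILLOVER` keyword value
#'
#' @param spill a [spillover_matrix()].
#' @return keyword string (row-major layout).
#' @export
serialize_spillover_keyword <- function(spill) {
  stopifnot(inherits(spill, "spillover_matrix"))
  paste(
    c(
      length(spill$detectors), spill$detectors,
      .fmt_num(as.vector(t(spill$S)))
    ),
    collapse = ","
  )
}

.spill_inverse <- function(spill) {
  S <- spill$S
  dt <- det(S)
  scale <- prod(diag(S))
  if (abs(dt) < 1e-12 * max(abs(scale), 1)) {
    cyto_error("spillover_singular_error", sprintf(
      "spillover matrix is numerically singular (|det| = %.3g); inspect the matrix",
      abs(dt)
    ))
  }
  solve(S)
}

#' Apply spillover to true signals (forward model)
#'
#' Maps true fluorochrome signals to observed detector signals:
#' `observed = true %*% S`.  Used by the synthetic-data generator and as
#' the inverse of [compensate()].
#'
#' @param events numeric matrix whose mapped columns hold true signals.
#' @param spill a [spillover_matrix()].
#' @param channel_map integer or character index of the event-matrix
#'   columns corresponding to `spill$detectors` (default: match by name).
#' @return event matrix with the mapped columns mixed by `S`.
#' @export
apply_spillover <- function(events, spill, channel_map = NULL) {
  idx <- .resolve_channel_map(events, spill, channel_map)
  events[, idx] <- events[, idx, drop = FALSE] %*% spill$S
  events
}

#' Compensate observed signals
#'
#' Replaces the mapped columns of the event matrix with
#' `observed %*% solve(S)`; unmapped columns (e.g. scatter) are untouched.
#'
#' @inheritParams apply_spillover
#' @return compensated event matrix.
#' @export
compensate <- function(events, spill, channel_map = NULL) {
  idx <- .resolve_channel_map(events, spill, channel_map)
  events[, idx] <- events[, idx, drop = FALSE] %*% .spill_inverse(spill)
  events
}

.resolve_channel_map <- function(events, spill, channel_map) {
  stopifnot(inherits(spill, "spillover_matrix"))
  k <- length(spill$detectors)
  if (is.null(channel_map)) {
    if (is.null(colnames(events))) {
      cyto_error("spillover_mapping_error", "event matrix has no column names; supply channel_map")
    }
    idx <- match(spill$detectors, colnames(events))
    if (anyNA(idx)) {
      cyto_error("spillover_mapping_error", sprintf(
        "detector(s) %s not found among event columns; candidates: %s",
        paste(spill$detectors[is.na(idx)], collapse = ", "),
        paste(colnames(events), collapse = ", ")
      ))
    }
  } else if (is.character(channel_map)) {
    idx <- match(channel_map, colnames(events))
    if (anyNA(idx)) {
      cyto_error("spillover_mapping_error", sprintf(
        "channel(s) %s not found among event columns",
        paste(channel_map[is.na(idx)], collapse = ", ")
      ))
    }
  } else {
    idx <- as.integer(channel_map)
  }
  if (length(idx) != k || anyDuplicated(idx)) {
    cyto_error("spillover_mapping_error", sprintf(
      "channel_map must give %d distinct columns", k
    ))
  }
  idx
}

#' Compensate an FCS dataset in place
#'
#' Uses the supplied spillover matrix, or the dataset's own `$SPILLOVER`
#' keyword when none is given.
#'
#' @param dataset an [fcs_dataset()].
#' @param spill optional [spillover_matrix()].
#' @return the dataset with compensated events.
#' @export
compensate_dataset <- function(dataset, spill = NULL) {
  if (is.null(spill)) {
    v <- kw_get(dataset$keywords, "$SPILLOVER")
    if (is.null(v)) {
      cyto_error("spillover_error", "dataset has no $SPILLOVER keyword and no matrix was supplied")
    }
    spill <- parse_spillover_keyword(v)
  }
  dataset$events <- compensate(dataset$events, spill)
  dataset
}
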