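# Data model for gates and gating strategies.
#
# A gate selects events by a geometric predicate on one or more dimensions;
# a dimension names a channel ($PnN) and optionally a compensation and a
# scale transformation applied before the geometry is evaluated.  Gates are
# arranged in a forest: a gate's population is the intersection of its own
# predicate with its parent's population.

#' Define a gate dimension
#'
#' @param channel channel short name (`$PnN`).
#' @param transform_ref optional id of a transform registered in the owning
#'   [gating_strategy()]; when present the gate geometry lives in that
#'   transform's display space.
#' @param compensation_ref `"uncompensated"` (default), `"FCS"` (use the
#'   dataset's own `$SPILLOVER`), or the id of a spectrum matrix registered
#'   in the strategy.
#' @return object of class `gate_dimension`.
#' @export
gate_dimension <- function(channel, transform_ref = NULL,
                           compensation_ref = "uncompensated") {
  stopifnot(is.character(channel), length(channel) == 1L)
  structure(
    list(
      channel = channel,
      transform_ref = transform_ref,
      compensation_ref = compensation_ref
    ),
    class = "gate_dimension"
  )
}

.as_dims <- function(dims) {
  lapply(dims, function(d) {
    if (inherits(d, "gate_dimension")) d else gate_dimension(d)
  })
}

#' Rectangle gate
#'
#' An axis-aligned box; absent bounds are infinite, so one-dimensional
#' range gates are rectangles with a single dimension.  Membership is
#' min-edge inclusive and max-edge exclusive.
#'
#' @param id gate identifier.
#' @param dims list of [gate_dimension()]s (or channel names).
#' @param mins,maxs numeric vectors of per-dimension bounds (in display
#'   space when the dimension has a transform); use `-Inf` / `Inf` for
#'   absent bounds.
#' @param parent_id optional id of the parent gate.
#' @return object of class `rectangle_gate`.
#' @export
rectangle_gate <- function(id, dims, mins, maxs, parent_id = NULL) {
  dims <- .as_dims(dims)
  if (length(dims) < 1L) cyto_error("gate_error", "rectangle gate needs >= 1 dimension")
  mins <- rep_len(as.numeric(mins), length(dims))
  maxs <- rep_len(as.numeric(maxs), length(dims))
  both <- is.finite(mins) & is.finite(maxs)
  if (any(both & mins >= maxs)) {
    cyto_error("gate_error", sprintf("gate '%s': min must be < max on every dimension", id))
  }
  structure(
    list(id = id, parent_id = parent_id, dims = dims, mins = mins, maxs = maxs),
    class = c("rectangle_gate", "cyto_gate")
  )
}

#' Polygon gate
#'
#' A two-dimensional polygon evaluated with crossing-number (even-odd)
#' semantics; the boundary is inclusive.  Self-intersecting polygons are
#' allowed (even-odd rule applies); zero-area polygons are rejected.
#'
#' @param id gate identifier.
#' @param dims two [gate_dimension()]s (or channel names).
#' @param vertices numeric matrix (>= 3 rows, 2 columns) of vertices in the
#'   dimensions' (possibly transformed) space.
#' @param parent_id optional parent gate id.
#' @return object of class `polygon_gate`.
#' @export
polygon_gate <- function(id, dims, vertices, parent_id = NULL) {
  dims <- .as_dims(dims)
  if (length(dims) != 2L) cyto_error("gate_error", "polygon gate needs exactly 2 dimensions")
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3L || ncol(vertices) != 2L) {
    cyto_error("gate_error", sprintf("gate '%s': need >= 3 two-dimensional vertices", id))
  }
  x <- vertices[, 1]
  y <- vertices[, 2]
  area2 <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  if (abs(area2) < .Machine$double.eps * max(abs(c(x, y, 1)))^2) {
    cyto_error("gate_error", sprintf("gate '%s': polygon has zero area", id))
  }
  structure(
    list(id = id, parent_id = parent_id, dims = dims, vertices = unname(vertices)),
    class = c("polygon_gate", "cyto_gate")
  )
}

#' Ellipsoid gate
#'
#' Membership rule: `(x - mu)' C^{-1} (x - mu) <= D^2` (boundary
#' inclusive).
#'
#' @param id gate identifier.
#' @param dims list of [gate_dimension()]s (or channel names).
#' @param mean numeric center vector (one entry per dimension).
#' @param covariance symmetric positive-definite matrix.
#' @param distance_square positive scalar `D^2`.
#' @param parent_id optional parent gate id.
#' @return object of class `ellipsoid_gate`.
#' @export
ellipsoid_gate <- function(id, dims, mean, covariance, distance_square,
                           parent_id = NULL) {
  dims <- .as_dims(dims)
  d <- length(dims)
  mean <- as.numeric(mean)
  covariance <- as.matrix(covariance)
  if (length(mean) != d || any(dim(covariance) != d)) {
    cyto_error("gate_error", sprintf("gate '%s': mean/covariance dimensions must match dims", id))
  }
  if (max(abs(covariance - t(covariance))) > 1e-9 * max(abs(covariance))) {
    cyto_error("gate_error", sprintf("gate '%s': covariance must be symmetric", id))
  }
  ev <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    cyto_error("gate_error", sprintf("gate '%s': covariance must be positive definite", id))
  }
  if (!is.finite(distance_square) || distance_square <= 0) {
    cyto_error("gate_error", sprintf("gate '%s': distance_square must be > 0", id))
  }
  structure(
    list(
      id = id, parent_id = parent_id, dims = dims, mean = mean,
      covariance = unname(covariance), distance_square = distance_square
    ),
    class = c("ellipsoid_gate", "cyto_gate")
  )
}

#' Boolean gate
#'
#' Combines other gates by AND, OR or NOT; operands may be individually
#' complemented.  Operand membership includes the operand's own parent
#' clipping.
#'
#' @param id gate identifier.
#' @param operator `"AND"`, `"OR"` or `"NOT"`.
#' @param operands character vector of gate ids, or a list of
#'   `list(ref = , complement = )` entries.
#' @param parent_id optional parent gate id.
#' @return object of class `boolean_gate`.
#' @export
boolean_gate <- function(id, operator = c("AND", "OR", "NOT"), operands,
                         parent_id = NULL) {
  operator <- match.arg(operator)
  if (is.character(operands)) {
    operands <- lapply(operands, function(r) list(ref = r, complement = FALSE))
  }
  operands <- lapply(operands, function(o) {
    list(ref = o$ref, complement = isTRUE(o$complement))
  })
  n <- length(operands)
  if (operator == "NOT" && n != 1L) {
    cyto_error("gate_error", sprintf("gate '%s': NOT takes exactly 1 operand", id))
  }
  if (operator != "NOT" && n < 2L) {
    cyto_error("gate_error", sprintf("gate '%s': %s takes >= 2 operands", id, operator))
  }
  structure(
    list(id = id, parent_id = parent_id, operator = operator, operands = operands),
    class = c("boolean_gate", "cyto_gate")
  )
}

#' Assemble a gating strategy
#'
#' @param gates list of gates (any order; declaration order never affects
#'   evaluation).
#' @param transforms list of [transform_scale()] objects referenced by gate
#'   dimensions.
#' @param spectrum_matrices list of [spillover_matrix()] objects referenced
#'   by gate dimensions.
#' @return object of class `gating_strategy` with gates, transforms and
#'   matrices keyed by id.
#' @export
gating_strategy <- function(gates = list(), transforms = list(),
                            spectrum_matrices = list()) {
  gates <- stats::setNames(gates, vapply(gates, `[[`, "", "id"))
  transforms <- stats::setNames(transforms, vapply(transforms, `[[`, "", "id"))
  spectrum_matrices <- stats::setNames(
    spectrum_matrices,
    vapply(spectrum_matrices, function(m) m$id %||% "", "")
  )
  all_ids <- c(names(gates), names(transforms), names(spectrum_matrices))
  if (anyDuplicated(all_ids)) {
    cyto_error("reference_error", sprintf(
      "id collision across registries: %s",
      paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")
    ))
  }
  s <- structure(
    list(
      gates = gates, transforms = transforms,
      spectrum_matrices = spectrum_matrices
    ),
    class = "gating_strategy"
  )
  .validate_strategy(s)
  s
}

.validate_strategy <- function(s) {
  gids <- names(s$gates)
  dangling <- character(0)
  for (g in s$gates) {
    if (!is.null(g$parent_id) && !g$parent_id %in% gids) {
      dangling <- c(dangling, g$parent_id)
    }
    if (inherits(g, "boolean_gate")) {
      refs <- vapply(g$operands, `[[`, "", "ref")
      dangling <- c(dangling, setdiff(refs, gids))
    }
    for (d in g$dims %||% list()) {
      if (!is.null(d$transform_ref) && !d$transform_ref %in% names(s$transforms)) {
        dangling <- c(dangling, d$transform_ref)
      }
      if (!d$compensation_ref %in% c("uncompensated", "FCS") &&
        !d$compensation_ref %in% names(s$spectrum_matrices)) {
        dangling <- c(dangling, d$compensation_ref)
      }
    }
  }
  if (length(dangling)) {
    cyto_error("reference_error", sprintf(
      "dangling reference(s): %s", paste(unique(dangling), collapse = ", ")
    ))
  }
  # parent graph must be a forest (cycles through parent_id are impossible
  # to evaluate); boolean reference cycles are caught at evaluation time
  for (start in gids) {
    seen <- character(0)
    cur <- start
    while (!is.null(cur)) {
      if (cur %in% seen) {
        cyto_error("cycle_error", sprintf(
          "parent cycle: %s", paste(c(seen, cur), collapse = " -> ")
        ))
      }
      seen <- c(seen, cur)
      cur <- s$gates[[cur]]$parent_id
    }
  }
  invisible(s)
}

#' @export
print.gating_strategy <- function(x, ...) {
  cat(sprintf(
    "<gating_strategy> %d gate(s), %d transform(s), %d spectrum matrix/matrices\n",
    length(x$gates), length(x$transforms), length(x$spectrum_matrices)
  ))
  for (g in x$gates) {
    cat(sprintf(
      "  %s (%s)%s\n", g$id, class(g)[1],
      if (is.null(g$parent_id)) "" else paste0(" < ", g$parent_id)
    ))
  }
  invisible(x)
}
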