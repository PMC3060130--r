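# Vectorized evaluation of gates against an FCS dataset.
#
# A gate's population is its own geometric predicate intersected with its
# parent's population, recursively.  Dimension values are prepared by
# applying the dimension's compensation first and its transform second.
# Boundary rules are pinned: rectangles are min-inclusive / max-exclusive,
# polygon and ellipsoid boundaries are inclusive.

# Evaluation context: caches compensated event matrices and per-gate
# memberships so shared ancestors are computed once.
.new_eval_ctx <- function(strategy, dataset) {
  env <- new.env(parent = emptyenv())
  env$strategy <- strategy
  env$dataset <- dataset
  env$comp <- list() # compensation_ref -> event matrix
  env$membership <- list() # gate id -> logical vector
  env$visiting <- character(0) # boolean-reference cycle detection
  env
}

.compensated_events <- function(ctx, comp_ref) {
  key <- comp_ref
  if (!is.null(ctx$comp[[key]])) {
    return(ctx$comp[[key]])
  }
  ev <- ctx$dataset$events
  out <- if (identical(comp_ref, "uncompensated")) {
    ev
  } else if (identical(comp_ref, "FCS")) {
    v <- kw_get(ctx$dataset$keywords, "$SPILLOVER")
    if (is.null(v)) {
      cyto_error("spillover_error", "gate requests FCS compensation but the dataset has no $SPILLOVER keyword")
    }
    compensate(ev, parse_spillover_keyword(v))
  } else {
    compensate(ev, ctx$strategy$spectrum_matrices[[comp_ref]])
  }
  ctx$comp[[key]] <- out
  out
}

# Channel values for one dimension, in display space when the dimension
# has a transform and in data space otherwise.
.dim_values <- function(ctx, dim, space = c("display", "data")) {
  space <- match.arg(space)
  ev <- .compensated_events(ctx, dim$compensation_ref)
  j <- match(dim$channel, ctx$dataset$parameters$name)
  if (is.na(j)) {
    cyto_error("channel_error", sprintf(
      "channel '%s' not in dataset; available $PnN values: %s",
      dim$channel, paste(ctx$dataset$parameters$name, collapse = ", ")
    ))
  }
  x <- ev[, j]
  if (space == "display" && !is.null(dim$transform_ref)) {
    x <- apply_transform(ctx$strategy$transforms[[dim$transform_ref]], x)
  }
  x
}

.dim_transform <- function(ctx, dim) {
  if (is.null(dim$transform_ref)) NULL else ctx$strategy$transforms[[dim$transform_ref]]
}

# Crossing-number (even-odd) point-in-polygon with inclusive boundary.
.points_in_polygon <- function(px, py, vx, vy) {
  nv <- length(vx)
  inside <- rep(FALSE, length(px))
  on_boundary <- rep(FALSE, length(px))
  j <- nv
  for (i in seq_len(nv)) {
    xi <- vx[i]
    yi <- vy[i]
    xj <- vx[j]
    yj <- vy[j]
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    on_seg <- cross == 0 &
      px >= pmin(xi, xj) & px <= pmax(xi, xj) &
      py >= pmin(yi, yj) & py <= pmax(yi, yj)
    on_boundary <- on_boundary | on_seg
    crosses <- ((yi > py) != (yj > py)) &
      (px < xi + (py - yi) * (xj - xi) / (yj - yi))
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_boundary
}

.geometry_membership <- function(gate, ctx) {
  UseMethod(".geometry_membership")
}

#' @export
.geometry_membership.rectangle_gate <- function(gate, ctx) {
  # rectangles are evaluated in data space: display-space bounds are
  # inverse-transformed once, which is cheaper than transforming events
  # and identical because transforms are strictly increasing
  keep <- rep(TRUE, n_events(ctx$dataset))
  for (k in seq_along(gate$dims)) {
    dim <- gate$dims[[k]]
    x <- .dim_values(ctx, dim, space = "data")
    tr <- .dim_transform(ctx, dim)
    lo <- gate$mins[k]
    hi <- gate$maxs[k]
    if (!is.null(tr)) {
      if (is.finite(lo)) lo <- invert_transform(tr, lo)
      if (is.finite(hi)) hi <- invert_transform(tr, hi)
    }
    keep <- keep & (x >= lo) & (x < hi)
  }
  keep
}

#' @export
.geometry_membership.polygon_gate <- function(gate, ctx) {
  px <- .dim_values(ctx, gate$dims[[1]])
  py <- .dim_values(ctx, gate$dims[[2]])
  .points_in_polygon(px, py, gate$vertices[, 1], gate$vertices[, 2])
}

#' @export
.geometry_membership.ellipsoid_gate <- function(gate, ctx) {
  X <- vapply(gate$dims, function(d) .dim_values(ctx, d), numeric(n_events(ctx$dataset)))
  if (n_events(ctx$dataset) == 1L) X <- matrix(X, nrow = 1L)
  d2 <- stats::mahalanobis(X, center = gate$mean, cov = gate$covariance)
  d2 <= gate$distance_square
}

#' @export
.geometry_membership.boolean_gate <- function(gate, ctx) {
  if (gate$id %in% ctx$visiting) {
    cyto_error("cycle_error", sprintf(
      "Boolean gate reference cycle: %s",
      paste(c(ctx$visiting, gate$id), collapse = " -> ")
    ))
  }
  ctx$visiting <- c(ctx$visiting, gate$id)
  on.exit(ctx$visiting <- setdiff(ctx$visiting, gate$id))
  ops <- lapply(gate$operands, function(o) {
    m <- .gate_membership(ctx, o$ref)
    if (o$complement) !m else m
  })
  switch(gate$operator,
    NOT = !ops[[1]],
    AND = Reduce(`&`, ops),
    OR = Reduce(`|`, ops)
  )
}

.gate_membership <- function(ctx, gate_id) {
  if (!is.null(ctx$membership[[gate_id]])) {
    return(ctx$membership[[gate_id]])
  }
  gate <- ctx$strategy$gates[[gate_id]]
  if (is.null(gate)) {
    cyto_error("reference_error", sprintf("no gate with id '%s'", gate_id))
  }
  m <- .geometry_membership(gate, ctx)
  if (!is.null(gate$parent_id)) {
    m <- m & .gate_membership(ctx, gate$parent_id)
  }
  ctx$membership[[gate_id]] <- m
  m
}

#' Evaluate one gate
#'
#' @param strategy a [gating_strategy()].
#' @param gate_id gate to evaluate.
#' @param dataset an [fcs_dataset()].
#' @return logical membership vector of length `n_events`.
#' @export
evaluate_gate <- function(strategy, gate_id, dataset) {
  ctx <- .new_eval_ctx(strategy, dataset)
  .gate_membership(ctx, gate_id)
}

#' Evaluate every gate in a strategy
#'
#' @param strategy a [gating_strategy()].
#' @param dataset an [fcs_dataset()].
#' @return list with `membership` (named list of logical vectors) and
#'   `stats` (data frame: gate id, parent, count, pct_of_parent,
#'   pct_of_total).
#' @export
evaluate_all <- function(strategy, dataset) {
  ctx <- .new_eval_ctx(strategy, dataset)
  ids <- names(strategy$gates)
  membership <- lapply(ids, function(id) .gate_membership(ctx, id))
  names(membership) <- ids
  n <- n_events(dataset)
  stats <- do.call(rbind, lapply(ids, function(id) {
    g <- strategy$gates[[id]]
    cnt <- sum(membership[[id]])
    pcount <- if (is.null(g$parent_id)) n else sum(membership[[g$parent_id]])
    data.frame(
      id = id,
      parent = g$parent_id %||% NA_character_,
      count = cnt,
      pct_of_parent = if (pcount > 0) 100 * cnt / pcount else NA_real_,
      pct_of_total = if (n > 0) 100 * cnt / n else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  list(membership = membership, stats = stats)
}
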