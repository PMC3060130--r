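# XML serialization of gating strategies.
#
# The written dialect follows the harmonized gate-description schema
# (rectangle/polygon/ellipsoid/Boolean gates, five transform kinds, and
# spectrum matrices) under a single pinned namespace triple.  Reading is
# tolerant: any root namespace under the isac-net Gating-ML URI prefix is
# accepted where element shapes coincide, so both the 2008 and the revised
# vocabularies parse.  Unsupported gate elements (quadrant gates, decision
# trees, ...) fail with a named unsupported-feature error.

GATINGML_NS <- c(
  gating = "http://www.isac-net.org/std/Gating-ML/v2.0/gating",
  transforms = "http://www.isac-net.org/std/Gating-ML/v2.0/transformations",
  `data-type` = "http://www.isac-net.org/std/Gating-ML/v2.0/datatypes"
)

GATINGML_READ_NS_PREFIX <- "http://www.isac-net.org/std/Gating-ML/"

.local_name <- function(node) xml2::xml_name(node, ns = character())

# attribute lookup by local name, ignoring any namespace prefix
.gml_attr <- function(node, name, default = NULL) {
  at <- xml2::xml_attrs(node)
  if (!length(at)) {
    return(default)
  }
  loc <- sub("^.*:", "", names(at))
  hit <- which(loc == name)
  if (!length(hit)) default else unname(at[hit[1]])
}

.gml_attr_num <- function(node, name, default = NULL) {
  v <- .gml_attr(node, name)
  if (is.null(v)) {
    return(default)
  }
  out <- suppressWarnings(as.numeric(v))
  if (is.na(out)) {
    cyto_error("gatingml_format_error", sprintf(
      "attribute %s has non-numeric value '%s'", name, v
    ))
  }
  out
}

.gml_children <- function(node, name) {
  kids <- xml2::xml_children(node)
  kids[vapply(kids, .local_name, "") == name]
}

# ---------------------------------------------------------------- writing

.write_dimension <- function(parent, dim, min = NULL, max = NULL) {
  attrs <- list("gating:compensation-ref" = dim$compensation_ref)
  if (!is.null(dim$transform_ref)) {
    attrs[["gating:transformation-ref"]] <- dim$transform_ref
  }
  if (!is.null(min) && is.finite(min)) attrs[["gating:min"]] <- .fmt_num(min)
  if (!is.null(max) && is.finite(max)) attrs[["gating:max"]] <- .fmt_num(max)
  node <- do.call(xml2::xml_add_child, c(list(parent, "gating:dimension"), attrs))
  xml2::xml_add_child(node, "data-type:fcs-dimension", "data-type:name" = dim$channel)
  node
}

.gate_attrs <- function(gate) {
  a <- list("gating:id" = gate$id)
  if (!is.null(gate$parent_id)) a[["gating:parent_id"]] <- gate$parent_id
  a
}

.write_gate <- function(root, gate) {
  if (inherits(gate, "rectangle_gate")) {
    node <- do.call(xml2::xml_add_child, c(list(root, "gating:RectangleGate"), .gate_attrs(gate)))
    for (k in seq_along(gate$dims)) {
      .write_dimension(node, gate$dims[[k]], gate$mins[k], gate$maxs[k])
    }
  } else if (inherits(gate, "polygon_gate")) {
    node <- do.call(xml2::xml_add_child, c(list(root, "gating:PolygonGate"), .gate_attrs(gate)))
    for (d in gate$dims) .write_dimension(node, d)
    for (r in seq_len(nrow(gate$vertices))) {
      v <- xml2::xml_add_child(node, "gating:vertex")
      xml2::xml_add_child(v, "gating:coordinate", "data-type:value" = .fmt_num(gate$vertices[r, 1]))
      xml2::xml_add_child(v, "gating:coordinate", "data-type:value" = .fmt_num(gate$vertices[r, 2]))
    }
  } else if (inherits(gate, "ellipsoid_gate")) {
    node <- do.call(xml2::xml_add_child, c(list(root, "gating:EllipsoidGate"), .gate_attrs(gate)))
    for (d in gate$dims) .write_dimension(node, d)
    mn <- xml2::xml_add_child(node, "gating:mean")
    for (v in gate$mean) {
      xml2::xml_add_child(mn, "gating:coordinate", "data-type:value" = .fmt_num(v))
    }
    cv <- xml2::xml_add_child(node, "gating:covarianceMatrix")
    for (r in seq_len(nrow(gate$covariance))) {
      row <- xml2::xml_add_child(cv, "gating:row")
      for (v in gate$covariance[r, ]) {
        xml2::xml_add_child(row, "gating:entry", "data-type:value" = .fmt_num(v))
      }
    }
    xml2::xml_add_child(node, "gating:distanceSquare",
      "data-type:value" = .fmt_num(gate$distance_square)
    )
  } else if (inherits(gate, "boolean_gate")) {
    node <- do.call(xml2::xml_add_child, c(list(root, "gating:BooleanGate"), .gate_attrs(gate)))
    op <- xml2::xml_add_child(node, paste0("gating:", tolower(gate$operator)))
    for (o in gate$operands) {
      attrs <- list("gating:ref" = o$ref)
      if (o$complement) attrs[["gating:use-as-complement"]] <- "true"
      do.call(xml2::xml_add_child, c(list(op, "gating:gateReference"), attrs))
    }
  } else {
    cyto_error("gatingml_unsupported_feature", sprintf(
      "cannot serialize gate of class %s", class(gate)[1]
    ))
  }
}

.write_transform <- function(root, tr) {
  node <- xml2::xml_add_child(root, "transforms:transformation", "transforms:id" = tr$id)
  attrs <- list("transforms:T" = .fmt_num(tr$T))
  if (tr$kind == "flin") {
    attrs[["transforms:A"]] <- .fmt_num(tr$A)
  } else {
    attrs[["transforms:M"]] <- .fmt_num(tr$M)
    if (tr$kind %in% c("logicle", "hyperlog")) attrs[["transforms:W"]] <- .fmt_num(tr$W)
    if (tr$kind != "flog") attrs[["transforms:A"]] <- .fmt_num(tr$A)
  }
  do.call(xml2::xml_add_child, c(list(node, paste0("transforms:", tr$kind)), attrs))
}

.write_spectrum_matrix <- function(root, sm) {
  node <- xml2::xml_add_child(root, "transforms:spectrumMatrix", "transforms:id" = sm$id)
  fl <- xml2::xml_add_child(node, "transforms:fluorochromes")
  dt <- xml2::xml_add_child(node, "transforms:detectors")
  for (d in sm$detectors) {
    xml2::xml_add_child(fl, "data-type:fcs-dimension", "data-type:name" = d)
    xml2::xml_add_child(dt, "data-type:fcs-dimension", "data-type:name" = d)
  }
  for (r in seq_len(nrow(sm$S))) {
    row <- xml2::xml_add_child(node, "transforms:spectrum")
    for (v in sm$S[r, ]) {
      xml2::xml_add_child(row, "transforms:coefficient", "transforms:value" = .fmt_num(v))
    }
  }
}

#' Write a gating strategy as Gating-ML XML
#'
#' @param strategy a [gating_strategy()].
#' @param path optional file path; when `NULL` the XML text is returned.
#' @return XML as a character scalar (invisibly when `path` is given).
#' @export
write_gatingml <- function(strategy, path = NULL) {
  stopifnot(inherits(strategy, "gating_strategy"))
  root <- xml2::xml_new_root("gating:Gating-ML",
    "xmlns:gating" = GATINGML_NS[["gating"]],
    "xmlns:transforms" = GATINGML_NS[["transforms"]],
    "xmlns:data-type" = GATINGML_NS[["data-type"]]
  )
  for (tr in strategy$transforms) .write_transform(root, tr)
  for (sm in strategy$spectrum_matrices) .write_spectrum_matrix(root, sm)
  for (g in strategy$gates) .write_gate(root, g)
  txt <- as.character(root)
  if (!is.null(path)) {
    writeLines(txt, path, useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

# ---------------------------------------------------------------- reading

.read_dimension <- function(node) {
  fcsdim <- .gml_children(node, "fcs-dimension")
  if (!length(fcsdim)) {
    cyto_error("gatingml_format_error", "dimension without fcs-dimension child")
  }
  gate_dimension(
    channel = .gml_attr(fcsdim[[1]], "name"),
    transform_ref = .gml_attr(node, "transformation-ref"),
    compensation_ref = .gml_attr(node, "compensation-ref", "uncompensated")
  )
}

.read_gate <- function(node) {
  kind <- .local_name(node)
  id <- .gml_attr(node, "id")
  parent_id <- .gml_attr(node, "parent_id")
  dims_nodes <- .gml_children(node, "dimension")
  if (kind == "RectangleGate") {
    dims <- lapply(dims_nodes, .read_dimension)
    mins <- vapply(dims_nodes, function(d) .gml_attr_num(d, "min", -Inf), numeric(1))
    maxs <- vapply(dims_nodes, function(d) .gml_attr_num(d, "max", Inf), numeric(1))
    rectangle_gate(id, dims, mins, maxs, parent_id = parent_id)
  } else if (kind == "PolygonGate") {
    dims <- lapply(dims_nodes, .read_dimension)
    verts <- t(vapply(.gml_children(node, "vertex"), function(v) {
      vapply(.gml_children(v, "coordinate"), .gml_attr_num, numeric(1), name = "value")
    }, numeric(2)))
    polygon_gate(id, dims, verts, parent_id = parent_id)
  } else if (kind == "EllipsoidGate") {
    dims <- lapply(dims_nodes, .read_dimension)
    mean <- vapply(
      .gml_children(.gml_children(node, "mean")[[1]], "coordinate"),
      .gml_attr_num, numeric(1),
      name = "value"
    )
    rows <- .gml_children(.gml_children(node, "covarianceMatrix")[[1]], "row")
    cov <- t(vapply(rows, function(r) {
      vapply(.gml_children(r, "entry"), .gml_attr_num, numeric(1), name = "value")
    }, numeric(length(mean))))
    d2 <- .gml_attr_num(.gml_children(node, "distanceSquare")[[1]], "value")
    ellipsoid_gate(id, dims, mean, cov, d2, parent_id = parent_id)
  } else if (kind == "BooleanGate") {
    kids <- xml2::xml_children(node)
    opname <- .local_name(kids[[1]])
    if (!opname %in% c("and", "or", "not")) {
      cyto_error("gatingml_unsupported_feature", sprintf(
        "unsupported Boolean operator element '%s'", opname
      ))
    }
    operands <- lapply(.gml_children(kids[[1]], "gateReference"), function(r) {
      list(
        ref = .gml_attr(r, "ref"),
        complement = identical(.gml_attr(r, "use-as-complement"), "true")
      )
    })
    boolean_gate(id, toupper(opname), operands, parent_id = parent_id)
  } else {
    cyto_error("gatingml_unsupported_feature", sprintf(
      "unsupported gate element '%s'", kind
    ))
  }
}

.read_transform <- function(node) {
  id <- .gml_attr(node, "id")
  kids <- xml2::xml_children(node)
  if (!length(kids)) cyto_error("gatingml_format_error", "empty transformation element")
  spec <- kids[[1]]
  kind <- .local_name(spec)
  if (!kind %in% c("flin", "flog", "fasinh", "logicle", "hyperlog")) {
    cyto_error("gatingml_unsupported_feature", sprintf(
      "unsupported transformation element '%s'", kind
    ))
  }
  transform_scale(
    kind,
    T = .gml_attr_num(spec, "T"),
    M = .gml_attr_num(spec, "M", 4.5),
    W = .gml_attr_num(spec, "W", 0),
    A = .gml_attr_num(spec, "A", 0),
    id = id
  )
}

.read_spectrum_matrix <- function(node) {
  id <- .gml_attr(node, "id")
  det_nodes <- .gml_children(.gml_children(node, "detectors")[[1]], "fcs-dimension")
  detectors <- vapply(det_nodes, .gml_attr, "", name = "name")
  rows <- .gml_children(node, "spectrum")
  S <- t(vapply(rows, function(r) {
    vapply(.gml_children(r, "coefficient"), .gml_attr_num, numeric(1), name = "value")
  }, numeric(length(detectors))))
  spillover_matrix(S, detectors, id = id)
}

#' Read a Gating-ML XML document
#'
#' @param xml file path, XML text, or an `xml_document`.
#' @return a [gating_strategy()].
#' @export
read_gatingml <- function(xml) {
  doc <- if (inherits(xml, "xml_document")) xml else xml2::read_xml(xml)
  root <- xml2::xml_root(doc)
  ns_uri <- xml2::xml_ns(doc)
  root_ns <- tryCatch(xml2::xml_attr(root, "xmlns"), error = function(e) NA)
  uris <- unlist(as.list(ns_uri))
  if (!any(startsWith(uris, GATINGML_READ_NS_PREFIX))) {
    cyto_error("gatingml_format_error", sprintf(
      "document namespace(s) %s are not a Gating-ML vocabulary",
      paste(unique(uris), collapse = ", ")
    ))
  }
  if (.local_name(root) != "Gating-ML") {
    cyto_error("gatingml_format_error", sprintf(
      "unexpected root element '%s'", .local_name(root)
    ))
  }
  gates <- list()
  transforms <- list()
  matrices <- list()
  for (node in xml2::xml_children(root)) {
    nm <- .local_name(node)
    if (nm == "transformation") {
      transforms <- c(transforms, list(.read_transform(node)))
    } else if (nm == "spectrumMatrix") {
      matrices <- c(matrices, list(.read_spectrum_matrix(node)))
    } else if (endsWith(nm, "Gate")) {
      gates <- c(gates, list(.read_gate(node)))
    } else {
      cyto_error("gatingml_unsupported_feature", sprintf(
        "unsupported element '%s'", nm
      ))
    }
  }
  gating_strategy(gates, transforms, matrices)
}
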