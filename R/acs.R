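# Archival Cytometry Standard (ACS) containers.
#
# An ACS container is a ZIP archive whose members are the files of an
# experiment (FCS data, gate descriptions, classification results, ...)
# plus an XML table of contents (ToC) at "TOC.xml" that types each member,
# records per-member checksums, and relates members to one another
# ("preprocessed-from", "classification-results-of", ...).  Integrity is
# checksum-based (SHA-256 per entry); opaque signature blocks in the ToC
# are preserved round-trip as an extension point for digital signatures.

ACS_TOC_NS <- "http://www.cytostd.org/ns/acs-toc/v1.0"
ACS_TOC_NAME <- "TOC.xml"
ACS_TOC_PATTERN <- "^TOC[^/]*\\.xml$"
ACS_VERSION <- "1.0"

ACS_KNOWN_RELATIONSHIPS <- c(
  "preprocessed-from", "gating-description-of", "classification-results-of",
  "compensated-version-of", "derived-from"
)

#' Describe one container member
#'
#' @param uri container-internal path of the member.
#' @param media_type free-form media type, e.g.
#'   `"application/vnd.isac.fcs"`, `"application/xml+gating-ml"`,
#'   `"text/csv+clr"`.
#' @param role free-text description of the member's role.
#' @param checksum optional hex digest; computed from the member bytes by
#'   [acs_container()] when left `NULL`.
#' @param checksum_algorithm digest algorithm label (default `"SHA-256"`).
#' @return list of class `acs_entry`.
#' @export
acs_entry <- function(uri, media_type = "application/octet-stream",
                      role = NULL, checksum = NULL,
                      checksum_algorithm = "SHA-256") {
  structure(
    list(
      uri = uri, media_type = media_type, role = role,
      checksum = checksum, checksum_algorithm = checksum_algorithm
    ),
    class = "acs_entry"
  )
}

#' Relate two container members
#'
#' @param subject_uri,object_uri member uris; the subject is derived from /
#'   describes the object.
#' @param relationship controlled term; the known vocabulary is
#'   `preprocessed-from`, `gating-description-of`,
#'   `classification-results-of`, `compensated-version-of`,
#'   `derived-from`.  Unknown terms validate with a warning, not an error.
#' @return list of class `acs_relation`.
#' @export
acs_relation <- function(subject_uri, object_uri, relationship) {
  structure(
    list(
      subject_uri = subject_uri, object_uri = object_uri,
      relationship = relationship
    ),
    class = "acs_relation"
  )
}

#' Assemble an ACS container
#'
#' @param members named list of raw vectors (names are member uris).
#' @param entries list of [acs_entry()] objects; an entry is created
#'   automatically (with a SHA-256 checksum) for any member without one.
#' @param relations list of [acs_relation()] objects.
#' @param version ToC schema version string.
#' @param signatures optional opaque XML fragment (one or more elements)
#'   preserved verbatim inside the ToC's signatures block.
#' @return object of class `acs_container`.
#' @export
acs_container <- function(members = list(), entries = list(),
                          relations = list(), version = ACS_VERSION,
                          signatures = NULL) {
  if (length(members)) {
    stopifnot(!is.null(names(members)), all(nzchar(names(members))))
    if (anyDuplicated(names(members))) {
      cyto_error("acs_validation_error", "duplicate member uri(s)")
    }
  }
  entry_uris <- vapply(entries, `[[`, "", "uri")
  if (anyDuplicated(entry_uris)) {
    cyto_error("acs_validation_error", sprintf(
      "duplicate ToC entry uri(s): %s",
      paste(unique(entry_uris[duplicated(entry_uris)]), collapse = ", ")
    ))
  }
  # auto-register members lacking an entry, with a computed checksum
  for (uri in setdiff(names(members), entry_uris)) {
    entries <- c(entries, list(acs_entry(
      uri,
      media_type = .guess_media_type(uri),
      checksum = sha256_hex(members[[uri]])
    )))
  }
  entries <- lapply(entries, function(e) {
    if (is.null(e$checksum) && !is.null(members[[e$uri]])) {
      e$checksum <- sha256_hex(members[[e$uri]])
    }
    e
  })
  structure(
    list(
      members = members, entries = entries, relations = relations,
      version = version, signatures = signatures
    ),
    class = "acs_container"
  )
}

.guess_media_type <- function(uri) {
  low <- tolower(uri)
  if (endsWith(low, ".fcs")) {
    "application/vnd.isac.fcs"
  } else if (endsWith(low, ".xml")) {
    "application/xml"
  } else if (endsWith(low, ".csv")) {
    "text/csv"
  } else {
    "application/octet-stream"
  }
}

#' @export
print.acs_container <- function(x, ...) {
  cat(sprintf(
    "<acs_container> v%s: %d member(s), %d ToC entr%s, %d relation(s)\n",
    x$version, length(x$members), length(x$entries),
    if (length(x$entries) == 1) "y" else "ies", length(x$relations)
  ))
  for (e in x$entries) {
    cat(sprintf("  %s [%s]%s\n", e$uri, e$media_type, if (is.null(e$role)) "" else paste0(" - ", e$role)))
  }
  invisible(x)
}

# ------------------------------------------------------------------ ToC

.toc_xml <- function(container) {
  root <- xml2::xml_new_root("toc:TOC",
    "xmlns:toc" = ACS_TOC_NS,
    "toc:version" = container$version %||% ""
  )
  for (e in container$entries) {
    attrs <- list("toc:uri" = e$uri, "toc:mediaType" = e$media_type)
    if (!is.null(e$role)) attrs[["toc:role"]] <- e$role
    node <- do.call(xml2::xml_add_child, c(list(root, "toc:file"), attrs))
    if (!is.null(e$checksum)) {
      xml2::xml_add_child(node, "toc:checksum", e$checksum,
        "toc:algorithm" = e$checksum_algorithm
      )
    }
  }
  for (r in container$relations) {
    xml2::xml_add_child(root, "toc:relation",
      "toc:subject" = r$subject_uri, "toc:object" = r$object_uri,
      "toc:relationship" = r$relationship
    )
  }
  if (!is.null(container$signatures)) {
    sig <- xml2::xml_add_child(root, "toc:signatures")
    wrapped <- xml2::read_xml(sprintf(
      '<wrap xmlns:toc="%s">%s</wrap>', ACS_TOC_NS, container$signatures
    ))
    for (child in xml2::xml_children(wrapped)) {
      xml2::xml_add_child(sig, child)
    }
  }
  as.character(root)
}

.parse_toc <- function(xml_text) {
  doc <- xml2::read_xml(xml_text)
  root <- xml2::xml_root(doc)
  if (.local_name(root) != "TOC") {
    cyto_error("acs_format_error", sprintf(
      "ToC root element is '%s', expected 'TOC'", .local_name(root)
    ))
  }
  version <- .gml_attr(root, "version")
  entries <- list()
  relations <- list()
  signatures <- NULL
  for (node in xml2::xml_children(root)) {
    nm <- .local_name(node)
    if (nm == "file") {
      cs <- .gml_children(node, "checksum")
      entries <- c(entries, list(acs_entry(
        uri = .gml_attr(node, "uri"),
        media_type = .gml_attr(node, "mediaType", "application/octet-stream"),
        role = .gml_attr(node, "role"),
        checksum = if (length(cs)) xml2::xml_text(cs[[1]]) else NULL,
        checksum_algorithm = if (length(cs)) .gml_attr(cs[[1]], "algorithm", "SHA-256") else "SHA-256"
      )))
    } else if (nm == "relation") {
      relations <- c(relations, list(acs_relation(
        .gml_attr(node, "subject"), .gml_attr(node, "object"),
        .gml_attr(node, "relationship")
      )))
    } else if (nm == "signatures") {
      # keep the inner fragment verbatim (extension point for future
      # digital-signature support)
      signatures <- paste(
        vapply(xml2::xml_children(node), as.character, ""),
        collapse = ""
      )
    }
  }
  list(
    entries = entries, relations = relations, version = version,
    signatures = signatures
  )
}

# ----------------------------------------------------------- pack/unpack

#' Pack a container into ACS (ZIP) bytes
#'
#' The ToC is serialized as the first archive member, `TOC.xml`.  Output
#' is deterministic: identical containers pack to identical bytes.
#'
#' @param container an [acs_container()].
#' @param path optional output path (conventionally with extension
#'   `.acs`).
#' @return raw vector of archive bytes (invisibly when `path` is given).
#' @export
acs_pack <- function(container, path = NULL) {
  stopifnot(inherits(container, "acs_container"))
  rep <- acs_validate(container)
  errs <- rep[rep$level == "error", , drop = FALSE]
  if (nrow(errs)) {
    cyto_error("acs_validation_error", paste0(
      "container is not consistent:\n",
      paste(sprintf("  [%s] %s", errs$code, errs$message), collapse = "\n")
    ))
  }
  toc <- charToRaw(.toc_xml(container))
  members <- c(stats::setNames(list(toc), ACS_TOC_NAME), container$members)
  out <- zip_build(members)
  if (!is.null(path)) {
    writeBin(out, path)
    return(invisible(out))
  }
  out
}

#' Unpack ACS (ZIP) bytes into a container
#'
#' @param bytes_or_path raw archive bytes or a file path.
#' @return an [acs_container()]; the entry list, relations, version and
#'   any signature block come from the archive's ToC (checksums are kept
#'   as recorded, not recomputed — use [acs_validate()] to verify them).
#' @export
acs_unpack <- function(bytes_or_path) {
  members <- zip_extract(bytes_or_path)
  toc_idx <- grep(ACS_TOC_PATTERN, names(members))
  if (!length(toc_idx)) {
    cyto_error("acs_format_error", sprintf(
      "no table of contents: archive has no member matching %s", ACS_TOC_PATTERN
    ))
  }
  toc <- .parse_toc(rawToChar(members[[toc_idx[1]]]))
  structure(
    list(
      members = members[-toc_idx[1]],
      entries = toc$entries,
      relations = toc$relations,
      version = toc$version,
      signatures = toc$signatures
    ),
    class = "acs_container"
  )
}

# ------------------------------------------------------------- validate

.finding <- function(level, code, message) {
  data.frame(
    level = level, code = code, message = message,
    stringsAsFactors = FALSE
  )
}

#' Validate an ACS container
#'
#' Checks the bidirectional closure between ToC entries and archive
#' members, recomputes checksums, and vets relations.  An empty report
#' means the container is fully consistent.
#'
#' @param container an [acs_container()].
#' @return data frame of findings with columns `level` (`"error"` /
#'   `"warning"`), `code` and `message`.
#' @export
acs_validate <- function(container) {
  stopifnot(inherits(container, "acs_container"))
  findings <- list()
  entry_uris <- vapply(container$entries, `[[`, "", "uri")
  member_uris <- names(container$members) %||% character(0)

  for (uri in setdiff(entry_uris, member_uris)) {
    findings <- c(findings, list(.finding(
      "error", "MISSING_MEMBER",
      sprintf("ToC entry '%s' has no archive member", uri)
    )))
  }
  for (uri in setdiff(member_uris, entry_uris)) {
    findings <- c(findings, list(.finding(
      "warning", "ORPHAN_MEMBER",
      sprintf("member '%s' is not listed in the ToC", uri)
    )))
  }
  for (e in container$entries) {
    if (is.null(e$checksum) || is.null(container$members[[e$uri]])) next
    actual <- switch(toupper(e$checksum_algorithm),
      "SHA-256" = sha256_hex(container$members[[e$uri]]),
      "CRC-32" = sprintf("%08x", crc32(container$members[[e$uri]])),
      NA_character_
    )
    if (is.na(actual)) {
      findings <- c(findings, list(.finding(
        "warning", "UNKNOWN_CHECKSUM_ALGORITHM",
        sprintf("'%s': unknown checksum algorithm '%s'", e$uri, e$checksum_algorithm)
      )))
    } else if (!identical(tolower(e$checksum), actual)) {
      findings <- c(findings, list(.finding(
        "error", "CHECKSUM_MISMATCH",
        sprintf(
          "'%s': expected %s digest %s, actual %s",
          e$uri, e$checksum_algorithm, tolower(e$checksum), actual
        )
      )))
    }
  }
  for (r in container$relations) {
    missing <- setdiff(c(r$subject_uri, r$object_uri), entry_uris)
    if (length(missing)) {
      findings <- c(findings, list(.finding(
        "error", "DANGLING_RELATION",
        sprintf(
          "relation '%s' references uri(s) absent from the ToC: %s",
          r$relationship, paste(missing, collapse = ", ")
        )
      )))
    }
    if (!r$relationship %in% ACS_KNOWN_RELATIONSHIPS) {
      findings <- c(findings, list(.finding(
        "warning", "UNKNOWN_RELATIONSHIP",
        sprintf("relationship term '%s' is not in the known vocabulary", r$relationship)
      )))
    }
  }
  if (is.null(container$version) || !nzchar(container$version %||% "")) {
    findings <- c(findings, list(.finding(
      "warning", "MISSING_VERSION", "ToC has no version attribute"
    )))
  }
  if (length(findings)) do.call(rbind, findings) else .finding("error", "x", "y")[0, ]
}

# ---------------------------------------------------------------- graph

#' Relation graph of a container
#'
#' @param container an [acs_container()].
#' @return list with `nodes` (entry uris) and `edges` (data frame
#'   `subject`, `object`, `relationship`); an edge subject -> object means
#'   the subject was produced from (or describes) the object.
#' @export
acs_relation_graph <- function(container) {
  stopifnot(inherits(container, "acs_container"))
  nodes <- vapply(container$entries, `[[`, "", "uri")
  edges <- if (length(container$relations)) {
    do.call(rbind, lapply(container$relations, function(r) {
      data.frame(
        subject = r$subject_uri, object = r$object_uri,
        relationship = r$relationship, stringsAsFactors = FALSE
      )
    }))
  } else {
    data.frame(
      subject = character(0), object = character(0),
      relationship = character(0), stringsAsFactors = FALSE
    )
  }
  list(nodes = nodes, edges = edges)
}

#' All files derived (transitively) from a member
#'
#' Follows relation edges backwards: a file whose relation chain reaches
#' `uri` is counted as derived from it.
#'
#' @param container an [acs_container()].
#' @param uri the ancestor member uri.
#' @return character vector of uris (excluding `uri` itself).
#' @export
acs_derived_from <- function(container, uri) {
  g <- acs_relation_graph(container)
  out <- character(0)
  frontier <- uri
  while (length(frontier)) {
    nxt <- unique(g$edges$subject[g$edges$object %in% frontier])
    nxt <- setdiff(nxt, c(out, uri))
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}
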