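# Minimal deterministic ZIP writer (and a reader shim).
#
# Containers are written with stored (uncompressed) entries, zeroed DOS
# timestamps and no extra fields, so packing the same members always
# yields byte-identical archives while remaining openable by any ZIP
# tool.  Reading goes through utils::unzip, which also accepts deflated
# entries produced by other tools.

.u16 <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))
.u32 <- function(x) {
  as.raw(c(
    x %% 256, (x %/% 256) %% 256,
    (x %/% 65536) %% 256, (x %/% 16777216) %% 256
  ))
}

# DOS date 0x0021 = 1980-01-01, the earliest representable date
.ZIP_DOSTIME <- .u16(0)
.ZIP_DOSDATE <- .u16(33)

#' Build a ZIP archive from named raw members
#'
#' @param members named list of raw vectors; names are archive paths.
#' @return raw vector of archive bytes (stored entries, fixed metadata).
#' @export
zip_build <- function(members) {
  stopifnot(is.list(members), !is.null(names(members)))
  locals <- list()
  centrals <- list()
  offset <- 0
  for (i in seq_along(members)) {
    name <- names(members)[i]
    data <- members[[i]]
    stopifnot(is.raw(data))
    nameraw <- charToRaw(name)
    crc <- crc32(data)
    n <- length(data)
    common <- c(
      .u16(20), # version needed
      .u16(0), # flags
      .u16(0), # method: stored
      .ZIP_DOSTIME, .ZIP_DOSDATE,
      .u32(crc), .u32(n), .u32(n),
      .u16(length(nameraw)), .u16(0) # name len, extra len
    )
    locals[[i]] <- c(.u32(67324752), common, nameraw, data) # PK\3\4
    centrals[[i]] <- c(
      .u32(33639248), # PK\1\2
      .u16(20), # version made by
      common,
      .u16(0), .u16(0), .u16(0), # comment len, disk, internal attrs
      .u32(0), # external attrs
      .u32(offset),
      nameraw
    )
    offset <- offset + length(locals[[i]])
  }
  cd <- unlist(centrals) %||% raw(0)
  if (!is.raw(cd)) cd <- raw(0)
  eocd <- c(
    .u32(101010256), # PK\5\6
    .u16(0), .u16(0),
    .u16(length(members)), .u16(length(members)),
    .u32(length(cd)), .u32(offset),
    .u16(0)
  )
  c(unlist(locals) %||% raw(0), cd, eocd)
}

#' Extract all members of a ZIP archive
#'
#' @param bytes_or_path raw vector of archive bytes, or a file path.
#' @return named list of raw vectors in archive order (directories
#'   skipped).
#' @export
zip_extract <- function(bytes_or_path) {
  path <- if (is.raw(bytes_or_path)) {
    tf <- tempfile(fileext = ".zip")
    writeBin(bytes_or_path, tf)
    tf
  } else {
    bytes_or_path
  }
  info <- tryCatch(
    utils::unzip(path, list = TRUE),
    error = function(e) cyto_error("acs_format_error", paste0("not a readable ZIP archive: ", conditionMessage(e))),
    warning = function(e) cyto_error("acs_format_error", paste0("not a readable ZIP archive: ", conditionMessage(e)))
  )
  names <- info$Name[!endsWith(info$Name, "/")]
  exdir <- tempfile("zipx")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  utils::unzip(path, exdir = exdir)
  out <- lapply(names, function(nm) {
    f <- file.path(exdir, nm)
    readBin(f, "raw", n = file.info(f)$size)
  })
  names(out) <- names
  out
}
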