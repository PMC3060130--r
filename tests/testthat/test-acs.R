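make_container <- function() {
  d <- fcs_dataset(matrix(1:20, 10, 2), channels = c("A", "B"))
  members <- list(
    "fcs/raw.fcs" = write_fcs(d),
    "fcs/pre.fcs" = write_fcs(d),
    "clr/res.csv" = charToRaw(write_clr(clr_table(matrix(1, 10, 1), "all")))
  )
  acs_container(
    members,
    relations = list(
      acs_relation("fcs/pre.fcs", "fcs/raw.fcs", "preprocessed-from"),
      acs_relation("clr/res.csv", "fcs/pre.fcs", "classification-results-of")
    )
  )
}

test_that("containers round trip through pack and unpack", {
  c1 <- make_container()
  bytes <- acs_pack(c1)
  c2 <- acs_unpack(bytes)
  expect_identical(c2$members, c1$members)
  expect_equal(length(c2$entries), length(c1$entries))
  for (i in seq_along(c1$entries)) {
    expect_identical(unclass(c2$entries[[i]]), unclass(c1$entries[[i]]))
  }
  expect_identical(
    lapply(c2$relations, unclass),
    lapply(c1$relations, unclass)
  )
  expect_identical(c2$version, c1$version)
  # packing the unpacked container reproduces the bytes
  expect_identical(acs_pack(c2), bytes)
})

test_that("a stock ZIP tool opens packed containers", {
  c1 <- make_container()
  f <- tempfile(fileext = ".acs")
  acs_pack(c1, path = f)
  listing <- utils::unzip(f, list = TRUE) # R's bundled ZIP reader
  expect_setequal(listing$Name, c("TOC.xml", names(c1$members)))
  # and the external unzip utility, when present, agrees
  if (nzchar(Sys.which("unzip"))) {
    out <- system2("unzip", c("-l", f), stdout = TRUE)
    expect_true(any(grepl("TOC.xml", out, fixed = TRUE)))
  }
})

test_that("empty containers (ToC only) are valid and round trip", {
  c1 <- acs_container()
  c2 <- acs_unpack(acs_pack(c1))
  expect_equal(length(c2$members), 0L)
  expect_equal(nrow(acs_validate(c2)), 0L)
})

test_that("a flipped byte in a checksummed member is detected exactly once", {
  c1 <- make_container()
  bytes <- acs_pack(c1)
  c2 <- acs_unpack(bytes)
  target <- "fcs/raw.fcs"
  c2$members[[target]][100] <- xor(c2$members[[target]][100], as.raw(0xFF))
  findings <- acs_validate(c2)
  bad <- findings[findings$code == "CHECKSUM_MISMATCH", ]
  expect_equal(nrow(bad), 1L)
  expect_match(bad$message, target, fixed = TRUE)
  expect_match(bad$message, "expected SHA-256")
})

test_that("every mutation class yields at least one finding", {
  base <- acs_unpack(acs_pack(make_container()))
  # remove member
  m1 <- base
  m1$members[["fcs/raw.fcs"]] <- NULL
  f1 <- acs_validate(m1)
  expect_true(any(f1$code == "MISSING_MEMBER"))
  # remove entry
  m2 <- base
  m2$entries <- m2$entries[-1]
  f2 <- acs_validate(m2)
  expect_true(any(f2$code %in% c("ORPHAN_MEMBER", "DANGLING_RELATION")))
  # corrupt byte
  m3 <- base
  m3$members[[1]][1] <- xor(m3$members[[1]][1], as.raw(1))
  expect_true(any(acs_validate(m3)$code == "CHECKSUM_MISMATCH"))
  # dangling relation
  m4 <- base
  m4$relations <- c(m4$relations, list(acs_relation("ghost.fcs", "fcs/raw.fcs", "derived-from")))
  f4 <- acs_validate(m4)
  expect_true(any(f4$code == "DANGLING_RELATION"))
  expect_match(f4$message[f4$code == "DANGLING_RELATION"], "ghost.fcs")
})

test_that("unknown relationship terms and missing versions warn", {
  c1 <- acs_container(
    list("a.txt" = charToRaw("x"), "b.txt" = charToRaw("y")),
    relations = list(acs_relation("a.txt", "b.txt", "scribbled-on"))
  )
  f <- acs_validate(c1)
  expect_equal(f$level[f$code == "UNKNOWN_RELATIONSHIP"], "warning")
  c1$version <- NULL
  expect_true(any(acs_validate(c1)$code == "MISSING_VERSION"))
})

test_that("missing ToC members fail unpack", {
  plain <- zip_build(list("data.bin" = as.raw(1:10)))
  expect_error(acs_unpack(plain), class = "acs_format_error")
})

test_that("the relation graph answers derivation queries", {
  members <- list(
    "raw.fcs" = as.raw(1), "pre.fcs" = as.raw(2), "res.csv" = as.raw(3),
    "other.fcs" = as.raw(4)
  )
  c1 <- acs_container(members, relations = list(
    acs_relation("pre.fcs", "raw.fcs", "preprocessed-from"),
    acs_relation("res.csv", "pre.fcs", "classification-results-of")
  ))
  g <- acs_relation_graph(c1)
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(acs_derived_from(c1, "raw.fcs"), c("pre.fcs", "res.csv"))
  expect_equal(acs_derived_from(c1, "other.fcs"), character(0))

  c2 <- acs_container(members)
  expect_equal(nrow(acs_relation_graph(c2)$edges), 0L)
})

test_that("opaque signature blocks are preserved round trip", {
  c1 <- acs_container(
    list("a.txt" = charToRaw("x")),
    signatures = "<sig><value alg=\"ext\">opaque-blob</value></sig>"
  )
  c2 <- acs_unpack(acs_pack(c1))
  expect_false(is.null(c2$signatures))
  expect_match(c2$signatures, "opaque-blob")
  # and survives a second round trip unchanged
  c3 <- acs_unpack(acs_pack(c2))
  expect_identical(c3$signatures, c2$signatures)
})

test_that("packing an inconsistent container is refused", {
  c1 <- acs_container(
    list("a.txt" = charToRaw("x")),
    entries = list(
      acs_entry("a.txt", checksum = sha256_hex(charToRaw("x"))),
      acs_entry("missing.txt")
    )
  )
  expect_error(acs_pack(c1), class = "acs_validation_error")
})
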