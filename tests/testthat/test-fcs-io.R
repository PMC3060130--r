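test_that("headers parse to segment offsets", {
  hdr <- paste0(
    "FCS3.1", "    ",
    sprintf("%8d", 58), sprintf("%8d", 1000),
    sprintf("%8d", 1001), sprintf("%8d", 5000),
    sprintf("%8d", 0), sprintf("%8d", 0)
  )
  off <- parse_fcs_header(charToRaw(hdr))
  expect_equal(off$version_string, "FCS3.1")
  expect_equal(off$text_begin, 58)
  expect_equal(off$text_end, 1000)
  expect_equal(off$data_begin, 1001)
  expect_equal(off$data_end, 5000)
  expect_equal(off$analysis_begin, 0)

  expect_error(parse_fcs_header(charToRaw("NOTFCS")), class = "fcs_format_error")
  bad <- charToRaw(paste0("FCS3.1", "    ", "      xx", strrep(" ", 40)))
  expect_error(parse_fcs_header(bad), class = "fcs_format_error")
})

test_that("written headers parse back to identical offsets", {
  set.seed(1)
  d <- random_dataset(100, 3)
  b <- write_fcs(d)
  off <- parse_fcs_header(b)
  expect_equal(off$version_string, "FCS3.1")
  kw <- read_fcs(b)$keywords
  expect_equal(as.numeric(kw[["$BEGINDATA"]]), off$data_begin)
  expect_equal(as.numeric(kw[["$ENDDATA"]]), off$data_end)
})

test_that("float event data survives a write/read round trip", {
  ev <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE)
  d <- fcs_dataset(ev, channels = c("FSC-A", "SSC-A"))
  got <- read_fcs(write_fcs(d, datatype = "F"))
  expect_equal(unname(got$events), ev)
  expect_equal(got$parameters$name, c("FSC-A", "SSC-A"))
  expect_equal(unname(got$keywords[["$TOT"]]), "3")
})

test_that("integer data is masked to the bits implied by $PnR", {
  # stored 0xFFFF with $PnR 1024 must decode as 0xFFFF & 0x03FF = 1023
  d <- fcs_dataset(matrix(2^16 - 1, 1, 1), channels = "CH1", ranges = 1024, bits = 16L)
  b <- write_fcs(d, datatype = "I")
  # the writer clips to [0, 2^PnB-1]; patch the stored 16-bit word to 0xFFFF
  off <- parse_fcs_header(b)
  kw <- read_fcs(b)$keywords
  db <- as.integer(kw[["$BEGINDATA"]])
  b[(db + 1):(db + 2)] <- as.raw(c(0xFF, 0xFF))
  expect_equal(unname(read_fcs(b)$events[1, 1]), 1023)
})

test_that("round trips are exact for I and D and float32-close for F", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(c(1, 7, 100, 2000), 1)
    p <- sample(1:24, 1)
    d <- random_dataset(n, p, dist = sample(c("unif", "lnorm"), 1))
    expect_equal(unname(read_fcs(write_fcs(d, datatype = "D"))$events), unname(d$events))
    got_f <- read_fcs(write_fcs(d, datatype = "F"))$events
    expect_lt(max(abs(got_f - d$events) / pmax(abs(d$events), 1)), 1e-6)
    di <- d
    di$events <- round(di$events) %% 262144
    expect_equal(
      unname(read_fcs(write_fcs(di, datatype = "I"))$events),
      unname(di$events)
    )
  }
})

test_that("big- and little-endian encodings decode identically", {
  set.seed(7)
  for (i in 1:10) {
    d <- random_dataset(sample(1:500, 1), sample(1:8, 1))
    little <- write_fcs(d)
    big <- to_big_endian_fcs(little)
    expect_equal(read_fcs(big)$events, read_fcs(little)$events)
  }
})

test_that("FCS 3.1 metadata keywords are preserved on re-read", {
  d <- fcs_dataset(matrix(1:10, 5, 2), channels = c("A", "B"), keywords = c(
    "$ORIGINALITY" = "Original", "$PLATEID" = "P1",
    "$WELLID" = "A01", "$VOL" = "50000"
  ))
  kw <- read_fcs(write_fcs(d))$keywords
  expect_equal(unname(kw[["$ORIGINALITY"]]), "Original")
  expect_equal(unname(kw[["$PLATEID"]]), "P1")
  expect_equal(unname(kw[["$WELLID"]]), "A01")
  expect_equal(unname(kw[["$VOL"]]), "50000")
})

test_that("empty datasets round trip as 0-event files", {
  d <- fcs_dataset(matrix(numeric(0), 0, 2), channels = c("A", "B"))
  got <- read_fcs(write_fcs(d))
  expect_equal(dim(got$events), c(0L, 2L))
  expect_equal(unname(got$keywords[["$TOT"]]), "0")
})

test_that("older FCS versions are accepted on read", {
  d <- random_dataset(20, 2)
  for (v in c("FCS2.0", "FCS3.0")) {
    b <- write_fcs(d)
    b[1:6] <- charToRaw(v)
    got <- read_fcs(b)
    expect_equal(got$version, v)
    expect_equal(dim(got$events), c(20L, 2L))
  }
})

test_that("multi-dataset files are read by explicit index", {
  d1 <- fcs_dataset(matrix(1:4, 2, 2), channels = c("A", "B"))
  d2 <- fcs_dataset(matrix(11:16, 3, 2), channels = c("A", "B"))
  b2 <- write_fcs(d2)
  b1 <- write_fcs(d1, nextdata = length(write_fcs(d1)))
  chain <- c(b1, b2)
  expect_equal(unname(read_fcs(chain)$events), unname(d1$events))
  expect_equal(unname(read_fcs(chain, dataset = 2)$events), unname(d2$events))
  expect_error(read_fcs(chain, dataset = 3), class = "fcs_format_error")
})

test_that("unsupported modes, datatypes and truncation are rejected", {
  d <- random_dataset(10, 2)
  b <- write_fcs(d)
  txt_begin <- as.integer(rawToChar(b[11:18]))
  txt_end <- as.integer(rawToChar(b[19:26]))
  text <- rawToChar(b[(txt_begin + 1):(txt_end + 1)])

  swap <- function(bytes, from, to) {
    stopifnot(nchar(from) == nchar(to))
    t2 <- sub(from, to, text, fixed = TRUE)
    bytes[(txt_begin + 1):(txt_end + 1)] <- charToRaw(t2)
    bytes
  }
  expect_error(read_fcs(swap(b, "$MODE/L", "$MODE/C")), class = "fcs_unsupported_mode")
  expect_error(read_fcs(swap(b, "$DATATYPE/F", "$DATATYPE/A")), class = "fcs_unsupported_datatype")
  expect_error(read_fcs(b[1:(length(b) - 10)]),
    regexp = "bytes", class = "fcs_truncation_error"
  )
})
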