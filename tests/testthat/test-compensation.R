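random_spillover <- function(k, max_off = 0.5) {
  S <- matrix(runif(k * k, 0, max_off), k, k)
  diag(S) <- 1
  spillover_matrix(S, paste0("FL", seq_len(k)))
}

test_that("$SPILLOVER keyword values parse to the stated layout", {
  sp <- parse_spillover_keyword("2,FL1,FL2,1,0.1,0.05,1")
  expect_equal(sp$detectors, c("FL1", "FL2"))
  expect_equal(unname(sp$S), matrix(c(1, 0.1, 0.05, 1), 2, byrow = TRUE))

  one <- parse_spillover_keyword("1,FL1,1")
  expect_equal(unname(one$S), matrix(1, 1, 1))

  expect_error(parse_spillover_keyword("2,FL1,FL2,1,0.1,0.05"),
    regexp = "7 tokens", class = "spillover_format_error"
  )
  expect_error(parse_spillover_keyword("2,FL1,FL2,1,0.1,x,1"),
    regexp = "token", class = "spillover_format_error"
  )
})

test_that("serialize and parse are mutually inverse for random matrices", {
  set.seed(21)
  for (i in 1:200) {
    sp <- random_spillover(sample(1:6, 1))
    v <- serialize_spillover_keyword(sp)
    back <- parse_spillover_keyword(v)
    expect_equal(back$detectors, sp$detectors)
    expect_equal(back$S, sp$S, tolerance = 1e-14)
    expect_identical(serialize_spillover_keyword(back), v)
  }
})

test_that("compensation inverts the forward spillover model", {
  # identity spillover: no-op
  sp1 <- spillover_matrix(diag(2), c("FL1", "FL2"))
  X <- matrix(runif(20), 10, 2, dimnames = list(NULL, c("FL1", "FL2")))
  expect_equal(compensate(X, sp1), X)

  # worked 2x2 example: true [100, 10] observed as [100.5, 20]
  sp <- parse_spillover_keyword("2,FL1,FL2,1,0.1,0.05,1")
  true <- matrix(c(100, 10), 1, dimnames = list(NULL, c("FL1", "FL2")))
  observed <- apply_spillover(true, sp)
  expect_equal(unname(observed), matrix(c(100.5, 20), 1))
  expect_lt(max(abs(compensate(observed, sp) - true)), 1e-9)
})

test_that("random spillovers are recovered within 1e-8 relative", {
  set.seed(22)
  for (i in 1:50) {
    k <- sample(2:8, 1)
    sp <- random_spillover(k)
    X <- matrix(rlnorm(50 * k, 4, 1), 50, k, dimnames = list(NULL, sp$detectors))
    back <- compensate(apply_spillover(X, sp), sp)
    expect_lt(max(abs(back - X) / pmax(abs(X), 1)), 1e-8)
  }
})

test_that("compensation commutes with event-row permutation", {
  set.seed(23)
  sp <- random_spillover(4)
  X <- matrix(rlnorm(200), 50, 4, dimnames = list(NULL, sp$detectors))
  perm <- sample(50)
  expect_equal(compensate(X, sp)[perm, ], compensate(X[perm, ], sp))
})

test_that("singular and mismatched spillovers fail informatively", {
  S <- matrix(c(1, 1, 1, 1), 2, 2) # rank 1
  sp <- suppressWarnings(spillover_matrix(S, c("FL1", "FL2")))
  X <- matrix(1, 2, 2, dimnames = list(NULL, c("FL1", "FL2")))
  expect_error(compensate(X, sp), class = "spillover_singular_error")

  sp2 <- spillover_matrix(diag(2), c("FL1", "FLX"))
  expect_error(compensate(X, sp2),
    regexp = "FLX", class = "spillover_mapping_error"
  )
})

test_that("non-unit diagonals are normalized with a warning", {
  expect_warning(
    sp <- spillover_matrix(matrix(c(2, 0.2, 0.1, 4), 2, byrow = TRUE), c("A", "B")),
    "normaliz"
  )
  expect_equal(diag(sp$S), c(A = 1, B = 1))
  expect_equal(sp$S[1, 2], 0.1) # 0.2 / 2
})

test_that("scatter columns are untouched by dataset compensation", {
  sp <- parse_spillover_keyword("2,FL1,FL2,1,0.2,0.1,1")
  ev <- cbind(
    `FSC-A` = runif(5, 1e4, 1e5),
    FL1 = runif(5, 0, 1e3), FL2 = runif(5, 0, 1e3)
  )
  d <- fcs_dataset(ev, keywords = c("$SPILLOVER" = serialize_spillover_keyword(sp)))
  out <- compensate_dataset(d)
  expect_equal(out$events[, "FSC-A"], ev[, "FSC-A"])
  expect_false(isTRUE(all.equal(out$events[, "FL1"], ev[, "FL1"])))
})
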