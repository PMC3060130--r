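xy_dataset <- function(pts) {
  fcs_dataset(matrix(pts, ncol = 2, byrow = TRUE, dimnames = list(NULL, c("x", "y"))))
}

test_that("rectangle gates are min-inclusive and max-exclusive", {
  s <- gating_strategy(list(rectangle_gate("r", list("x", "y"), c(0, 0), c(1, 1))))
  d <- xy_dataset(c(0.5, 0.5, 2, 2, 0, 0, 1, 1))
  expect_equal(unname(evaluate_gate(s, "r", d)), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("one-sided rectangle bounds act as half-open ranges", {
  s <- gating_strategy(list(rectangle_gate("r", list("x"), 10, Inf)))
  d <- xy_dataset(c(5, 0, 10, 0, 1e9, 0))
  expect_equal(unname(evaluate_gate(s, "r", d)), c(FALSE, TRUE, TRUE))
})

test_that("polygon membership equals the crossing-number oracle", {
  set.seed(31)
  for (rep in 1:50) {
    verts <- random_simple_polygon(sample(3:12, 1))
    g <- polygon_gate("p", list("x", "y"), verts)
    s <- gating_strategy(list(g))
    pts <- cbind(runif(1000, -1.2, 1.2), runif(1000, -1.2, 1.2))
    d <- fcs_dataset(pts, channels = c("x", "y"))
    got <- evaluate_gate(s, "p", d)
    want <- vapply(
      seq_len(nrow(pts)),
      function(i) oracle_point_in_polygon(pts[i, 1], pts[i, 2], verts),
      logical(1)
    )
    expect_identical(unname(got), want)
  }
})

test_that("polygon boundary points (vertices and edges) are inclusive", {
  verts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  s <- gating_strategy(list(polygon_gate("p", list("x", "y"), verts)))
  d <- xy_dataset(c(
    0, 0, # vertex
    0.5, 0, # on edge
    1, 0.5, # on edge
    0.5, 0.5, # interior
    1.0001, 0.5 # outside
  ))
  expect_equal(unname(evaluate_gate(s, "p", d)), c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("ellipsoid boundaries are inclusive at exactly D^2", {
  s <- gating_strategy(list(ellipsoid_gate("e", list("x", "y"), c(0, 0), diag(2), 1)))
  d <- xy_dataset(c(1, 0, 1.01, 0, 0, 0))
  expect_equal(unname(evaluate_gate(s, "e", d)), c(TRUE, FALSE, TRUE))
})

test_that("degenerate gates are rejected at construction", {
  expect_error(
    polygon_gate("p", list("x", "y"), rbind(c(0, 0), c(1, 1), c(2, 2))),
    regexp = "zero area", class = "gate_error"
  )
  expect_error(
    rectangle_gate("r", list("x"), 1, 1),
    class = "gate_error"
  )
  expect_error(
    ellipsoid_gate("e", list("x", "y"), c(0, 0), matrix(c(1, 2, 2, 1), 2), 1),
    class = "gate_error"
  )
  expect_error(
    boolean_gate("b", "NOT", c("a", "b")),
    class = "gate_error"
  )
})

test_that("child populations are clipped by their parents", {
  # child region strictly contains the parent region; hierarchy still clips
  parent <- rectangle_gate("parent", list("x", "y"), c(0.4, 0.4), c(0.6, 0.6))
  child <- rectangle_gate("child", list("x", "y"), c(0, 0), c(1, 1), parent_id = "parent")
  s <- gating_strategy(list(parent, child))
  set.seed(32)
  d <- fcs_dataset(matrix(runif(2000), 1000, 2, dimnames = list(NULL, c("x", "y"))))
  res <- evaluate_all(s, d)
  expect_identical(res$membership$child, res$membership$parent)
  st <- res$stats
  expect_equal(st$count[st$id == "child"], st$count[st$id == "parent"])
  expect_equal(st$pct_of_parent[st$id == "child"], 100)
})

test_that("NOT gates complement their operand", {
  g <- rectangle_gate("g", list("x"), 0.5, Inf)
  ng <- boolean_gate("not_g", "NOT", "g")
  s <- gating_strategy(list(g, ng))
  set.seed(33)
  d <- fcs_dataset(matrix(runif(200), 100, 2, dimnames = list(NULL, c("x", "y"))))
  res <- evaluate_all(s, d)
  expect_equal(sum(res$membership$not_g), 100 - sum(res$membership$g))
  expect_identical(res$membership$not_g, !res$membership$g)
})

test_that("Boolean gates obey De Morgan's laws on random strategies", {
  set.seed(34)
  for (rep in 1:20) {
    a <- rectangle_gate("a", list("x", "y"), runif(2, 0, 0.4), runif(2, 0.5, 1))
    b <- polygon_gate("b", list("x", "y"), random_simple_polygon(6) / 2 + 0.5)
    s <- gating_strategy(list(
      a, b,
      boolean_gate("lhs", "NOT", list(list(ref = "ab"))),
      boolean_gate("ab", "AND", c("a", "b")),
      boolean_gate("rhs", "OR", list(
        list(ref = "a", complement = TRUE),
        list(ref = "b", complement = TRUE)
      ))
    ))
    d <- fcs_dataset(matrix(runif(600), 300, 2, dimnames = list(NULL, c("x", "y"))))
    res <- evaluate_all(s, d)
    expect_identical(res$membership$lhs, res$membership$rhs)
  }
})

test_that("hierarchy membership is monotone along parent chains", {
  set.seed(35)
  for (rep in 1:10) {
    depth <- sample(2:4, 1)
    gates <- list()
    for (lev in seq_len(depth)) {
      gates[[lev]] <- rectangle_gate(
        paste0("g", lev), list("x", "y"),
        runif(2, 0, 0.5), runif(2, 0.5, 1),
        parent_id = if (lev > 1) paste0("g", lev - 1)
      )
    }
    s <- gating_strategy(gates)
    d <- fcs_dataset(matrix(runif(1000), 500, 2, dimnames = list(NULL, c("x", "y"))))
    res <- evaluate_all(s, d)
    for (lev in 2:depth) {
      child <- res$membership[[paste0("g", lev)]]
      parent <- res$membership[[paste0("g", lev - 1)]]
      expect_true(all(!child | parent))
    }
  }
})

test_that("rectangle evaluation agrees between data and display space", {
  # bounds defined in flog display space, evaluated by inverse-transforming;
  # must match explicit transformation of the events
  tr <- transform_scale("flog", T = 10000, M = 4, id = "lg")
  g <- rectangle_gate("r", list(gate_dimension("x", transform_ref = "lg")), 0.25, 0.75)
  s <- gating_strategy(list(g), transforms = list(tr))
  set.seed(36)
  x <- 10^runif(500, 0, 4)
  d <- fcs_dataset(cbind(x = x, y = 0))
  got <- evaluate_gate(s, "r", d)
  disp <- apply_transform(tr, x)
  expect_identical(unname(got), disp >= 0.25 & disp < 0.75)
})

test_that("gate declaration order never changes results", {
  a <- rectangle_gate("a", list("x"), 0.2, 0.8)
  b <- rectangle_gate("b", list("y"), 0.3, 0.9, parent_id = "a")
  n <- boolean_gate("n", "NOT", "b")
  set.seed(37)
  d <- fcs_dataset(matrix(runif(400), 200, 2, dimnames = list(NULL, c("x", "y"))))
  r1 <- evaluate_all(gating_strategy(list(a, b, n)), d)
  r2 <- evaluate_all(gating_strategy(list(n, b, a)), d)
  for (id in c("a", "b", "n")) {
    expect_identical(r1$membership[[id]], r2$membership[[id]])
  }
})

test_that("evaluation errors name the problem precisely", {
  g <- rectangle_gate("r", list("missing-channel"), 0, 1)
  s <- gating_strategy(list(g))
  d <- xy_dataset(c(1, 2))
  expect_error(evaluate_gate(s, "r", d),
    regexp = "missing-channel.*x, y", class = "channel_error"
  )
  s2 <- gating_strategy(list(
    boolean_gate("b1", "NOT", "b2"),
    boolean_gate("b2", "NOT", "b1")
  ))
  expect_error(evaluate_gate(s2, "b1", d),
    regexp = "b1 -> b2 -> b1", class = "cycle_error"
  )
  expect_error(
    gating_strategy(list(rectangle_gate("r", list("x"), 0, 1, parent_id = "ghost"))),
    regexp = "ghost", class = "reference_error"
  )
})

test_that("gating strategies round trip through XML", {
  # 6 gates in a 3-level hierarchy + 2 transforms + 1 spectrum matrix
  lg <- transform_scale("flog", T = 262144, M = 4.5, id = "lg")
  lgc <- transform_scale("logicle", T = 262144, M = 4.5, W = 0.5, A = 0.1, id = "lgc")
  sm <- spillover_matrix(matrix(c(1, 0.1, 0.05, 1), 2, byrow = TRUE), c("FL1", "FL2"), id = "sm")
  gates <- list(
    rectangle_gate("live", list("FSC-A", "SSC-A"), c(1e4, 5e3), c(Inf, Inf)),
    rectangle_gate(
      "fl1hi",
      list(gate_dimension("FL1", transform_ref = "lg", compensation_ref = "sm")),
      0.5, Inf,
      parent_id = "live"
    ),
    polygon_gate("poly", list(
      gate_dimension("FL1", transform_ref = "lgc"),
      gate_dimension("FL2", transform_ref = "lg")
    ), rbind(c(0.1, 0.1), c(0.9, 0.15), c(0.5, 0.95)), parent_id = "live"),
    ellipsoid_gate("ell", list("FL1", "FL2"),
      mean = c(1000, 2000),
      covariance = matrix(c(4e4, 1e3, 1e3, 9e4), 2), distance_square = 9.21,
      parent_id = "fl1hi"
    ),
    boolean_gate("either", "OR", c("poly", "ell")),
    boolean_gate("neither", "NOT", list(list(ref = "either")))
  )
  s <- gating_strategy(gates, list(lg, lgc), list(sm))
  s2 <- read_gatingml(write_gatingml(s))
  expect_identical(names(s2$gates), names(s$gates))
  for (id in names(s$gates)) {
    g1 <- s$gates[[id]]
    g2 <- s2$gates[[id]]
    expect_identical(class(g2), class(g1))
    expect_identical(g2$parent_id, g1$parent_id)
    for (fld in c("mins", "maxs", "vertices", "mean", "covariance", "distance_square")) {
      if (!is.null(g1[[fld]])) expect_equal(g2[[fld]], g1[[fld]], tolerance = 1e-12)
    }
    if (!is.null(g1$dims)) {
      expect_identical(
        lapply(g2$dims, unclass),
        lapply(g1$dims, unclass)
      )
    }
    if (inherits(g1, "boolean_gate")) expect_identical(g2$operands, g1$operands)
  }
  expect_equal(s2$transforms$lgc$W, 0.5)
  expect_equal(s2$spectrum_matrices$sm$S, s$spectrum_matrices$sm$S, tolerance = 1e-14)

  # one-rectangle strategy round trip
  s3 <- gating_strategy(list(rectangle_gate("r", list("FSC-A", "SSC-A"), c(0, 0), c(1, 1))))
  s4 <- read_gatingml(write_gatingml(s3))
  expect_equal(s4$gates$r$mins, s3$gates$r$mins)

  # evaluation is unchanged by the round trip
  set.seed(38)
  d <- fcs_dataset(
    matrix(rlnorm(300 * 4, 6, 2), 300, 4,
      dimnames = list(NULL, c("FSC-A", "SSC-A", "FL1", "FL2"))
    )
  )
  r1 <- evaluate_all(s, d)
  r2 <- evaluate_all(s2, d)
  for (id in names(s$gates)) expect_identical(r1$membership[[id]], r2$membership[[id]])
})

test_that("unsupported XML features fail with named errors", {
  xml <- paste0(
    '<gating:Gating-ML xmlns:gating="http://www.isac-net.org/std/Gating-ML/v2.0/gating">',
    '<gating:QuadrantGate gating:id="q"/></gating:Gating-ML>'
  )
  expect_error(read_gatingml(xml),
    regexp = "QuadrantGate", class = "gatingml_unsupported_feature"
  )
  expect_error(read_gatingml("<foo xmlns=\"http://example.org/ns\"/>"),
    class = "gatingml_format_error"
  )
})

test_that("the 2008 namespace is accepted where shapes coincide", {
  xml <- paste0(
    '<gating:Gating-ML xmlns:gating="http://www.isac-net.org/std/Gating-ML/v1.5/gating" ',
    'xmlns:data-type="http://www.isac-net.org/std/Gating-ML/v1.5/datatypes">',
    '<gating:RectangleGate gating:id="r">',
    '<gating:dimension gating:min="0" gating:max="100">',
    '<data-type:fcs-dimension data-type:name="FSC-A"/>',
    "</gating:dimension></gating:RectangleGate></gating:Gating-ML>"
  )
  s <- read_gatingml(xml)
  expect_equal(names(s$gates), "r")
  expect_equal(s$gates$r$maxs, 100)
})
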