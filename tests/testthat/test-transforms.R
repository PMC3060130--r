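all_kinds <- c("flin", "flog", "fasinh", "logicle", "hyperlog")

random_transform <- function(kind) {
  T <- 10^runif(1, 2, 6)
  M <- runif(1, 3, 5.5)
  W <- runif(1, 0.05, M / 2 - 0.01)
  A <- runif(1, 0, 1)
  switch(kind,
    flin = transform_scale("flin", T = T, A = runif(1, 0, T / 10)),
    flog = transform_scale("flog", T = T, M = M),
    fasinh = transform_scale("fasinh", T = T, M = M, A = A),
    logicle = transform_scale("logicle", T = T, M = M, W = W, A = runif(1, -W / 2, 1)),
    hyperlog = transform_scale("hyperlog", T = T, M = M, W = W, A = A)
  )
}

test_that("closed-form transform values match their definitions", {
  fl <- transform_scale("flin", T = 1000, A = 0)
  expect_equal(apply_transform(fl, c(1000, 0)), c(1, 0))
  expect_equal(invert_transform(transform_scale("flin", T = 100, A = 0), 0.5), 50)

  fa <- transform_scale("fasinh", T = 1000, M = 4, A = 1)
  expect_equal(apply_transform(fa, 0), 1 / (4 + 1) * 1) # A/(M+A) = 0.2
  expect_equal(apply_transform(fa, 0), 0.2)
  expect_equal(apply_transform(fa, 1000), 1)

  lgn <- transform_scale("flog", T = 10000, M = 4)
  expect_equal(invert_transform(lgn, 0), 1) # T * 10^-M
  expect_warning(out <- apply_transform(lgn, c(-1, 0, 10)), "NaN")
  expect_true(all(is.nan(out[1:2])))
})

test_that("every kind maps T to 1 within 1e-12", {
  set.seed(11)
  for (kind in all_kinds) {
    for (i in 1:20) {
      tr <- random_transform(kind)
      expect_lt(abs(apply_transform(tr, tr$T) - 1), 1e-12)
    }
  }
})

test_that("transforms are strictly increasing on their domain", {
  set.seed(12)
  for (kind in all_kinds) {
    tr <- random_transform(kind)
    x <- sort(runif(200, if (kind == "flog") 1e-6 else -tr$T / 2, tr$T * 2))
    y <- apply_transform(tr, x)
    expect_true(all(diff(y) > 0), info = kind)
  }
})

test_that("forward and inverse round-trip within 1e-9", {
  set.seed(13)
  cases_per_kind <- 400 # 2000 round-trip cases across the five kinds
  for (kind in all_kinds) {
    for (i in 1:20) {
      tr <- random_transform(kind)
      y <- runif(cases_per_kind / 20, -0.2, 1.2)
      expect_lt(max(abs(apply_transform(tr, invert_transform(tr, y)) - y)), 1e-9)
    }
  }
})

test_that("logicle forward/inverse agree to 1e-9 over the display range", {
  tr <- transform_scale("logicle", T = 10000, W = 0.5, M = 4.5, A = 0)
  y <- seq(0, 1, length.out = 1000)
  expect_lt(max(abs(apply_transform(tr, invert_transform(tr, y)) - y)), 1e-9)
})

test_that("logicle with W=0, A=0 approaches flog away from zero", {
  # at the lower cutoff x = T*10^(-M+1) the residual asinh curvature is
  # ~0.00993/(M ln 10), which stays under 1e-3 for M >= 4.5 decades
  for (M in c(4.5, 5, 5.5)) {
    T <- 10000
    lgc <- transform_scale("logicle", T = T, M = M, W = 0, A = 0)
    flg <- transform_scale("flog", T = T, M = M)
    x <- 10^seq(log10(T) - M + 1, log10(T), length.out = 200)
    expect_lt(max(abs(apply_transform(lgc, x) - apply_transform(flg, x))), 1e-3)
  }
})

test_that("invalid parameter combinations are rejected", {
  expect_error(transform_scale("flog", T = -1), class = "transform_error")
  expect_error(transform_scale("logicle", T = 100, M = 4, W = 3), class = "transform_error")
  expect_error(transform_scale("logicle", T = 100, M = 4, W = 0.5, A = -1), class = "transform_error")
  expect_error(transform_scale("hyperlog", T = 100, M = 4, W = 0), class = "transform_error")
})
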