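# Parametrized display-scale transformations used by gate definitions.
#
# All five kinds share the harmonized (T, M, W, A) parametrization:
#   T  top-of-scale data value (> 0); every transform maps T to 1
#   M  number of decades covered by the display (> 0)
#   W  linearization width in decades near zero (logicle/hyperlog)
#   A  additional negative-display-range decades (or the offset for flin)
#
# Closed forms:
#   flin(x)   = (x + A) / (T + A)
#   flog(x)   = (1/M) log10(x / T) + 1
#   fasinh(x) = (asinh(x sinh(M ln 10) / T) + A ln 10) / ((M + A) ln 10)
# logicle is the inverse of a biexponential B(y) = a e^{by} - c e^{-dy} - f
# and hyperlog the inverse of EH(y) = a e^{by} + c y - f; both are computed
# by safeguarded Newton/bisection root finding on precomputed constants.

LN10 <- log(10)

#' Construct a scale transformation
#'
#' @param kind one of `"flin"`, `"flog"`, `"fasinh"`, `"logicle"`,
#'   `"hyperlog"`.
#' @param T top-of-scale data value, > 0.
#' @param M decades (> 0; ignored for `flin`).
#' @param W linearization width in decades (logicle/hyperlog; `0 <= W <=
#'   M/2`, strictly positive for hyperlog).
#' @param A additional negative decades (`A >= -W` for logicle), or the
#'   offset added to the data value for `flin`.
#' @param id identifier used when the transform is referenced from gates.
#' @return object of class `cyto_transform`.
#' @export
#' @examples
#' lg <- transform_scale("logicle", T = 10000, M = 4.5, W = 0.5)
#' apply_transform(lg, c(0, 100, 10000))
transform_scale <- function(kind = c("flin", "flog", "fasinh", "logicle", "hyperlog"),
                            T = 262144, M = 4.5, W = 0, A = 0, id = kind) {
  kind <- match.arg(kind)
  if (!is.finite(T) || T <= 0) cyto_error("transform_error", "T must be > 0")
  if (kind != "flin" && (!is.finite(M) || M <= 0)) {
    cyto_error("transform_error", "M must be > 0")
  }
  if (kind %in% c("logicle", "hyperlog")) {
    if (W < 0 || W > M / 2) cyto_error("transform_error", "need 0 <= W <= M/2")
    if (kind == "hyperlog" && W == 0) {
      cyto_error("transform_error", "hyperlog requires W > 0")
    }
    if (kind == "logicle" && A < -W) cyto_error("transform_error", "logicle requires A >= -W")
  }
  if (kind == "flin" && T + A <= 0) cyto_error("transform_error", "flin requires T + A > 0")
  obj <- structure(
    list(id = id, kind = kind, T = T, M = M, W = W, A = A),
    class = "cyto_transform"
  )
  obj$consts <- switch(kind,
    logicle = .logicle_constants(T, M, W, A),
    hyperlog = .hyperlog_constants(T, M, W, A),
    NULL
  )
  obj
}

#' @export
print.cyto_transform <- function(x, ...) {
  cat(sprintf(
    "<cyto_transform %s '%s'> T=%g M=%g W=%g A=%g\n",
    x$kind, x$id, x$T, x$M, x$W, x$A
  ))
  invisible(x)
}

# d solves 2 (ln d - ln b) + w (d + b) = 0 on (0, b]; d = b when w = 0.
.logicle_constants <- function(T, M, W, A) {
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b <- (M + A) * LN10
  d <- if (w == 0) {
    b
  } else {
    stats::uniroot(
      function(d) 2 * (log(d) - log(b)) + w * (d + b),
      lower = b * 1e-9, upper = b, tol = 1e-14
    )$root
  }
  c_a <- exp(x0 * (b + d))
  mf_a <- exp(b * x1) - c_a * exp(-d * x1)
  a <- T / (exp(b) - mf_a - c_a * exp(-d))
  list(a = a, b = b, c = c_a * a, d = d, f = mf_a * a)
}

.hyperlog_constants <- function(T, M, W, A) {
  w <- W / (M + A)
  x2 <- A / (M + A)
  x1 <- x2 + w
  x0 <- x2 + 2 * w
  b <- (M + A) * LN10
  c_a <- exp(b * x0) / w
  f_a <- exp(b * x1) + c_a * x1
  a <- T / (exp(b) + c_a - f_a)
  list(a = a, b = b, c = c_a * a, f = f_a * a)
}

# The data-space value displayed at position y (the function whose inverse
# is the forward transform).
.inverse_fun <- function(t) {
  k <- t$consts
  switch(t$kind,
    flin = function(y) y * (t$T + t$A) - t$A,
    flog = function(y) t$T * 10^(t$M * (y - 1)),
    fasinh = function(y) {
      sinh((t$M + t$A) * LN10 * y - t$A * LN10) * t$T / sinh(t$M * LN10)
    },
    logicle = function(y) k$a * exp(k$b * y) - k$c * exp(-k$d * y) - k$f,
    hyperlog = function(y) k$a * exp(k$b * y) + k$c * y - k$f
  )
}

.inverse_deriv <- function(t) {
  k <- t$consts
  switch(t$kind,
    logicle = function(y) k$a * k$b * exp(k$b * y) + k$c * k$d * exp(-k$d * y),
    hyperlog = function(y) k$a * k$b * exp(k$b * y) + k$c
  )
}

# Vectorized safeguarded Newton/bisection inversion of a strictly
# increasing smooth function g: solves g(y) = x per element.
.invert_increasing <- function(g, gprime, x, lo0 = -2, hi0 = 3) {
  n <- length(x)
  lo <- rep(lo0, n)
  hi <- rep(hi0, n)
  for (i in 1:64) { # expand brackets where needed
    bad_hi <- g(hi) < x
    bad_lo <- g(lo) > x
    if (!any(bad_hi) && !any(bad_lo)) break
    hi[bad_hi] <- hi[bad_hi] + 1
    lo[bad_lo] <- lo[bad_lo] - 1
  }
  y <- (lo + hi) / 2
  for (i in 1:100) {
    gy <- g(y)
    hi <- ifelse(gy >= x, y, hi)
    lo <- ifelse(gy < x, y, lo)
    step <- (gy - x) / gprime(y)
    yn <- y - step
    # fall back to bisection where Newton leaves the bracket
    outside <- !is.finite(yn) | yn <= lo | yn >= hi
    yn[outside] <- (lo[outside] + hi[outside]) / 2
    if (max(abs(yn - y)) < 1e-14) {
      y <- yn
      break
    }
    y <- yn
  }
  y
}

#' Apply a transformation (data space to display space)
#'
#' @param t a [transform_scale()] object.
#' @param x numeric vector of channel (data-space) values.
#' @return numeric vector of display-space values; `f(T) = 1` for every
#'   kind.  `flog` of non-positive values yields `NaN` with a warning.
#' @export
apply_transform <- function(t, x) {
  stopifnot(inherits(t, "cyto_transform"))
  x <- as.numeric(x)
  switch(t$kind,
    flin = (x + t$A) / (t$T + t$A),
    flog = {
      bad <- is.finite(x) & x <= 0
      if (any(bad)) {
        cyto_warn(sprintf("flog: %d non-positive value(s) mapped to NaN", sum(bad)))
        x[bad] <- NaN
      }
      log10(x / t$T) / t$M + 1
    },
    fasinh = (asinh(x * sinh(t$M * LN10) / t$T) + t$A * LN10) / ((t$M + t$A) * LN10),
    .invert_increasing(.inverse_fun(t), .inverse_deriv(t), x)
  )
}

#' Invert a transformation (display space to data space)
#'
#' Out-of-range display values are extrapolated: the underlying functions
#' are defined beyond `[0, 1]`.
#'
#' @param t a [transform_scale()] object.
#' @param y numeric vector of display-space values.
#' @return numeric vector of data-space values such that
#'   `apply_transform(t, invert_transform(t, y))` equals `y` within 1e-9.
#' @export
invert_transform <- function(t, y) {
  stopifnot(inherits(t, "cyto_transform"))
  .inverse_fun(t)(as.numeric(y))
}
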