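# Shared fixtures and independent oracles for the test suite.  All
# fixtures are generated in code under fixed seeds.

# random dataset with events drawn uniform or log-normal
random_dataset <- function(n_events, n_parameters, dist = c("unif", "lnorm"),
                           range = 262144) {
  dist <- match.arg(dist)
  ev <- switch(dist,
    unif = matrix(runif(n_events * n_parameters, 0, range), n_events),
    lnorm = matrix(pmin(rlnorm(n_events * n_parameters, 5, 2), range - 1), n_events)
  )
  fcs_dataset(ev, channels = paste0("CH", seq_len(n_parameters)), ranges = range)
}

random_keyword_map <- function(n = 8) {
  # tokens may contain the delimiter anywhere but the first character
  # (the written dialect forbids leading delimiters)
  tok <- function(len, first_pool, pool) {
    paste0(
      sample(first_pool, 1),
      paste(sample(pool, len - 1, TRUE), collapse = "")
    )
  }
  nhalf <- max(n %/% 2, 1)
  nms <- c(
    paste0("$K", seq_len(nhalf)),
    replicate(n - nhalf, tok(6, letters, c(letters, "/", " ")))
  )
  nms <- make.unique(toupper(nms))
  vals <- replicate(
    n,
    tok(sample(2:12, 1), c(letters, LETTERS), c(letters, LETTERS, 0:9, "/", " ", ","))
  )
  setNames(vals, nms)
}

# star-shaped simple polygon: sorted angles with random radii
random_simple_polygon <- function(n_vertices) {
  theta <- sort(runif(n_vertices, 0, 2 * pi))
  r <- runif(n_vertices, 0.3, 1)
  cbind(r * cos(theta), r * sin(theta))
}

# independent scalar crossing-number classifier (boundary inclusive);
# works one point at a time from explicit edge-intersection parameters
oracle_point_in_polygon <- function(x, y, verts) {
  n <- nrow(verts)
  crossings <- 0L
  for (i in seq_len(n)) {
    x1 <- verts[i, 1]
    y1 <- verts[i, 2]
    k <- if (i == n) 1L else i + 1L
    x2 <- verts[k, 1]
    y2 <- verts[k, 2]
    # on-segment check via parametric projection
    dx <- x2 - x1
    dy <- y2 - y1
    len2 <- dx^2 + dy^2
    t <- ((x - x1) * dx + (y - y1) * dy) / len2
    if (t >= 0 && t <= 1) {
      px <- x1 + t * dx
      py <- y1 + t * dy
      if (px == x && py == y) {
        return(TRUE)
      }
    }
    # horizontal ray to +Inf; half-open rule on vertex y values
    if ((y1 <= y) != (y2 <= y)) {
      xi <- x1 + (y - y1) * dx / dy
      if (xi > x) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# naive per-row argmax-with-threshold scan
oracle_hard_assignment <- function(p, labels, threshold) {
  out <- character(nrow(p))
  for (i in seq_len(nrow(p))) {
    best <- 1L
    for (j in seq_len(ncol(p))) if (p[i, j] > p[i, best]) best <- j
    out[i] <- if (p[i, best] >= threshold) labels[best] else "unclassified"
  }
  out
}

# exhaustive assignment maximization over row permutations (rows <= cols
# padded implicitly by allowing "no column"); for small tables only
oracle_assignment_max <- function(overlap) {
  nr <- nrow(overlap)
  nc <- ncol(overlap)
  n <- max(nr, nc)
  padded <- matrix(0, n, n)
  padded[seq_len(nr), seq_len(nc)] <- overlap
  perms <- function(v) {
    if (length(v) <= 1) {
      return(list(v))
    }
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    }
    out
  }
  best <- NULL
  bestval <- -Inf
  for (p in perms(seq_len(n))) {
    val <- sum(padded[cbind(seq_len(n), p)])
    if (val > bestval) {
      bestval <- val
      best <- p
    }
  }
  out <- best[seq_len(nr)]
  out[out > nc] <- 0L
  list(assignment = out, value = bestval)
}

# byte-swap the DATA segment of a little-endian float FCS file and flip
# $BYTEORD, producing the big-endian encoding of the same data
to_big_endian_fcs <- function(bytes, value_size = 4L) {
  txt_begin <- as.integer(rawToChar(bytes[11:18]))
  txt_end <- as.integer(rawToChar(bytes[19:26]))
  text <- rawToChar(bytes[(txt_begin + 1):(txt_end + 1)])
  kw <- parse_text_segment(text)
  db <- as.integer(kw[["$BEGINDATA"]])
  de <- as.integer(kw[["$ENDDATA"]])
  stopifnot(grepl("1,2,3,4", text, fixed = TRUE))
  text2 <- sub("1,2,3,4", "4,3,2,1", text, fixed = TRUE)
  out <- bytes
  out[(txt_begin + 1):(txt_end + 1)] <- charToRaw(text2)
  if (de > 0) {
    data <- bytes[(db + 1):(de + 1)]
    idx <- seq_along(data)
    grp <- (idx - 1) %/% value_size
    out[(db + 1):(de + 1)] <- data[order(grp, -idx)]
  }
  out
}

example_channels <- c("FSC-A", "SSC-A", "CD123", "CD11c", "MHC-II", "CD14")
example_population_names <- c("monocytes", "mDC", "pDC", "B cells")
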