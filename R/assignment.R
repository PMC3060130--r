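# Linear assignment by the Hungarian method (shortest augmenting paths,
# O(n^3)).  Small helper used to match clusters to reference populations
# by maximizing contingency-table overlap.

# Minimize sum(cost[i, sigma(i)]) over permutations sigma of a square
# matrix; returns the column assigned to each row.
solve_assignment_min <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  if (n == 0L) {
    return(integer(0))
  }
  INF <- Inf
  # columns indexed 1..n stored at positions 2..n+1; position 1 is the
  # virtual column that seeds each augmenting path
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1) # p[j]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(INF, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF
      j1 <- 0L
      for (j in seq.int(2L, n + 1L)) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0 + 1L] - v[j]
        if (cur < minv[j]) {
          minv[j] <- cur
          way[j] <- j0
        }
        if (minv[j] < delta) {
          delta <- minv[j]
          j1 <- j
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j] + 1L] <- u[p[j] + 1L] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  assignment <- integer(n)
  for (j in seq.int(2L, n + 1L)) {
    if (p[j] > 0L) assignment[p[j]] <- j - 1L
  }
  assignment
}

# Maximize total overlap on a (possibly rectangular) table by padding with
# zeros; rows assigned to padding get 0 (unmatched).
solve_assignment_max <- function(overlap) {
  overlap <- as.matrix(overlap)
  nr <- nrow(overlap)
  nc <- ncol(overlap)
  n <- max(nr, nc)
  padded <- matrix(0, n, n)
  padded[seq_len(nr), seq_len(nc)] <- overlap
  sol <- solve_assignment_min(-padded)
  out <- sol[seq_len(nr)]
  out[out > nc] <- 0L
  out
}
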