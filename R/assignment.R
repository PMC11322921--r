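# Minimal-cost bipartite assignment (Hungarian algorithm, O(n^3)
# augmenting-path formulation with row/column potentials). Used to align
# repeated messages and padded lists; cross-checked against an exhaustive
# brute-force oracle in the test suite.

#' Solve a square minimal-cost assignment problem
#'
#' @param cost A square numeric cost matrix (rows: ground truth, columns:
#'   prediction).
#' @return An integer vector `a` with `a[i]` the column assigned to row `i`,
#'   minimizing `sum(cost[cbind(seq_len(n), a)])`.
#' @export
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (is.null(n) || n == 0L) return(integer(0))
  if (ncol(cost) != n) abort("cost matrix must be square")
  if (n == 1L) return(1L)
  # potentials: u over rows (1..n), v over columns (index 1 = virtual col 0)
  u <- numeric(n)
  v <- numeric(n + 1L)
  p <- integer(n + 1L) # p[j+1]: row currently assigned to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0L:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  out <- integer(n)
  for (j in seq_len(n)) out[p[j + 1L]] <- j
  out
}

# Deterministic tie canonicalization: among cost-equal two-swaps, prefer the
# lower prediction index for the lower ground-truth index. Leaves the total
# cost unchanged (swaps are applied only when cost-neutral) and terminates
# because every swap lowers the assignment vector lexicographically.
canonicalize_assignment <- function(cost, assign) {
  n <- length(assign)
  if (n < 2L) return(assign)
  tol <- 1e-9
  repeat {
    changed <- FALSE
    for (i in seq_len(n - 1L)) {
      for (k in (i + 1L):n) {
        j <- assign[i]
        l <- assign[k]
        if (l < j && abs((cost[i, j] + cost[k, l]) - (cost[i, l] + cost[k, j])) < tol) {
          assign[i] <- l
          assign[k] <- j
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  assign
}
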