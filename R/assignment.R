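## Minimum-cost square assignment via shortest augmenting paths
## (Jonker-Volgenant / Hungarian with potentials). Exact, deterministic.
## Used by matchFrames(); instances are small (a few cells per frame),
## so an O(n^3) dense implementation is ample.
solveAssignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  u <- numeric(n + 1L)           # row potentials (index = row)
  v <- numeric(n + 1L)           # column potentials (n+1 = sentinel)
  p <- integer(n + 1L)           # p[j]: row currently assigned to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      js <- which(!used[seq_len(n)])
      cur <- cost[i0, js] - u[i0] - v[js]
      better <- cur < minv[js]
      if (any(better)) {
        minv[js[better]] <- cur[better]
        way[js[better]] <- j0
      }
      j1 <- js[which.min(minv[js])]
      delta <- minv[j1]
      uj <- which(used)
      u[p[uj]] <- u[p[uj]] + delta
      v[uj] <- v[uj] - delta
      nuj <- which(!used[seq_len(n)])
      minv[nuj] <- minv[nuj] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  ans <- integer(n)
  ans[p[seq_len(n)]] <- seq_len(n)
  ans
}
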