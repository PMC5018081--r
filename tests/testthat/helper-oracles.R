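# Independent oracles used across test files. These deliberately use naive
# algorithms (exhaustive enumeration, linear scans, quadrature) so they stay
# independent of the implementation paths they check.

xdist <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      out[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  out
}

# exhaustive search over all degree-feasible frame matchings (child <= 1
# parent, parent <= 2 children); objective: minimize unmatched endpoints
# (starts + terminations), then total matched distance
bruteMatch <- function(prev, nxt) {
  np <- nrow(prev); nc <- nrow(nxt)
  if (np == 0L || nc == 0L)
    return(list(unmatched = np + nc, distance = 0))
  d <- xdist(prev, nxt)
  best <- list(unmatched = Inf, distance = Inf)
  rec <- function(j, cap, dist) {
    if (j > nc) {
      obj1 <- sum(cap == 0L) + nUnassigned
      if (obj1 < best$unmatched ||
          (obj1 == best$unmatched && dist < best$distance - 1e-9))
        best <<- list(unmatched = obj1, distance = dist)
      return(invisible())
    }
    for (p in 0:np) {
      if (p > 0L && cap[p] >= 2L) next
      if (p == 0L) {
        nUnassigned <<- nUnassigned + 1L
        rec(j + 1L, cap, dist)
        nUnassigned <<- nUnassigned - 1L
      } else {
        cap[p] <- cap[p] + 1L
        rec(j + 1L, cap, dist + d[p, j])
        cap[p] <- cap[p] - 1L
      }
    }
  }
  nUnassigned <- 0L
  rec(1L, integer(np), 0)
  best
}

matchObjective <- function(m) {
  list(unmatched = length(m$starts) + length(m$terminations),
       distance = m$total_distance)
}

# nearest neighbour by explicit loop
scanNearest <- function(cell, cloud) {
  best <- Inf; bi <- NA_integer_
  for (i in seq_len(nrow(cloud))) {
    di <- sqrt(sum((cloud[i, ] - cell)^2))
    if (di < best) { best <- di; bi <- i }
  }
  list(i = bi, distance = best)
}

# adaptive-quadrature integral of k from 0 to d, split at the breakpoints
# so each piece is smooth and the quadrature is near machine precision
quadCumK <- function(profile, d) {
  cuts <- sort(unique(c(0, pmin(pmax(c(profile@d1, profile@d2), 0), d), d)))
  sum(vapply(seq_len(length(cuts) - 1L), function(i)
    stats::integrate(function(u) kOfD(profile, u), cuts[i], cuts[i + 1L],
                     rel.tol = 1e-10)$value, numeric(1)))
}

# a tiny hand-built dataset: two tracks near one moving tip, one crop
tinyDataset <- function(n_steps = 6L, step_minutes = 20) {
  tt <- 0:(n_steps - 1L)
  cells <- rbind(
    data.frame(sample = "s1", crop = "1", track = "a", branch = NA_character_,
               time = tt, pos_x = 10 + tt, pos_y = 20, pos_z = 10),
    data.frame(sample = "s1", crop = "1", track = "b", branch = NA_character_,
               time = tt, pos_x = 30, pos_y = 20 + 0.5 * tt, pos_z = 12))
  cloud <- do.call(rbind, lapply(tt, function(t)
    data.frame(crop = "1", time = t,
               pos_x = 20 + t + c(0, 1, -1, 0, 0),
               pos_y = 20 + c(0, 0, 0, 1, -1), pos_z = 10)))
  ends <- data.frame(crop = "1", tip_track = "1", time = tt,
                     pos_x = 20 + tt, pos_y = 20, pos_z = 10)
  trackDataset(cells, tipClouds = cloud, tipEnds = ends,
               sampleInfo = data.frame(sample = "s1", crop = "1",
                                       step_minutes = step_minutes,
                                       x_min = 0, x_max = 60, y_min = 0,
                                       y_max = 60, z_min = 0, z_max = 30))
}

# small-but-structured simulation used by several files
smallScenario <- function(...)
  syntheticScenario(nCells = 40L, nSteps = 25L, nTips = 2L,
                    cloudPoints = 30L, ...)
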