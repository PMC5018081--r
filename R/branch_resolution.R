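#' Match cell positions across one frame pair
#'
#' Associates positions at time t with positions at time t+1 under the
#' tracking degree constraints: each position at t+1 has at most one parent
#' at t, each position at t has at most two children at t+1 (a division).
#' Among feasible matchings the optimum is lexicographic: first minimize the
#' number of unmatched endpoints (track terminations at t and track starts at
#' t+1; given a maximal matching this also minimizes bifurcations), then
#' minimize the total Euclidean distance between matched positions. Exact
#' ties are broken deterministically by (parent index, child index).
#'
#' Implemented as a single min-cost assignment: each parent is duplicated
#' (allowing two children) and dummy rows/columns absorb unmatched endpoints
#' at a penalty larger than any achievable distance sum, which encodes the
#' lexicographic objective in one cost matrix.
#'
#' @param prev numeric matrix (n_prev x 3) of positions at time t (µm).
#' @param nxt numeric matrix (n_next x 3) of positions at time t+1 (µm).
#' @return list with elements `pairs` (data.frame with columns `parent`,
#'   `child`: row indices into `prev` and `nxt`), `starts` (indices of
#'   unmatched children), `terminations` (indices of childless parents),
#'   `bifurcations` (indices of parents with two children) and
#'   `total_distance` (µm, over matched pairs).
#' @examples
#' matchFrames(rbind(c(0, 0, 0)), rbind(c(1, 0, 0)))
#' @export
matchFrames <- function(prev, nxt) {
  prev <- .as_xyz(prev); nxt <- .as_xyz(nxt)
  np <- nrow(prev); nc <- nrow(nxt)
  empty <- list(pairs = data.frame(parent = integer(), child = integer()),
                starts = seq_len(nc), terminations = seq_len(np),
                bifurcations = integer(), total_distance = 0)
  if (np == 0L || nc == 0L) return(empty)

  d <- .cross_dist(prev, nxt)                      # np x nc
  P <- sum(d) + 1                                  # > any distance total
  tie <- outer(seq_len(np) - 1L, seq_len(nc) - 1L,
               function(i, j) i * nc + j) *
    (1e-9 * (1 + max(d)) / (np * nc + 1))
  N <- 2L * np + nc
  cost <- matrix(0, N, N)
  cost[seq_len(np), seq_len(nc)] <- d + tie        # first parent copies
  cost[np + seq_len(np), seq_len(nc)] <- d + tie   # second copies
  cost[seq_len(np), nc + seq_len(2L * np)] <- P    # unmatched 1st copy = termination
  cost[np + seq_len(np), nc + seq_len(2L * np)] <- 0
  cost[2L * np + seq_len(nc), seq_len(nc)] <- P    # unmatched child = start
  a <- solveAssignment(cost)

  rows <- seq_len(2L * np)
  matched <- rows[a[rows] <= nc]
  parent <- ((matched - 1L) %% np) + 1L
  child <- a[matched]
  o <- order(parent, child)
  pairs <- data.frame(parent = parent[o], child = child[o])
  nchild <- tabulate(pairs$parent, nbins = np)
  list(pairs = pairs,
       starts = setdiff(seq_len(nc), pairs$child),
       terminations = which(nchild == 0L),
       bifurcations = which(nchild == 2L),
       total_distance = sum(d[cbind(pairs$parent, pairs$child)]))
}

.as_xyz <- function(m) {
  if (is.null(m) || length(m) == 0L) return(matrix(numeric(), 0L, 3L))
  m <- as.matrix(m)
  if (ncol(m) != 3L) stop("positions must have 3 columns (x, y, z)")
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("positions must be finite")
  m
}

.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Resolve a branched track into unbranched segments
#'
#' Runs [matchFrames()] over every consecutive frame pair of one (possibly
#' branched) track, identifies branch points (a position with two children),
#' and splits the track there: the parent segment ends at the branch point
#' and two daughter segments begin at the next step, carrying a link to
#' their parent segment. A frame with no spots inside the track's time span
#' splits the track into independent parts (with a warning). Spots within a
#' frame are put in canonical (x, y, z) order before matching, so the result
#' does not depend on input row order.
#'
#' @param track data.frame of the spots of a single track, with columns
#'   `time, pos_x, pos_y, pos_z` (other columns are carried through).
#' @return list with `spots` (the input rows plus `branch` — integer segment
#'   index within the track — and `parent_branch`, `NA` for root segments)
#'   and `branch_points` (data.frame `time, pos_x, pos_y, pos_z`).
#' @export
resolveTrack <- function(track) {
  stopifnot(all(c("time", "pos_x", "pos_y", "pos_z") %in% names(track)))
  track <- track[order(track$time, track$pos_x, track$pos_y, track$pos_z), ,
                 drop = FALSE]
  times <- sort(unique(track$time))
  if (length(times) && any(diff(times) > 1L))
    warning("track has empty frame(s) inside its span; ",
            "splitting into independent tracks")

  # fast path: one spot per frame, no gaps -> a single unbranched segment
  if (nrow(track) == length(times) &&
      (length(times) < 2L || all(diff(times) == 1L))) {
    track$branch <- 1L
    track$parent_branch <- NA_integer_
    rownames(track) <- NULL
    return(list(spots = track,
                branch_points = data.frame(time = integer(),
                                           pos_x = numeric(),
                                           pos_y = numeric(),
                                           pos_z = numeric())))
  }

  track$branch <- NA_integer_
  track$parent_branch <- NA_integer_
  nseg <- 0L
  seg_parent <- integer()          # parent segment id per segment
  branch_pts <- list()

  idx_at <- function(t) which(track$time == t)
  prev_idx <- integer()            # row indices at previous time
  prev_t <- NULL
  for (t in times) {
    cur_idx <- idx_at(t)
    if (is.null(prev_t) || t != prev_t + 1L) {
      # run break (start of track or empty-frame gap): all spots start segments
      for (i in cur_idx) {
        nseg <- nseg + 1L
        seg_parent[nseg] <- NA_integer_
        track$branch[i] <- nseg
      }
    } else {
      pm <- as.matrix(track[prev_idx, c("pos_x", "pos_y", "pos_z")])
      cm <- as.matrix(track[cur_idx, c("pos_x", "pos_y", "pos_z")])
      m <- matchFrames(pm, cm)
      nchild <- tabulate(m$pairs$parent, nbins = length(prev_idx))
      for (r in seq_len(nrow(m$pairs))) {
        p <- m$pairs$parent[r]; ch <- m$pairs$child[r]
        pseg <- track$branch[prev_idx[p]]
        if (nchild[p] == 1L) {
          track$branch[cur_idx[ch]] <- pseg       # continue segment
        } else {
          nseg <- nseg + 1L                       # division: new daughter segment
          seg_parent[nseg] <- pseg
          track$branch[cur_idx[ch]] <- nseg
          track$parent_branch[cur_idx[ch]] <- pseg
        }
      }
      for (p in m$bifurcations)
        branch_pts[[length(branch_pts) + 1L]] <-
          track[prev_idx[p], c("time", "pos_x", "pos_y", "pos_z")]
      for (s in m$starts) {
        nseg <- nseg + 1L
        seg_parent[nseg] <- NA_integer_
        track$branch[cur_idx[s]] <- nseg
      }
    }
    prev_idx <- cur_idx
    prev_t <- t
  }
  # propagate parent link onto every spot of each daughter segment
  track$parent_branch <- seg_parent[track$branch]
  bp <- if (length(branch_pts)) do.call(rbind, branch_pts) else
    data.frame(time = integer(), pos_x = numeric(), pos_y = numeric(),
               pos_z = numeric())
  rownames(track) <- NULL
  rownames(bp) <- NULL
  list(spots = track, branch_points = bp)
}

#' Resolve all branched tracks in a dataset
#'
#' Applies [resolveTrack()] to every (sample, crop, track) group and fills
#' the `branch` column of the spot table, adding a globally unique `segment`
#' id (`sample.crop.track.branch`) and a `parent_segment` link for daughter
#' segments. Every input spot appears in exactly one segment.
#'
#' @param dataset a [TrackDataset-class].
#' @return a `TrackDataset` whose spots carry `branch`, `segment` and
#'   `parent_segment` columns; branch points are available as
#'   `attr(spots(x), "branch_points")`.
#' @export
resolveBranches <- function(dataset) {
  stopifnot(is(dataset, "TrackDataset"))
  sp <- dataset@spots
  if (!nrow(sp)) return(dataset)
  key <- paste(sp$sample, sp$crop, sp$track, sep = "\r")
  groups <- split(seq_len(nrow(sp)), key)
  out <- vector("list", length(groups))
  bps <- vector("list", length(out))
  for (i in seq_along(out)) {
    rows <- sp[groups[[i]], , drop = FALSE]
    res <- resolveTrack(rows[, setdiff(names(rows),
                                       c("branch", "parent_branch")),
                             drop = FALSE])
    s <- res$spots
    s$segment <- paste(s$sample, s$crop, s$track, s$branch, sep = ".")
    s$parent_segment <- ifelse(is.na(s$parent_branch), NA_character_,
                               paste(s$sample, s$crop, s$track,
                                     s$parent_branch, sep = "."))
    out[[i]] <- s
    if (nrow(res$branch_points)) {
      b <- res$branch_points
      b$sample <- rows$sample[1]; b$crop <- rows$crop[1]
      b$track <- rows$track[1]
      bps[[i]] <- b
    }
  }
  allsp <- do.call(rbind, out)
  rownames(allsp) <- NULL
  bp <- do.call(rbind, bps[!vapply(bps, is.null, logical(1))])
  attr(allsp, "branch_points") <- bp
  initialize(dataset, spots = allsp)
}
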