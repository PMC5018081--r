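#' Inverse-square-distance tip weights
#'
#' Weights the tracked tip positions for one cell at one time step,
#' proportional to the inverse square distance from the cell to each tip.
#' When the cell is associated with a single tip's niche this puts almost
#' all weight on that tip while transitioning smoothly when the niche is
#' ambiguous. A cell coinciding with a tip (distance below `eps`) takes that
#' tip's weight as 1 (the 1/d² limit).
#'
#' @param cell numeric length-3 cell position (µm).
#' @param tip_positions numeric matrix (n x 3) of tip end positions at the
#'   same time step.
#' @param tip_ids ids parallel to rows of `tip_positions`.
#' @param eps coincidence guard (µm).
#' @return named numeric vector of weights (sums to 1).
#' @export
tipWeights <- function(cell, tip_positions, tip_ids = seq_len(nrow(tip_positions)),
                       eps = 1e-9) {
  tip_positions <- .as_xyz(tip_positions)
  if (!nrow(tip_positions))
    stop("correction error: no usable tip for weighting")
  d2 <- (tip_positions[, 1] - cell[1])^2 + (tip_positions[, 2] - cell[2])^2 +
    (tip_positions[, 3] - cell[3])^2
  w <- if (any(d2 < eps^2)) as.numeric(d2 < eps^2) else 1 / d2
  w <- w / sum(w)
  names(w) <- as.character(tip_ids)
  w
}

#' Drift-corrected movement over one interval
#'
#' Subtracts the weighted average of the tip movements from the cell
#' movement, horizontal (x, y) components only; the vertical component is
#' passed through unchanged. Any bulk movement of the sample perturbs all
#' tips equally, is carried through the weighted average, and is therefore
#' removed.
#'
#' @param cell_move numeric length-3 cell displacement over the interval (µm).
#' @param tip_moves numeric matrix (n x 3 or n x 2) of tip displacements.
#' @param weights numeric weights (summing to 1) parallel to tip rows.
#' @return numeric length-3 corrected displacement.
#' @export
correctedMovement <- function(cell_move, tip_moves, weights) {
  tip_moves <- as.matrix(tip_moves)
  stopifnot(nrow(tip_moves) == length(weights))
  drift <- colSums(tip_moves[, 1:2, drop = FALSE] * weights)
  c(cell_move[1] - drift[1], cell_move[2] - drift[2], cell_move[3])
}

#' Rebuild positions from corrected movements
#'
#' Anchors the corrected track at the raw position of the segment's first
#' time step and accumulates the drift-corrected movements. z equals the raw
#' z series exactly.
#'
#' @param positions numeric matrix (n x 3) of raw positions on consecutive
#'   time steps.
#' @param movements numeric matrix ((n-1) x 3) of corrected displacements.
#' @return numeric matrix (n x 3) of corrected positions.
#' @export
reconstructPositions <- function(positions, movements) {
  positions <- .as_xyz(positions)
  n <- nrow(positions)
  stopifnot(nrow(movements) == n - 1L || (n == 1L && nrow(movements) == 0L))
  out <- positions
  if (n > 1L) {
    out[, 1] <- positions[1, 1] + c(0, cumsum(movements[, 1]))
    out[, 2] <- positions[1, 2] + c(0, cumsum(movements[, 2]))
  }
  out[, 3] <- positions[, 3]
  out
}

#' Drift-correct all segments of a dataset
#'
#' For every interval between consecutive time steps of every unbranched
#' segment, computes inverse-square-distance weights over the tip end tracks
#' of the spot's crop (distance measured at the interval's start step; tips
#' missing at either end of the interval are excluded and the rest
#' re-weighted), subtracts the weighted average tip movement from the
#' horizontal cell movement, and rebuilds positions anchored at each
#' segment's first raw position. Daughter segments anchor at their own first
#' raw position.
#'
#' @param dataset a [TrackDataset-class] whose spots carry a `segment`
#'   column ([resolveBranches()]) and with tip end tracks present.
#' @param eps coincidence guard for weighting (µm).
#' @return the spot table with added `corr_x, corr_y, corr_z` columns.
#' @export
driftCorrect <- function(dataset, eps = 1e-9) {
  stopifnot(is(dataset, "TrackDataset"))
  sp <- dataset@spots
  if (!"segment" %in% names(sp))
    stop("run resolveBranches() before drift correction")
  te <- dataset@tipEnds
  if (!nrow(te))
    stop("correction error: dataset has no tip end tracks")
  sp$corr_x <- NA_real_; sp$corr_y <- NA_real_; sp$corr_z <- sp$pos_z
  te_by <- lapply(split(te, te$crop), function(x)
    lapply(split(x, x$time), function(y)
      list(ids = y$tip_track,
           mat = as.matrix(y[, c("pos_x", "pos_y", "pos_z")]))))
  segrows <- split(seq_len(nrow(sp)), sp$segment)
  for (seg in names(segrows)) {
    rows <- segrows[[seg]]
    rows <- rows[order(sp$time[rows])]
    pos <- as.matrix(sp[rows, c("pos_x", "pos_y", "pos_z")])
    n <- length(rows)
    if (n == 1L) {
      sp$corr_x[rows] <- pos[1, 1]; sp$corr_y[rows] <- pos[1, 2]
      next
    }
    cr <- as.character(sp$crop[rows[1]])
    tec <- te_by[[cr]]
    if (is.null(tec))
      stop("correction error: no tip end tracks in crop ", cr)
    times <- sp$time[rows]
    mv <- matrix(NA_real_, n - 1L, 3L)
    for (i in seq_len(n - 1L)) {
      t0 <- times[i]
      tip0 <- tec[[as.character(t0)]]
      tip1 <- tec[[as.character(t0 + 1L)]]
      ids <- intersect(tip0$ids, tip1$ids)
      if (!length(ids))
        stop("correction error: no tip end track spans interval [", t0, ", ",
             t0 + 1L, "] in crop ", cr)
      p0 <- tip0$mat[match(ids, tip0$ids), , drop = FALSE]
      p1 <- tip1$mat[match(ids, tip1$ids), , drop = FALSE]
      w <- tipWeights(pos[i, ], p0, ids, eps = eps)
      mv[i, ] <- correctedMovement(pos[i + 1L, ] - pos[i, ], p1 - p0, w)
    }
    cp <- reconstructPositions(pos, mv)
    sp$corr_x[rows] <- cp[, 1]; sp$corr_y[rows] <- cp[, 2]
  }
  sp
}
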