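#' Nearest tip-volume point
#'
#' Finds, for a cell position, the closest point of the tip spot cloud at
#' the same time step and the vector from the cell to that point. Exact
#' nearest neighbour by linear scan (cloud sizes are small). Positions are
#' the raw (pre-drift-correction) coordinates.
#'
#' @param cell numeric length-3 position (µm).
#' @param cloud numeric matrix (n x 3) of tip-volume points (µm).
#' @return list `vector` (length-3, cell to tip point), `distance` (µm).
#' @examples
#' nearestTipPoint(c(0, 0, 0), rbind(c(1, 0, 0)))
#' @export
nearestTipPoint <- function(cell, cloud) {
  cloud <- .as_xyz(cloud)
  if (!nrow(cloud)) stop("missing tip: empty tip cloud")
  d2 <- (cloud[, 1] - cell[1])^2 + (cloud[, 2] - cell[2])^2 +
    (cloud[, 3] - cell[3])^2
  i <- which.min(d2)
  list(vector = cloud[i, ] - cell, distance = sqrt(d2[i]))
}

#' Nearest tip end track
#'
#' Identifies the closest manually tracked tip extremity at a time step.
#' Ties are broken by lowest tip track id.
#'
#' @param cell numeric length-3 position (µm).
#' @param tip_positions numeric matrix (n x 3) of tip end positions at the
#'   time step.
#' @param tip_ids character/numeric ids parallel to `tip_positions` rows.
#' @return list `tip_track` (id), `distance` (µm).
#' @export
nearestTipEnd <- function(cell, tip_positions, tip_ids) {
  tip_positions <- .as_xyz(tip_positions)
  if (!nrow(tip_positions)) stop("missing tip: no tip end track at this step")
  stopifnot(length(tip_ids) == nrow(tip_positions))
  d <- sqrt((tip_positions[, 1] - cell[1])^2 +
            (tip_positions[, 2] - cell[2])^2 +
            (tip_positions[, 3] - cell[3])^2)
  o <- order(d, as.character(tip_ids))
  list(tip_track = tip_ids[o[1]], distance = d[o[1]])
}

#' Horizontal location relative to the tip
#'
#' A spot is horizontally located when the vertical angle of its
#' cell-to-nearest-tip-point vector is strictly less than 45 degrees,
#' i.e. |dz| < sqrt(dx^2 + dy^2). The boundary (exactly 45 degrees) is not
#' horizontal. A zero vector (cell touching the tip point) is treated as
#' horizontal contact.
#'
#' @param v numeric length-3 vector, or an n x 3 matrix of vectors.
#' @param threshold_deg vertical angle threshold in degrees (default 45).
#' @return logical (vectorized over matrix rows).
#' @export
classifyHorizontal <- function(v, threshold_deg = 45) {
  if (is.null(dim(v))) v <- matrix(v, ncol = 3)
  h <- sqrt(v[, 1]^2 + v[, 2]^2)
  ang <- atan2(abs(v[, 3]), h) * 180 / pi
  out <- ang < threshold_deg
  zero <- h == 0 & v[, 3] == 0
  if (any(zero)) {
    warning("zero tip vector(s): treating distance-0 contact as horizontal")
    out[zero] <- TRUE
  }
  out
}

#' Tip context for every spot of a dataset
#'
#' Computes, per spot: the vector and distance to the nearest tip-volume
#' point at the spot's time step, the nearest tip end track id and distance,
#' and the horizontal/vertical classification. All on raw positions
#' (pre-drift-correction), per the study convention.
#'
#' @param dataset a [TrackDataset-class] with tip clouds (and optionally tip
#'   end tracks).
#' @return data.frame keyed like the spot table with added columns `tip_dx,
#'   tip_dy, tip_dz, tip_distance, is_horizontal` and, when tip end tracks
#'   exist, `tip_track, tip_track_distance`.
#' @export
tipContext <- function(dataset) {
  stopifnot(is(dataset, "TrackDataset"))
  sp <- dataset@spots
  cl <- dataset@tipClouds
  te <- dataset@tipEnds
  if (!nrow(cl)) stop("missing tip: dataset has no tip clouds")
  sp$tip_dx <- sp$tip_dy <- sp$tip_dz <- sp$tip_distance <- NA_real_
  sp$tip_track <- NA_character_
  sp$tip_track_distance <- NA_real_
  for (cr in unique(sp$crop)) {
    crows <- which(sp$crop == cr)
    clc <- cl[cl$crop == cr, , drop = FALSE]
    tec <- te[te$crop == cr, , drop = FALSE]
    for (t in unique(sp$time[crows])) {
      rows <- crows[sp$time[crows] == t]
      cloud <- as.matrix(clc[clc$time == t, c("pos_x", "pos_y", "pos_z")])
      if (!nrow(cloud))
        stop("missing tip: crop ", cr, " has no tip cloud at time ", t)
      cells <- as.matrix(sp[rows, c("pos_x", "pos_y", "pos_z")])
      d <- .cross_dist(cells, cloud)
      j <- max.col(-d, ties.method = "first")
      sp$tip_dx[rows] <- cloud[j, 1] - cells[, 1]
      sp$tip_dy[rows] <- cloud[j, 2] - cells[, 2]
      sp$tip_dz[rows] <- cloud[j, 3] - cells[, 3]
      sp$tip_distance[rows] <- d[cbind(seq_along(rows), j)]
      if (nrow(tec)) {
        tt <- tec[tec$time == t, , drop = FALSE]
        if (nrow(tt)) {
          tt <- tt[order(tt$tip_track), , drop = FALSE]
          dte <- .cross_dist(cells,
                             as.matrix(tt[, c("pos_x", "pos_y", "pos_z")]))
          jj <- max.col(-dte, ties.method = "first")
          sp$tip_track[rows] <- tt$tip_track[jj]
          sp$tip_track_distance[rows] <- dte[cbind(seq_along(rows), jj)]
        }
      }
    }
  }
  sp$is_horizontal <- classifyHorizontal(
    as.matrix(sp[, c("tip_dx", "tip_dy", "tip_dz")]))
  sp
}

#' Map attachment annotation onto spots
#'
#' Spots on annotated unbranched segments are `attached` inside any of that
#' segment's annotated intervals and `free` outside; spots on segments not in
#' the annotation set are `unannotated`.
#'
#' @param spots spot table carrying a `segment` column (see
#'   [resolveBranches()]).
#' @param intervals attachment table (`track, first, last`), `track` holding
#'   segment ids.
#' @param annotated_tracks character vector of all annotated segment ids
#'   (must include every id in `intervals`).
#' @return the spot table with an added `attachment` factor column
#'   (`attached` / `free` / `unannotated`).
#' @export
mapAttachment <- function(spots, intervals, annotated_tracks) {
  stopifnot("segment" %in% names(spots))
  annotated_tracks <- unique(as.character(annotated_tracks))
  unknown <- setdiff(intervals$track, annotated_tracks)
  if (length(unknown))
    stop("attachment interval(s) reference track(s) outside the annotation ",
         "set: ", paste(unknown, collapse = ", "))
  unknown2 <- setdiff(intervals$track, spots$segment)
  if (length(unknown2))
    stop("attachment interval(s) reference unknown track(s): ",
         paste(unknown2, collapse = ", "))
  state <- ifelse(spots$segment %in% annotated_tracks, "free", "unannotated")
  for (r in seq_len(nrow(intervals))) {
    hit <- spots$segment == intervals$track[r] &
      spots$time >= intervals$first[r] & spots$time <= intervals$last[r]
    state[hit] <- "attached"
  }
  spots$attachment <- factor(state,
                             levels = c("attached", "free", "unannotated"))
  spots
}
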