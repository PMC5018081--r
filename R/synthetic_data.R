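#' Define a synthetic imaging scenario
#'
#' Defaults describe a realistic niche: a 160 x 160 x 60 µm crop holding
#' three drifting ureteric tips (5 µm spherical spot clouds) and 200 cap
#' cells followed for 70 twenty-minute steps. Cells move with the weighted
#' drift of the tips (inverse-square-distance weights), isotropic Gaussian
#' diffusion, and a radial convection v(d) = D * k(d) evaluated at the
#' distance to the tip surface (positive k pushes away from the tip). The
#' default truth profile is the simplified fitted profile of the source
#' study (k falling linearly from 0.293 per µm at the surface to -0.098 per
#' µm at 14.95 µm, constant beyond); sigma = sqrt(2 D) makes the radial
#' diffusion consistent with the steady-state model. Observed z carries
#' independent measurement jitter emulating the degraded axial resolution.
#'
#' @param nTips,tipSpeed,nCells,sigma,profile,D,divisionProb,zJitterSd
#'   see [SyntheticScenario-class].
#' @param stepMinutes,nSteps,bounds,tipRadius,cloudPoints,sampleId
#'   see [SyntheticScenario-class].
#' @return a [SyntheticScenario-class].
#' @export
syntheticScenario <- function(nTips = 3L, tipSpeed = 0.3, nCells = 200L,
                              D = 1.5, sigma = sqrt(2 * D),
                              profile = kProfile(0, 14.95, 0.293, -0.098),
                              divisionProb = 0.005, zJitterSd = 1.5,
                              stepMinutes = 20, nSteps = 70L,
                              bounds = c(0, 160, 0, 160, 0, 60),
                              tipRadius = 5, cloudPoints = 60L,
                              sampleId = "sim1") {
  methods::new("SyntheticScenario", nTips = as.integer(nTips),
               tipSpeed = tipSpeed, nCells = as.integer(nCells),
               sigma = sigma, profile = profile, D = D,
               divisionProb = divisionProb, zJitterSd = zJitterSd,
               stepMinutes = stepMinutes, nSteps = as.integer(nSteps),
               bounds = as.numeric(bounds), tipRadius = tipRadius,
               cloudPoints = as.integer(cloudPoints),
               sampleId = sampleId)
}

## fixed near-uniform ball template (Fibonacci spiral directions, cube-root
## radii) translated to each tip center: deterministic tip spot cloud
.ball_template <- function(n, radius) {
  i <- seq_len(n)
  phi <- (1 + sqrt(5)) / 2
  z <- 1 - (2 * i - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- 2 * pi * i / phi
  dirs <- cbind(r * cos(th), r * sin(th), z)
  dirs * radius * ((i / n)^(1 / 3))
}

.reflect <- function(x, lo, hi) {
  # reflect into [lo, hi]; records how many coordinates were reflected
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  refl <- x < lo | x > hi
  y <- ifelse(y > span, 2 * span - y, y) + lo
  list(x = y, reflected = refl)
}

#' Simulate a tracking dataset with known ground truth
#'
#' Forward model of the assumed cell motility: per step, cell movement =
#' inverse-square-weighted tip drift + radial convection D k(d) along the
#' cell-to-nearest-tip-center line (k evaluated at the distance to the tip
#' surface; positive k repels) + isotropic Gaussian diffusion. Cells are
#' seeded at steady-state distances from random tips, divide with fixed
#' per-step probability (daughters offset by ~1 µm), and reflect at the crop
#' bounds. Observed z adds independent jitter. Tracks without divisions are
#' annotated for attachment (observed tip-surface distance below 3 µm).
#'
#' @param scenario a [SyntheticScenario-class].
#' @param seed RNG seed (the same scenario and seed reproduce the dataset
#'   exactly).
#' @return list `dataset` (a [TrackDataset-class]) and `ledger` with ground
#'   truth: `cells` (one row per unbranched cell life: track, cell, parent
#'   cell, birth/death step), `divisions`, `intrinsic` (true per-step
#'   intrinsic displacements, before z jitter), `tip_centers`,
#'   `attachment` (intervals + annotated ids), `reflections`, and `counts`.
#' @export
simulateTracks <- function(scenario, seed = 1L) {
  stopifnot(is(scenario, "SyntheticScenario"))
  set.seed(seed)
  sc <- scenario
  b <- sc@bounds
  th <- c(sc@profile@d1, sc@profile@d2, sc@profile@k1, sc@profile@k2)

  ## tips: centers in the middle half of the crop, constant random horizontal
  ## velocity, reflected at (shrunken) bounds so clouds stay inside
  pad <- sc@tipRadius + 2
  tipc <- cbind(stats::runif(sc@nTips, b[1] + (b[2] - b[1]) * 0.25,
                             b[1] + (b[2] - b[1]) * 0.75),
                stats::runif(sc@nTips, b[3] + (b[4] - b[3]) * 0.25,
                             b[3] + (b[4] - b[3]) * 0.75),
                stats::runif(sc@nTips, (b[5] + b[6]) / 2 - 5,
                             (b[5] + b[6]) / 2 + 5))
  ang <- stats::runif(sc@nTips, 0, 2 * pi)
  tipv <- sc@tipSpeed * cbind(cos(ang), sin(ang), 0)
  tip_pos <- array(NA_real_, c(sc@nTips, 3L, sc@nSteps))
  tip_pos[, , 1] <- tipc
  for (t in 2:sc@nSteps) {
    p <- tip_pos[, , t - 1] + tipv
    for (ax in 1:2) {
      r <- .reflect(p[, ax], b[2 * ax - 1] + pad, b[2 * ax] - pad)
      p[, ax] <- r$x
      tipv[r$reflected, ax] <- -tipv[r$reflected, ax]
    }
    tip_pos[, , t] <- p
  }

  ## founder cells at steady-state surface distance from a random tip
  d0 <- sampleSteadyState(sc@profile, sc@nCells, 40)
  tipix <- sample.int(sc@nTips, sc@nCells, replace = TRUE)
  u <- matrix(stats::rnorm(sc@nCells * 3L), ncol = 3L)
  u <- u / sqrt(rowSums(u^2))
  pos <- tip_pos[tipix, , 1] + u * (d0 + sc@tipRadius)
  for (ax in 1:3)
    pos[, ax] <- .reflect(pos[, ax], b[2 * ax - 1], b[2 * ax])$x

  ncell <- sc@nCells
  cell_track <- as.character(seq_len(ncell))  # founder/lineage (track) id
  cell_id <- seq_len(ncell)                   # internal unbranched-cell id
  next_id <- ncell + 1L
  cells_ledger <- data.frame(cell = cell_id, track = cell_track,
                             parent = NA_integer_, birth = 0L,
                             death = NA_integer_)
  alive <- rep(TRUE, ncell)
  divisions <- list(); intrinsic <- list(); obs <- list()
  n_reflected <- 0L

  zjit <- function(n) stats::rnorm(n, 0, sc@zJitterSd)
  emit <- function(t, ids, p) {
    data.frame(sample = sc@sampleId, crop = "1",
               track = cell_track[match(ids, cell_id)],
               branch = NA_character_, time = t,
               pos_x = p[, 1], pos_y = p[, 2],
               pos_z = p[, 3] + zjit(nrow(p)),
               cell = ids, stringsAsFactors = FALSE)
  }
  live_ids <- cell_id
  obs[[1]] <- emit(0L, live_ids, pos)

  for (t in seq_len(sc@nSteps - 1L)) {
    na <- nrow(pos)
    ## weighted tip drift (weights at interval start, inverse square distance)
    tp0 <- tip_pos[, , t, drop = FALSE][, , 1, drop = TRUE]
    tp1 <- tip_pos[, , t + 1, drop = FALSE][, , 1, drop = TRUE]
    if (sc@nTips == 1L) { tp0 <- matrix(tp0, 1); tp1 <- matrix(tp1, 1) }
    d2t <- .cross_dist(pos, tp0)^2
    w <- 1 / pmax(d2t, 1e-18)
    w <- w / rowSums(w)
    drift <- w %*% (tp1 - tp0)
    drift[, 3] <- 0

    ## radial convection toward/away from the nearest tip center
    ndx <- max.col(-d2t, ties.method = "first")
    towards <- tp0[ndx, , drop = FALSE] - pos
    dcen <- sqrt(rowSums(towards^2))
    uhat <- towards / pmax(dcen, 1e-12)
    dsurf <- pmax(0, dcen - sc@tipRadius)
    conv <- -sc@D * .k_eval(th[1], th[2], th[3], th[4], dsurf) * uhat

    diffu <- matrix(stats::rnorm(na * 3L, 0, sc@sigma), ncol = 3L)
    intr <- conv + diffu
    newpos <- pos + drift + intr
    for (ax in 1:3) {
      r <- .reflect(newpos[, ax], b[2 * ax - 1], b[2 * ax])
      newpos[, ax] <- r$x
      n_reflected <- n_reflected + sum(r$reflected)
    }
    intrinsic[[t]] <- data.frame(cell = live_ids, time = t - 1L,
                                 dx = intr[, 1], dy = intr[, 2],
                                 dz = intr[, 3], tip = ndx)

    ## divisions: parent cell ends at t-1, two daughters appear at t
    div <- stats::runif(na) < sc@divisionProb
    if (any(div)) {
      for (i in which(div)) {
        pid <- live_ids[i]
        cells_ledger$death[cells_ledger$cell == pid] <- t - 1L
        doff <- stats::rnorm(3); doff <- doff / sqrt(sum(doff^2))
        ids2 <- c(next_id, next_id + 1L)
        next_id <- ids2[2] + 1L
        cell_track <- c(cell_track,
                        rep(cell_track[match(pid, cell_id)], 2L))
        cell_id <- c(cell_id, ids2)
        cells_ledger <- rbind(cells_ledger,
                              data.frame(cell = ids2,
                                         track = cell_track[match(pid, cell_id)],
                                         parent = pid, birth = t,
                                         death = NA_integer_))
        divisions[[length(divisions) + 1L]] <-
          data.frame(time = t - 1L, parent = pid,
                     track = cell_track[match(pid, cell_id)])
        p2 <- newpos[i, ] + doff * 1.0
        p2 <- pmin(pmax(p2, b[c(1, 3, 5)]), b[c(2, 4, 6)])
        newpos <- rbind(newpos, p2)
        live_ids <- c(live_ids, ids2[2])
        live_ids[i] <- ids2[1]
      }
    }
    pos <- newpos
    obs[[t + 1L]] <- emit(t, live_ids, pos)
  }
  cells_ledger$death[is.na(cells_ledger$death)] <- sc@nSteps - 1L

  spots <- do.call(rbind, obs)
  cloud_t <- .ball_template(sc@cloudPoints, sc@tipRadius)
  clouds <- do.call(rbind, lapply(seq_len(sc@nSteps), function(t) {
    do.call(rbind, lapply(seq_len(sc@nTips), function(i)
      data.frame(crop = "1", time = t - 1L,
                 pos_x = tip_pos[i, 1, t] + cloud_t[, 1],
                 pos_y = tip_pos[i, 2, t] + cloud_t[, 2],
                 pos_z = tip_pos[i, 3, t] + cloud_t[, 3])))
  }))
  tipends <- do.call(rbind, lapply(seq_len(sc@nTips), function(i)
    data.frame(crop = "1", tip_track = as.character(i),
               time = seq_len(sc@nSteps) - 1L,
               pos_x = tip_pos[i, 1, ], pos_y = tip_pos[i, 2, ],
               pos_z = tip_pos[i, 3, ])))

  ## attachment annotation on undivided tracks (segment id = track branch 1)
  divided <- unique(cells_ledger$track[!is.na(cells_ledger$parent)])
  undiv <- setdiff(unique(cells_ledger$track), divided)
  ann_ids <- paste(sc@sampleId, "1", undiv, "1", sep = ".")
  att <- list()
  for (j in seq_along(undiv)) {
    srows <- spots[spots$track == undiv[j], , drop = FALSE]
    srows <- srows[order(srows$time), ]
    dmin <- vapply(seq_len(nrow(srows)), function(r) {
      tt <- srows$time[r] + 1L
      min(sqrt((tip_pos[, 1, tt] - srows$pos_x[r])^2 +
               (tip_pos[, 2, tt] - srows$pos_y[r])^2 +
               (tip_pos[, 3, tt] - srows$pos_z[r])^2))
    }, numeric(1)) - sc@tipRadius
    rl <- rle(dmin < 3)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (q in which(rl$values & rl$lengths >= 2L))
      att[[length(att) + 1L]] <- data.frame(
        track = ann_ids[j], first = srows$time[starts[q]],
        last = srows$time[ends[q]])
  }
  att <- if (length(att)) do.call(rbind, att) else NULL

  spots_out <- spots[, setdiff(names(spots), "cell")]
  dataset <- trackDataset(
    spots_out, tipClouds = clouds, tipEnds = tipends, attachments = att,
    annotatedTracks = ann_ids,
    sampleInfo = data.frame(sample = sc@sampleId, crop = "1",
                            step_minutes = sc@stepMinutes,
                            x_min = b[1], x_max = b[2], y_min = b[3],
                            y_max = b[4], z_min = b[5], z_max = b[6]))
  ledger <- list(
    cells = cells_ledger,
    spot_cells = spots$cell,
    divisions = if (length(divisions)) do.call(rbind, divisions) else
      data.frame(time = integer(), parent = integer(), track = character()),
    intrinsic = do.call(rbind, intrinsic),
    tip_centers = tip_pos,
    attachment = list(intervals = att, annotated = ann_ids),
    reflections = n_reflected,
    counts = list(n_spots = nrow(spots),
                  n_tracks = length(unique(spots$track)),
                  n_segments = nrow(cells_ledger)))
  list(dataset = dataset, ledger = ledger)
}

#' Minimal division fixture
#'
#' One track: a single parent cell for `branch_step + 1` frames, then two
#' daughters diverging symmetrically until `n_frames` frames in total. The
#' true branch point is the parent's last position (time `branch_step`).
#'
#' @param n_frames total number of frames (time 0 .. n_frames-1).
#' @param branch_step time step of the division (parent's last frame).
#' @param divergence per-step lateral separation rate of the daughters (µm);
#'   0 gives coincident daughters (tie-break exercise).
#' @return data.frame of spots (`sample, crop, track, branch, time, pos_*`).
#' @export
makeDivisionFixture <- function(n_frames, branch_step, divergence = 1) {
  stopifnot(branch_step > 0, branch_step < n_frames - 1L)
  tt <- 0:(n_frames - 1L)
  parent <- data.frame(time = 0:branch_step, pos_x = as.numeric(0:branch_step),
                       pos_y = 0, pos_z = 0)
  after <- (branch_step + 1L):(n_frames - 1L)
  k <- seq_along(after)
  d1 <- data.frame(time = after, pos_x = as.numeric(after),
                   pos_y = k * divergence, pos_z = 0)
  d2 <- data.frame(time = after, pos_x = as.numeric(after),
                   pos_y = -k * divergence, pos_z = 0)
  out <- rbind(parent, d1, d2)
  data.frame(sample = "fix", crop = "1", track = "t1",
             branch = NA_character_, time = out$time, pos_x = out$pos_x,
             pos_y = out$pos_y, pos_z = out$pos_z,
             stringsAsFactors = FALSE)
}
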