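#' Mean squared displacement of one track
#'
#' Average squared 3D displacement over a time difference of `tau` steps,
#' averaged over all start times available in the track. Displacement is
#' straight-line, not path length. A linear MSD-vs-tau relationship indicates
#' Brownian motion (slope = diffusion rate); upward curvature indicates
#' persistent directed movement, downward a confinement effect.
#'
#' @param positions numeric matrix (n x 3) of positions on consecutive time
#'   steps (µm).
#' @param tau integer time difference in steps (>= 1).
#' @return MSD in µm², or `NA` if the track is too short (fewer than tau+1
#'   positions); short tracks are excluded from aggregation, never counted
#'   as zero.
#' @export
msd <- function(positions, tau) {
  positions <- .as_xyz(positions)
  n <- nrow(positions)
  if (n < tau + 1L) return(NA_real_)
  i <- seq_len(n - tau)
  dd <- positions[i + tau, , drop = FALSE] - positions[i, , drop = FALSE]
  mean(rowSums(dd^2))
}

#' Velocity autocorrelation of one track
#'
#' Mean dot product of horizontal (xy) step vectors separated by `tau`
#' steps, normalized by the track's mean squared single-step horizontal
#' displacement. Equals 1 at every lag for constant-velocity motion and
#' averages 0 for independent steps. Computed in the horizontal plane only
#' because axial (z) resolution artefacts ("jitter") produce spurious
#' negative single-step autocorrelation in z.
#'
#' @param positions numeric matrix (n x 3 or n x 2), consecutive steps.
#' @param tau integer lag in steps (>= 1).
#' @return dimensionless autocorrelation, or `NA` (with a warning) if every
#'   step is zero or the track is shorter than tau+2 positions.
#' @export
velocityAutocorrelation <- function(positions, tau) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < tau + 2L) return(NA_real_)
  v <- diff(positions[, 1:2, drop = FALSE])
  denom <- mean(rowSums(v^2))
  if (denom == 0) {
    warning("all steps zero: autocorrelation undefined, track excluded")
    return(NA_real_)
  }
  i <- seq_len(nrow(v) - tau)
  num <- mean(rowSums(v[i, , drop = FALSE] * v[i + tau, , drop = FALSE]))
  num / denom
}

.seg_split <- function(spots, coords = c("raw", "corrected")) {
  coords <- match.arg(coords)
  cols <- if (coords == "corrected") c("corr_x", "corr_y", "corr_z") else
    c("pos_x", "pos_y", "pos_z")
  if (!all(cols %in% names(spots)))
    stop("spot table lacks ", coords, " position columns (",
         paste(cols, collapse = ", "), ")")
  if (!"segment" %in% names(spots))
    stop("spot table lacks a 'segment' column; run resolveBranches()")
  sp <- spots[order(spots$segment, spots$time), , drop = FALSE]
  lapply(split(seq_len(nrow(sp)), sp$segment),
         function(ix) as.matrix(sp[ix, cols]))
}

.aggregate_per_track <- function(spots, taus, coords, fun) {
  if (!"step_minutes" %in% names(spots))
    stop("spot table lacks a 'step_minutes' column; aggregation must be ",
         "performed separately per time-step group")
  groups <- split(spots, spots$step_minutes)
  out <- lapply(names(groups), function(g) {
    tracks <- .seg_split(groups[[g]], coords)
    do.call(rbind, lapply(taus, function(tau) {
      vals <- suppressWarnings(
        vapply(tracks, function(p) fun(p, tau), numeric(1)))
      vals <- vals[!is.na(vals)]
      if (!length(vals)) return(NULL)
      data.frame(step_minutes = as.numeric(g), tau = tau,
                 value = mean(vals), n_tracks = length(vals))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate MSD / autocorrelation curves
#'
#' Per-track statistics averaged (unweighted) across all tracks, separately
#' per time-step group (15- and 20-minute data are never mixed, since a lag
#' in steps means a different physical time in each). Tracks too short for a
#' lag are excluded at that lag.
#'
#' @param spots spot table with `segment`, `time`, `step_minutes` and
#'   position columns.
#' @param taus integer lags (steps).
#' @param coords `"raw"` (`pos_*`) or `"corrected"` (`corr_*`).
#' @return data.frame `step_minutes, tau, value, n_tracks` (`value` is µm²
#'   for MSD, dimensionless for autocorrelation).
#' @export
aggregateMsd <- function(spots, taus, coords = c("raw", "corrected"))
  .aggregate_per_track(spots, taus, match.arg(coords), msd)

#' @rdname aggregateMsd
#' @export
aggregateAutocorrelation <- function(spots, taus,
                                     coords = c("raw", "corrected"))
  .aggregate_per_track(spots, taus, match.arg(coords),
                       velocityAutocorrelation)

#' Instantaneous horizontal speeds
#'
#' Horizontal (xy) step length per time step for every consecutive step pair
#' of every segment, in µm per time step.
#'
#' @param spots spot table with `segment`, `time` and position columns.
#' @param coords `"raw"` or `"corrected"`.
#' @return data.frame `sample, segment, time, speed`.
#' @export
instantaneousSpeeds <- function(spots, coords = c("raw", "corrected")) {
  coords <- match.arg(coords)
  cols <- if (coords == "corrected") c("corr_x", "corr_y") else
    c("pos_x", "pos_y")
  sp <- spots[order(spots$segment, spots$time), , drop = FALSE]
  same <- sp$segment[-1] == sp$segment[-nrow(sp)] &
    sp$time[-1] == sp$time[-nrow(sp)] + 1L
  i <- which(same)
  data.frame(sample = sp$sample[i], segment = sp$segment[i],
             time = sp$time[i],
             speed = sqrt((sp[[cols[1]]][i + 1L] - sp[[cols[1]]][i])^2 +
                          (sp[[cols[2]]][i + 1L] - sp[[cols[2]]][i])^2),
             stringsAsFactors = FALSE)
}

#' Between-track speed heterogeneity
#'
#' Nested linear-model comparison of instantaneous horizontal speed:
#' speed ~ sample versus speed ~ sample + track, compared by ANOVA F-test.
#' The residual sum-of-squares reduction of the second model is the
#' percentage of speed variability accounted for by track identity over and
#' above sample identity.
#'
#' @param speeds data.frame from [instantaneousSpeeds()] (`sample`,
#'   `segment`, `speed`).
#' @return list `F`, `p`, `rss_reduction_percent`, `rss1`, `rss2`, `anova`.
#' @export
speedHeterogeneity <- function(speeds) {
  stopifnot(all(c("sample", "segment", "speed") %in% names(speeds)))
  speeds$sample <- factor(speeds$sample)
  speeds$segment <- factor(speeds$segment)
  m1 <- if (nlevels(speeds$sample) > 1L)
    stats::lm(speed ~ sample, data = speeds)
  else stats::lm(speed ~ 1, data = speeds)
  m2 <- if (nlevels(speeds$sample) > 1L)
    stats::lm(speed ~ sample + segment, data = speeds)
  else stats::lm(speed ~ segment, data = speeds)
  rss1 <- sum(stats::residuals(m1)^2)
  rss2 <- sum(stats::residuals(m2)^2)
  # guard the degenerate zero-variance case against floating-point dust
  tiny <- 1e-10 * max(1, sum(speeds$speed^2))
  red <- if (rss1 > tiny) 100 * (rss1 - rss2) / rss1 else 0
  av <- stats::anova(m1, m2)
  list(F = av$F[2], p = av[["Pr(>F)"]][2],
       rss_reduction_percent = red, rss1 = rss1, rss2 = rss2, anova = av)
}

#' Exclude spots near the lateral crop edge
#'
#' Drops spots whose horizontal distance to any crop boundary is below the
#' margin (strictly less than 1 µm by default; a spot exactly at the margin
#' is kept). Near-edge cells have constrained possible movement (outward
#' moves can leave the imaged volume), which would bias directional
#' statistics. Applied in xy only.
#'
#' @param spots spot table.
#' @param bounds data.frame `sample, crop, x_min, x_max, y_min, y_max` (e.g.
#'   [sampleInfo()]).
#' @param margin exclusion margin (µm).
#' @return the filtered spot table.
#' @export
excludeNearEdge <- function(spots, bounds, margin = 1) {
  m <- match(paste(spots$sample, spots$crop),
             paste(bounds$sample, bounds$crop))
  if (anyNA(m))
    stop("missing crop bounds for crop(s): ",
         paste(unique(spots$crop[is.na(m)]), collapse = ", "),
         "; supply bounds or infer them from the data")
  keep <- spots$pos_x - bounds$x_min[m] >= margin &
    bounds$x_max[m] - spots$pos_x >= margin &
    spots$pos_y - bounds$y_min[m] >= margin &
    bounds$y_max[m] - spots$pos_y >= margin
  spots[keep, , drop = FALSE]
}

#' Movement toward or away from the tip
#'
#' For each spot (except each segment's last), projects the drift-corrected
#' movement over the subsequent time step onto the unit vector toward the
#' nearest tip-volume point at the current step (raw-position tip context).
#' Positive values are movement toward the tip surface, negative away. This
#' projection is used instead of the change in tip distance because with a
#' complex tip geometry random motion does not give equal chances of the
#' distance increasing or decreasing.
#'
#' @param spots spot table carrying tip context (`tip_dx, tip_dy, tip_dz,
#'   tip_distance`) and corrected positions (`corr_x, corr_y, corr_z`).
#' @param horizontal if `TRUE`, project the xy components only (sensitivity
#'   variant); default is the full 3D projection.
#' @return data.frame `sample, crop, segment, time, d` (initial tip distance,
#'   µm), `m` (projected movement, µm per step), `move_norm` (magnitude of
#'   the movement vector, µm). Spots with a zero tip vector are skipped with
#'   a warning.
#' @export
tipDirectedMovement <- function(spots, horizontal = FALSE) {
  need <- c("tip_dx", "tip_dy", "tip_dz", "tip_distance",
            "corr_x", "corr_y", "corr_z", "segment", "time")
  if (!all(need %in% names(spots)))
    stop("spot table lacks column(s): ",
         paste(setdiff(need, names(spots)), collapse = ", "))
  sp <- spots[order(spots$segment, spots$time), , drop = FALSE]
  nr <- nrow(sp)
  same <- sp$segment[-1] == sp$segment[-nr] & sp$time[-1] == sp$time[-nr] + 1L
  i <- which(same)
  u <- cbind(sp$tip_dx[i], sp$tip_dy[i], sp$tip_dz[i])
  mv <- cbind(sp$corr_x[i + 1L] - sp$corr_x[i],
              sp$corr_y[i + 1L] - sp$corr_y[i],
              sp$corr_z[i + 1L] - sp$corr_z[i])
  if (horizontal) { u <- u[, 1:2, drop = FALSE]; mv <- mv[, 1:2, drop = FALSE] }
  un <- sqrt(rowSums(u^2))
  ok <- un > 0
  if (any(!ok))
    warning(sum(!ok), " spot(s) with zero tip vector skipped")
  i <- i[ok]; u <- u[ok, , drop = FALSE]; mv <- mv[ok, , drop = FALSE]
  un <- un[ok]
  data.frame(sample = sp$sample[i], crop = sp$crop[i],
             segment = sp$segment[i], time = sp$time[i],
             d = sp$tip_distance[i],
             m = rowSums(mv * (u / un)),
             move_norm = sqrt(rowSums(mv^2)),
             stringsAsFactors = FALSE)
}

#' Tip attraction / repulsion tests
#'
#' Splits tip-directed movements into a near group (initial tip distance
#' below `split`) and a far group, and tests each group's mean projected
#' movement against zero with a classic one-sample two-sided t-test.
#' Edge-excluded moves should be supplied (see [excludeNearEdge()]).
#'
#' @param moves data.frame from [tipDirectedMovement()].
#' @param split distance split (µm); near is `d < split`, far `d >= split`.
#' @return data.frame per group: `group, n, mean_m, median_m,
#'   mean_move_norm, t, p` (`t`/`p` are `NA` when n < 2).
#' @export
attractionRepulsionTests <- function(moves, split = 10) {
  grp <- ifelse(moves$d < split, sprintf("d<%g", split),
                sprintf("d>%g", split))
  do.call(rbind, lapply(sort(unique(grp)), function(g) {
    m <- moves$m[grp == g]
    tt <- if (length(m) >= 2L && stats::sd(m) > 0)
      stats::t.test(m, mu = 0, alternative = "two.sided") else NULL
    data.frame(group = g, n = length(m),
               mean_m = mean(m), median_m = stats::median(m),
               mean_move_norm = mean(moves$move_norm[grp == g]),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  }))
}

#' Far-field distance trend regression
#'
#' Ordinary least squares of projected tip-directed movement on initial tip
#' distance, over moves whose initial distance exceeds `threshold`; tests
#' whether the level of attraction varies with distance in the far field.
#'
#' @param moves data.frame from [tipDirectedMovement()].
#' @param threshold distance threshold (µm).
#' @return list `slope`, `p`, `n`.
#' @export
distanceTrendRegression <- function(moves, threshold = 15) {
  sub <- moves[moves$d > threshold, , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("need at least 3 moves beyond ", threshold, " µm")
  if (stats::var(sub$d) == 0)
    stop("regression error: all distances equal")
  fit <- stats::lm(m ~ d, data = sub)
  cf <- summary(fit)$coefficients
  list(slope = cf["d", "Estimate"], p = cf["d", "Pr(>|t|)"], n = nrow(sub))
}
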