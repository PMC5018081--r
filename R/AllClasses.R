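#' @import methods
NULL

## Column contracts for the three spot-table roles and the annotation table.
## These mirror the "Spots" statistics export dialect of the acquisition
## software: physical coordinates in micrometres, integer time-step index.
.COLS_CELLS    <- c("sample", "crop", "track", "branch", "time",
                    "pos_x", "pos_y", "pos_z")
.COLS_TIPCLOUD <- c("crop", "time", "pos_x", "pos_y", "pos_z")
.COLS_TIPENDS  <- c("crop", "tip_track", "time", "pos_x", "pos_y", "pos_z")
.COLS_ATTACH   <- c("track", "first", "last")

#' TrackDataset: a collated cell-tracking dataset
#'
#' Container for one or more samples of manually tracked cap mesenchyme
#' cells together with the per-time-step ureteric tip representation:
#' cell spots (possibly branched tracks), tip-volume spot clouds, tip
#' end tracks (the moving reference used for drift correction), and
#' optional attachment annotation.
#'
#' @slot spots data.frame with columns `sample, crop, track, branch, time,
#'   pos_x, pos_y, pos_z`. `branch` may be `NA` before branch resolution.
#' @slot tipClouds data.frame with columns `crop, time, pos_x, pos_y, pos_z`;
#'   the arbitrary points filling each rendered tip volume, exported without
#'   track information.
#' @slot tipEnds data.frame with columns `crop, tip_track, time, pos_x,
#'   pos_y, pos_z`; unbranched manually tracked tip extremities.
#' @slot attachments data.frame with columns `track, first, last`: periods of
#'   observed attachment to the ureteric epithelium, keyed by unbranched
#'   segment id.
#' @slot annotatedTracks character vector of segment ids that were assessed
#'   for attachment (tracks listed here but absent from `attachments` were
#'   observed and found free throughout).
#' @slot sampleInfo data.frame with one row per (sample, crop): columns
#'   `sample, crop, step_minutes, x_min, x_max, y_min, y_max, z_min, z_max`.
#'   Bounds are the crop limits in micrometres; when not supplied they are
#'   inferred as the bounding box of all spots and tip points in the crop.
#'
#' @export
setClass("TrackDataset",
  representation(
    spots = "data.frame",
    tipClouds = "data.frame",
    tipEnds = "data.frame",
    attachments = "data.frame",
    annotatedTracks = "character",
    sampleInfo = "data.frame"
  ),
  prototype(
    spots = data.frame(sample = character(), crop = character(),
                       track = character(), branch = character(),
                       time = integer(), pos_x = numeric(),
                       pos_y = numeric(), pos_z = numeric()),
    tipClouds = data.frame(crop = character(), time = integer(),
                           pos_x = numeric(), pos_y = numeric(),
                           pos_z = numeric()),
    tipEnds = data.frame(crop = character(), tip_track = character(),
                         time = integer(), pos_x = numeric(),
                         pos_y = numeric(), pos_z = numeric()),
    attachments = data.frame(track = character(), first = integer(),
                             last = integer()),
    annotatedTracks = character(),
    sampleInfo = data.frame(sample = character(), crop = character(),
                            step_minutes = numeric(),
                            x_min = numeric(), x_max = numeric(),
                            y_min = numeric(), y_max = numeric(),
                            z_min = numeric(), z_max = numeric())
  )
)

setValidity("TrackDataset", function(object) {
  msg <- character()
  sp <- object@spots
  if (!all(.COLS_CELLS %in% names(sp)))
    msg <- c(msg, paste("spots must have columns:",
                        paste(.COLS_CELLS, collapse = ", ")))
  else {
    xyz <- as.matrix(sp[, c("pos_x", "pos_y", "pos_z")])
    if (nrow(sp) && !all(is.finite(xyz)))
      msg <- c(msg, "spot coordinates must be finite")
    if (nrow(sp) && any(sp$time < 0))
      msg <- c(msg, "time steps must be non-negative")
    # branch is unassigned (NA) on raw exports, where a divided track has
    # several cells per time step; uniqueness applies once branch is assigned
    key <- paste(sp$sample, sp$crop, sp$track, sp$branch, sp$time)
    if (anyDuplicated(key[!is.na(sp$branch)]))
      msg <- c(msg, "duplicate (sample, crop, track, branch, time) spot keys")
  }
  at <- object@attachments
  if (nrow(at) && any(at$first > at$last))
    msg <- c(msg, "attachment intervals must have first <= last")
  si <- object@sampleInfo
  if (nrow(si) && !all(si$step_minutes %in% c(15, 20)))
    msg <- c(msg, "step_minutes must be 15 or 20")
  if (nrow(si) && anyDuplicated(si$sample) &&
      any(tapply(si$step_minutes, si$sample,
                 function(v) length(unique(v))) > 1L))
    msg <- c(msg, "step_minutes must be constant within a sample")
  if (length(msg)) msg else TRUE
})

#' KProfile: piecewise-linear convection-to-diffusion ratio profile
#'
#' The four-parameter profile k(d) = v(d)/D of directed (convective) radial
#' velocity over diffusion as a function of distance d to the ureteric tip
#' surface: constant `k1` for d < `d1`, constant `k2` for d > `d2`, linear in
#' between. Positive values are repulsion from the tip, negative attraction.
#' Units of k are per micrometre; d1, d2 are micrometres.
#'
#' @slot d1 numeric breakpoint (µm), 0 <= d1 <= d2.
#' @slot d2 numeric breakpoint (µm).
#' @slot k1 numeric near-field rate (per µm).
#' @slot k2 numeric far-field rate (per µm).
#'
#' @export
setClass("KProfile",
  representation(d1 = "numeric", d2 = "numeric",
                 k1 = "numeric", k2 = "numeric"))

setValidity("KProfile", function(object) {
  msg <- character()
  for (s in c("d1", "d2", "k1", "k2"))
    if (length(slot(object, s)) != 1L || !is.finite(slot(object, s)))
      msg <- c(msg, paste(s, "must be a finite scalar"))
  if (!length(msg)) {
    if (object@d1 < 0) msg <- c(msg, "d1 must be >= 0")
    if (object@d1 > object@d2) msg <- c(msg, "d1 must be <= d2")
  }
  if (length(msg)) msg else TRUE
})

#' ConvectionFit: maximum-likelihood fit of the distance model
#'
#' Result of fitting the steady-state convection-diffusion distance model.
#'
#' @slot profile fitted [KProfile-class].
#' @slot estimates named numeric (d1, d2, k1, k2).
#' @slot se named numeric standard errors from the inverse observed
#'   information (numeric Hessian).
#' @slot logLik numeric maximized log-likelihood.
#' @slot converged logical.
#' @slot dMax numeric domain bound used for normalization (µm).
#' @slot n integer number of distances fitted.
#'
#' @export
setClass("ConvectionFit",
  representation(profile = "KProfile", estimates = "numeric",
                 se = "numeric", logLik = "numeric",
                 converged = "logical", dMax = "numeric", n = "integer"))

#' SyntheticScenario: parameterization of the track simulator
#'
#' Full description of a synthetic imaging experiment: drifting ureteric
#' tips, cap cells moving with tip-coupled drift plus isotropic diffusion
#' plus distance-dependent radial convection, mitotic divisions, and
#' degraded axial (z) resolution.
#'
#' @slot nTips integer number of tips.
#' @slot tipSpeed numeric per-tip horizontal drift speed (µm per step);
#'   each tip gets a fixed random direction.
#' @slot nCells integer number of founder cells.
#' @slot sigma numeric per-axis diffusion step standard deviation (µm).
#' @slot profile true [KProfile-class] (k = v/D).
#' @slot D numeric diffusion scale (µm² per step); convection speed is
#'   v(d) = D * k(d).
#' @slot divisionProb numeric probability of division per cell per step.
#' @slot zJitterSd numeric sd of independent per-frame z measurement noise
#'   (µm), emulating poor axial resolution.
#' @slot stepMinutes numeric, 15 or 20.
#' @slot nSteps integer number of time steps.
#' @slot bounds numeric length-6: x_min, x_max, y_min, y_max, z_min, z_max (µm).
#' @slot tipRadius numeric radius of the spherical tip spot cloud (µm).
#' @slot cloudPoints integer points per tip cloud per time step.
#' @slot sampleId character sample identifier for the emitted table.
#'
#' @export
setClass("SyntheticScenario",
  representation(nTips = "integer", tipSpeed = "numeric", nCells = "integer",
                 sigma = "numeric", profile = "KProfile", D = "numeric",
                 divisionProb = "numeric", zJitterSd = "numeric",
                 stepMinutes = "numeric", nSteps = "integer",
                 bounds = "numeric", tipRadius = "numeric",
                 cloudPoints = "integer", sampleId = "character"))

setValidity("SyntheticScenario", function(object) {
  msg <- character()
  if (object@nTips < 1L) msg <- c(msg, "nTips must be >= 1")
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (object@nSteps < 2L) msg <- c(msg, "nSteps must be >= 2")
  if (any(c(object@sigma, object@D, object@divisionProb, object@zJitterSd,
            object@tipSpeed) < 0))
    msg <- c(msg, "rates and noise scales must be >= 0")
  if (!object@stepMinutes %in% c(15, 20))
    msg <- c(msg, "stepMinutes must be 15 or 20")
  b <- object@bounds
  if (length(b) != 6L || b[1] >= b[2] || b[3] >= b[4] || b[5] >= b[6])
    msg <- c(msg, "bounds must be non-degenerate (x_min < x_max, ...)")
  if (length(msg)) msg else TRUE
})
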