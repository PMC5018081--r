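#' Accessors for TrackDataset components
#'
#' @param x a [TrackDataset-class]
#' @return the corresponding data.frame (or character vector for
#'   `annotatedTracks`).
#' @name TrackDataset-accessors
#' @aliases spots tipClouds tipEnds attachments annotatedTracks sampleInfo
NULL

#' @rdname TrackDataset-accessors
#' @export
setGeneric("spots", function(x) standardGeneric("spots"))
#' @rdname TrackDataset-accessors
#' @export
setGeneric("tipClouds", function(x) standardGeneric("tipClouds"))
#' @rdname TrackDataset-accessors
#' @export
setGeneric("tipEnds", function(x) standardGeneric("tipEnds"))
#' @rdname TrackDataset-accessors
#' @export
setGeneric("attachments", function(x) standardGeneric("attachments"))
#' @rdname TrackDataset-accessors
#' @export
setGeneric("annotatedTracks", function(x) standardGeneric("annotatedTracks"))
#' @rdname TrackDataset-accessors
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname TrackDataset-accessors
setMethod("spots", "TrackDataset", function(x) x@spots)

#' @rdname TrackDataset-accessors
#' @param value replacement spot table (keyed like the existing one; extra
#'   computed columns such as tip context are allowed).
#' @export
setGeneric("spots<-", function(x, value) standardGeneric("spots<-"))
#' @rdname TrackDataset-accessors
setMethod("spots<-", "TrackDataset", function(x, value)
  methods::initialize(x, spots = value))
#' @rdname TrackDataset-accessors
setMethod("tipClouds", "TrackDataset", function(x) x@tipClouds)
#' @rdname TrackDataset-accessors
setMethod("tipEnds", "TrackDataset", function(x) x@tipEnds)
#' @rdname TrackDataset-accessors
setMethod("attachments", "TrackDataset", function(x) x@attachments)
#' @rdname TrackDataset-accessors
setMethod("annotatedTracks", "TrackDataset", function(x) x@annotatedTracks)
#' @rdname TrackDataset-accessors
setMethod("sampleInfo", "TrackDataset", function(x) x@sampleInfo)

setMethod("show", "TrackDataset", function(object) {
  sp <- object@spots
  cat("TrackDataset\n")
  cat(sprintf("  %d spots, %d tracks, %d sample(s), %d crop(s)\n",
              nrow(sp),
              nrow(unique(sp[, c("sample", "crop", "track")])),
              length(unique(sp$sample)),
              nrow(unique(sp[, c("sample", "crop")]))))
  cat(sprintf("  tip cloud points: %d; tip end tracks: %d\n",
              nrow(object@tipClouds),
              nrow(unique(object@tipEnds[, c("crop", "tip_track")]))))
  if (nrow(object@attachments) || length(object@annotatedTracks))
    cat(sprintf("  attachment: %d interval(s) on %d annotated track(s)\n",
                nrow(object@attachments), length(object@annotatedTracks)))
  invisible(NULL)
})

setMethod("show", "KProfile", function(object) {
  cat("KProfile: k(d) = v(d)/D (per µm; positive = repulsion)\n")
  cat(sprintf("  k1 = %.4g for d < d1 = %.4g µm\n", object@k1, object@d1))
  cat(sprintf("  k2 = %.4g for d > d2 = %.4g µm\n", object@k2, object@d2))
  if (object@d2 > object@d1)
    cat("  linear between d1 and d2\n")
  invisible(NULL)
})

setMethod("show", "ConvectionFit", function(object) {
  cat("ConvectionFit (steady-state convection-diffusion distance model)\n")
  est <- object@estimates; se <- object@se
  for (p in names(est))
    cat(sprintf("  %-3s = %8.4g ± %.4g\n", p, est[[p]],
                if (p %in% names(se)) se[[p]] else NA_real_))
  cat(sprintf("  log-likelihood %.4f on n = %d distances (d_max = %.3g)\n",
              object@logLik, object@n, object@dMax))
  cat(sprintf("  converged: %s\n", object@converged))
  invisible(NULL)
})

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario\n")
  cat(sprintf("  %d cells, %d tips, %d steps of %g min\n",
              object@nCells, object@nTips, object@nSteps,
              object@stepMinutes))
  cat(sprintf("  sigma = %.3g µm/axis/step, D = %.3g µm²/step, division p = %.3g\n",
              object@sigma, object@D, object@divisionProb))
  cat(sprintf("  z jitter sd = %.3g µm, tip speed = %.3g µm/step\n",
              object@zJitterSd, object@tipSpeed))
  invisible(NULL)
})
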