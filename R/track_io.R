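.ROLE_COLS <- list(cells = .COLS_CELLS, tip_cloud = .COLS_TIPCLOUD,
                   tip_ends = .COLS_TIPENDS, attachment = .COLS_ATTACH)
.NUM_COLS <- c("pos_x", "pos_y", "pos_z")

#' Read one spot/annotation table
#'
#' Reads a CSV in the spot-statistics export dialect: UTF-8, header row,
#' physical coordinates in micrometres, integer time-step index. The
#' required columns depend on the table's role; extra columns are carried
#' through, except that a tip-cloud table must not carry track identity
#' (tip-volume points are exported without track information), so a `track`
#' column there is dropped with a warning.
#'
#' @param path path to a CSV file.
#' @param role one of `"cells"`, `"tip_cloud"`, `"tip_ends"`,
#'   `"attachment"`.
#' @return a validated data.frame for the given role.
#' @export
readTrackTable <- function(path, role = c("cells", "tip_cloud", "tip_ends",
                                          "attachment")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validateTrackTable(df, role)
}

#' @rdname readTrackTable
#' @param df a data.frame to validate against the role's schema.
#' @export
validateTrackTable <- function(df, role = c("cells", "tip_cloud", "tip_ends",
                                            "attachment")) {
  role <- match.arg(role)
  need <- .ROLE_COLS[[role]]
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema error (", role, "): missing column(s): ",
         paste(missing, collapse = ", "))
  if (role == "tip_cloud" && any(c("track", "branch") %in% names(df))) {
    warning("tip cloud table carries track identity; ",
            "ignoring column(s): ",
            paste(intersect(c("track", "branch"), names(df)),
                  collapse = ", "))
    df <- df[, setdiff(names(df), c("track", "branch")), drop = FALSE]
  }
  for (cc in intersect(c(.NUM_COLS, "time", "first", "last"), need)) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop("parse error (", role, "): non-numeric value in column '", cc,
             "', row ", bad[1])
      df[[cc]] <- vn
    }
    if (anyNA(df[[cc]]) || any(!is.finite(df[[cc]])))
      stop("parse error (", role, "): missing/non-finite value in column '",
           cc, "', row ", which(!is.finite(df[[cc]]))[1])
  }
  if ("time" %in% need) df$time <- as.integer(round(df$time))
  for (cc in intersect(c("sample", "crop", "track", "branch", "tip_track"),
                       names(df)))
    df[[cc]] <- as.character(df[[cc]])
  if (role == "cells" && !"branch" %in% names(df)) df$branch <- NA_character_
  df
}

#' Write one spot/annotation table
#'
#' Inverse of [readTrackTable()]: `writeTrackTable` then `readTrackTable`
#' reproduces the table exactly (round-trip identity on all fields).
#'
#' @param df a data.frame as returned by [readTrackTable()].
#' @param path output CSV path.
#' @param role table role, see [readTrackTable()].
#' @return `path`, invisibly.
#' @export
writeTrackTable <- function(df, path, role = c("cells", "tip_cloud",
                                               "tip_ends", "attachment")) {
  role <- match.arg(role)
  df <- validateTrackTable(df, role)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Assemble a TrackDataset
#'
#' Builds and validates the dataset container from its component tables.
#' Crop bounds not supplied in `sampleInfo` are inferred as the axis-aligned
#' bounding box of all cell spots and tip points in the crop. If a crop has
#' any tip-cloud points, it must have them at every time step where it has
#' cells.
#'
#' @param spots cells table (see [readTrackTable()]).
#' @param tipClouds tip-volume point table.
#' @param tipEnds tip end-track table.
#' @param attachments attachment-interval table.
#' @param annotatedTracks character vector of segment ids assessed for
#'   attachment.
#' @param sampleInfo optional data.frame `sample, crop, step_minutes` plus
#'   optional bound columns `x_min, x_max, y_min, y_max, z_min, z_max`.
#' @param stepMinutes fallback time step (minutes) for samples missing from
#'   `sampleInfo`.
#' @return a [TrackDataset-class].
#' @export
trackDataset <- function(spots,
                         tipClouds = NULL, tipEnds = NULL,
                         attachments = NULL, annotatedTracks = character(),
                         sampleInfo = NULL, stepMinutes = 20) {
  spots <- validateTrackTable(as.data.frame(spots), "cells")
  proto <- methods::new("TrackDataset")
  tipClouds <- if (is.null(tipClouds)) proto@tipClouds else
    validateTrackTable(as.data.frame(tipClouds), "tip_cloud")
  tipEnds <- if (is.null(tipEnds)) proto@tipEnds else
    validateTrackTable(as.data.frame(tipEnds), "tip_ends")
  attachments <- if (is.null(attachments)) proto@attachments else
    validateTrackTable(as.data.frame(attachments), "attachment")
  annotatedTracks <- unique(c(as.character(annotatedTracks),
                              attachments$track))

  crops <- unique(spots[, c("sample", "crop")])
  si <- data.frame(sample = crops$sample, crop = crops$crop,
                   step_minutes = stepMinutes,
                   x_min = NA_real_, x_max = NA_real_,
                   y_min = NA_real_, y_max = NA_real_,
                   z_min = NA_real_, z_max = NA_real_,
                   stringsAsFactors = FALSE)
  if (!is.null(sampleInfo)) {
    sampleInfo <- as.data.frame(sampleInfo)
    for (cc in c("sample", "crop"))
      if (cc %in% names(sampleInfo))
        sampleInfo[[cc]] <- as.character(sampleInfo[[cc]])
    m <- match(paste(si$sample, si$crop),
               paste(sampleInfo$sample, sampleInfo$crop))
    for (cc in intersect(names(si)[-(1:2)], names(sampleInfo)))
      si[[cc]] <- ifelse(is.na(m), si[[cc]], sampleInfo[[cc]][m])
  }
  for (ci in seq_len(nrow(si))) {
    inCrop <- spots$sample == si$sample[ci] & spots$crop == si$crop[ci]
    cl <- tipClouds[tipClouds$crop == si$crop[ci], , drop = FALSE]
    for (ax in c("x", "y", "z")) {
      v <- c(spots[[paste0("pos_", ax)]][inCrop], cl[[paste0("pos_", ax)]])
      lo <- paste0(ax, "_min"); hi <- paste0(ax, "_max")
      if (is.na(si[[lo]][ci])) si[[lo]][ci] <- min(v)
      if (is.na(si[[hi]][ci])) si[[hi]][ci] <- max(v)
    }
    if (any(spots$pos_x[inCrop] < si$x_min[ci] |
            spots$pos_x[inCrop] > si$x_max[ci] |
            spots$pos_y[inCrop] < si$y_min[ci] |
            spots$pos_y[inCrop] > si$y_max[ci]))
      stop("crop bounds do not contain all spot positions (crop ",
           si$crop[ci], ")")
    if (nrow(cl)) {
      tcell <- unique(spots$time[inCrop])
      miss <- setdiff(tcell, unique(cl$time))
      if (length(miss))
        stop("crop ", si$crop[ci], " has cells but no tip cloud at time ",
             paste(miss, collapse = ", "))
    }
  }
  methods::new("TrackDataset", spots = spots, tipClouds = tipClouds,
               tipEnds = tipEnds, attachments = attachments,
               annotatedTracks = annotatedTracks, sampleInfo = si)
}

#' Read / write a dataset directory
#'
#' A dataset directory holds `cells.csv` and optionally `tip_cloud.csv`,
#' `tip_ends.csv`, `attachment.csv`, `annotated_tracks.csv` (single column
#' `track`) and `sample_info.csv`.
#'
#' @param dir directory path.
#' @return `readDataset`: a [TrackDataset-class]; `writeDataset`: `dir`,
#'   invisibly.
#' @export
readDataset <- function(dir) {
  f <- function(name) file.path(dir, name)
  if (!file.exists(f("cells.csv"))) stop("missing input: ", f("cells.csv"))
  opt <- function(name, role) if (file.exists(f(name)))
    readTrackTable(f(name), role) else NULL
  ann <- if (file.exists(f("annotated_tracks.csv")))
    as.character(utils::read.csv(f("annotated_tracks.csv"),
                                 stringsAsFactors = FALSE)$track)
  else character()
  si <- if (file.exists(f("sample_info.csv")))
    utils::read.csv(f("sample_info.csv"), stringsAsFactors = FALSE) else NULL
  trackDataset(readTrackTable(f("cells.csv"), "cells"),
               tipClouds = opt("tip_cloud.csv", "tip_cloud"),
               tipEnds = opt("tip_ends.csv", "tip_ends"),
               attachments = opt("attachment.csv", "attachment"),
               annotatedTracks = ann, sampleInfo = si,
               stepMinutes = if (!is.null(si)) si$step_minutes[1] else 20)
}

#' @rdname readDataset
#' @param dataset a [TrackDataset-class].
#' @export
writeDataset <- function(dataset, dir) {
  stopifnot(is(dataset, "TrackDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeTrackTable(dataset@spots, file.path(dir, "cells.csv"), "cells")
  if (nrow(dataset@tipClouds))
    writeTrackTable(dataset@tipClouds, file.path(dir, "tip_cloud.csv"),
                    "tip_cloud")
  if (nrow(dataset@tipEnds))
    writeTrackTable(dataset@tipEnds, file.path(dir, "tip_ends.csv"),
                    "tip_ends")
  if (nrow(dataset@attachments))
    writeTrackTable(dataset@attachments, file.path(dir, "attachment.csv"),
                    "attachment")
  if (length(dataset@annotatedTracks))
    utils::write.csv(data.frame(track = dataset@annotatedTracks),
                     file.path(dir, "annotated_tracks.csv"),
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset@sampleInfo, file.path(dir, "sample_info.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Per-sample dataset summary
#'
#' Tabulates, per sample: number of crops, time step (minutes), experiment
#' duration (hours), branched track count, unbranched segment count (`NA`
#' until [resolveBranches()] has been applied) and total spot count, plus a
#' grand-total row. Totals are additive over samples and crops.
#'
#' @param dataset a [TrackDataset-class].
#' @return data.frame with one row per sample and a final `total` row.
#' @export
summarizeDataset <- function(dataset) {
  stopifnot(is(dataset, "TrackDataset"))
  sp <- dataset@spots
  si <- dataset@sampleInfo
  samples <- unique(si$sample)
  rows <- lapply(samples, function(s) {
    in_s <- sp$sample == s
    ss <- sp[in_s, , drop = FALSE]
    segs <- if ("segment" %in% names(ss) && !anyNA(ss$branch))
      length(unique(ss$segment)) else NA_integer_
    data.frame(
      sample = s,
      crops = sum(si$sample == s),
      step_minutes = si$step_minutes[si$sample == s][1],
      duration_hours = if (nrow(ss))
        round(diff(range(ss$time)) * si$step_minutes[si$sample == s][1] / 60,
              2) else 0,
      tracks = nrow(unique(ss[, c("crop", "track")])),
      segments = segs,
      spots = nrow(ss),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(NULL)))
  if (is.null(out))
    out <- data.frame(sample = character(), crops = integer(),
                      step_minutes = numeric(), duration_hours = numeric(),
                      tracks = integer(), segments = integer(),
                      spots = integer(), stringsAsFactors = FALSE)
  total <- data.frame(sample = "total", crops = sum(out$crops),
                      step_minutes = NA_real_, duration_hours = NA_real_,
                      tracks = sum(out$tracks),
                      segments = if (nrow(out) && !anyNA(out$segments))
                        sum(out$segments) else NA_integer_,
                      spots = sum(out$spots), stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Published per-sample summary of the source tracking study
#'
#' Loads the published data summary of the live-imaging study this package's
#' methods are modelled on: per imaged kidney sample, the number of crops,
#' time step, experiment duration, branched and unbranched track counts and
#' total spot observations. Useful for sanity checks and as realistic sizing
#' for simulations.
#'
#' @return data.frame with columns `sample, crops, step_minutes,
#'   duration_hours, tracks, unbranched_tracks, spots`.
#' @export
studyDataSummary <- function() {
  utils::read.csv(system.file("extdata", "study_track_summary.csv",
                              package = "capmotion"),
                  stringsAsFactors = FALSE)
}
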