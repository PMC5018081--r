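#' Pipeline configuration
#'
#' Collects the tunable constants of the analysis; the defaults are the
#' study constants (1 µm edge-exclusion margin, 10 µm near/far split, 15 µm
#' far-field regression threshold, 45 degree horizontal-angle threshold).
#' Either `input_dir` (a dataset directory, see [readDataset()]) or
#' `scenario` (a [SyntheticScenario-class], simulated with `seed`) supplies
#' the data.
#'
#' @param input_dir dataset directory, or `NULL` to simulate.
#' @param out_dir output directory.
#' @param scenario [SyntheticScenario-class] used when `input_dir` is `NULL`.
#' @param seed RNG seed for simulation.
#' @param edge_margin µm, edge exclusion for directional statistics.
#' @param distance_split µm, near/far split for the attraction test.
#' @param regression_threshold µm, far-field regression cutoff.
#' @param angle_threshold degrees, horizontal classification.
#' @param d_max_policy `"max"` (maximum observed distance) or a number.
#' @param stages subset of
#'   `c("resolve", "context", "drift", "motility", "fit")`.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(input_dir = NULL, out_dir = tempfile("capmotion"),
                           scenario = syntheticScenario(), seed = 1L,
                           edge_margin = 1, distance_split = 10,
                           regression_threshold = 15, angle_threshold = 45,
                           d_max_policy = "max",
                           stages = c("resolve", "context", "drift",
                                      "motility", "fit")) {
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 scenario = scenario, seed = seed,
                 edge_margin = edge_margin, distance_split = distance_split,
                 regression_threshold = regression_threshold,
                 angle_threshold = angle_threshold,
                 d_max_policy = d_max_policy, stages = stages),
            class = "pipelineConfig")
}

#' Load a pipeline configuration from a YAML file
#'
#' Flat key-value YAML mirroring the arguments of [pipelineConfig()];
#' scenario fields may be given under a `scenario:` mapping.
#'
#' @param path YAML file.
#' @return a `pipelineConfig` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  sc <- do.call(syntheticScenario, lapply(y$scenario %||% list(), identity))
  y$scenario <- NULL
  do.call(pipelineConfig, c(y, list(scenario = sc)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Runs the stages in dependency order — branch resolution, tip context,
#' drift correction, motility statistics, convection-diffusion fit — on a
#' dataset directory or a simulated scenario, writing per-stage outputs and
#' a machine-readable run report (`report.json`). A stage failure aborts the
#' downstream stages; the report records the partial completion. The same
#' configuration and seed reproduce identical outputs.
#'
#' @param config a [pipelineConfig()] list.
#' @return the run report, invisibly.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(stages = list(), outputs = character(), warnings = list())
  fail <- FALSE
  stage <- function(name, fun) {
    if (fail || !(name %in% c("load", config$stages))) return(NULL)
    res <- tryCatch(
      withCallingHandlers(fun(), warning = function(w) {
        report$warnings[[name]] <<-
          c(report$warnings[[name]], conditionMessage(w))
        invokeRestart("muffleWarning")
      }),
      error = function(e) {
        report$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
        fail <<- TRUE
        NULL
      })
    if (!fail && is.null(report$stages[[name]]))
      report$stages[[name]] <<- list(status = "ok")
    res
  }
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    report$outputs <<- c(report$outputs, p)
    p
  }

  dataset <- stage("load", function() {
    if (!is.null(config$input_dir)) readDataset(config$input_dir)
    else simulateTracks(config$scenario, seed = config$seed)$dataset
  })
  if (!fail)
    report$stages$load$n_spots <- nrow(spots(dataset))

  dataset <- if ("resolve" %in% config$stages) stage("resolve", function() {
    ds <- resolveBranches(dataset)
    writeTrackTable(spots(ds), out("segments.csv"), "cells")
    ds
  }) %||% dataset else dataset
  if (!fail && "resolve" %in% config$stages)
    report$stages$resolve$n_segments <-
      length(unique(spots(dataset)$segment))

  sp <- stage("context", function() {
    cx <- tipContext(dataset)
    utils::write.csv(cx, out("context.csv"), row.names = FALSE)
    cx
  })

  sp <- stage("drift", function() {
    ds2 <- initialize(dataset, spots = sp)
    cc <- driftCorrect(ds2)
    utils::write.csv(cc, out("corrected.csv"), row.names = FALSE)
    cc
  }) %||% sp

  stats_res <- stage("motility", function() {
    si <- sampleInfo(dataset)
    sp$step_minutes <- si$step_minutes[match(paste(sp$sample, sp$crop),
                                             paste(si$sample, si$crop))]
    taus <- 1:10
    msd_raw <- aggregateMsd(sp, taus, "raw")
    msd_cor <- aggregateMsd(sp, taus, "corrected")
    msd_raw$coords <- "raw"; msd_cor$coords <- "corrected"
    utils::write.csv(rbind(msd_raw, msd_cor), out("msd.csv"),
                     row.names = FALSE)
    ac <- aggregateAutocorrelation(sp, taus, "corrected")
    utils::write.csv(ac, out("autocorr.csv"), row.names = FALSE)
    sph <- speedHeterogeneity(instantaneousSpeeds(sp, "corrected"))
    writeLines(c(sprintf("F = %g", sph$F), sprintf("p = %g", sph$p),
                 sprintf("rss_reduction_percent = %g",
                         sph$rss_reduction_percent)),
               out("heterogeneity.txt"))
    kept <- excludeNearEdge(sp, si, margin = config$edge_margin)
    moves <- tipDirectedMovement(kept)
    art <- attractionRepulsionTests(moves, split = config$distance_split)
    utils::write.csv(art, out("attraction.csv"), row.names = FALSE)
    trend <- tryCatch(
      distanceTrendRegression(moves, threshold = config$regression_threshold),
      error = function(e) list(slope = NA_real_, p = NA_real_, n = 0L))
    list(heterogeneity = sph, attraction = art, trend = trend,
         moves = moves)
  })
  if (!fail && "motility" %in% config$stages)
    report$stages$motility$n_moves <- nrow(stats_res$moves)

  fit <- stage("fit", function() {
    d <- sp$tip_distance
    dmax <- if (identical(config$d_max_policy, "max")) max(d) else
      as.numeric(config$d_max_policy)
    f <- fitConvectionDiffusion(d, d_max = dmax)
    simp <- simplifyProfile(f)
    jsonlite::write_json(
      list(estimates = as.list(f@estimates), se = as.list(f@se),
           loglik = f@logLik, converged = f@converged,
           simplified = list(d1 = simp@d1, d2 = simp@d2,
                             k1 = simp@k1, k2 = simp@k2)),
      out("fit.json"), auto_unbox = TRUE, digits = NA)
    f
  })

  report$completed <- !fail
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(list(report = report, dataset = dataset, spots = sp,
                 motility = stats_res, fit = fit))
}
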