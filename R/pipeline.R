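.pipelineDefaults <- function() list(
  grid = list(start = 35, stop = 95, step = 0.1),
  smoothing = list(window = 7, polyorder = 3),
  peaks = list(min_prominence_frac = 0.05, split_temp = 71),
  kmeans = list(restarts = 50, standardize = FALSE, seed = 1),
  cv = list(folds = 5, seed = 1, grid_step = 0.5,
            algorithms = c("LR", "SVM", "RF", "ADABOOST")),
  cohort = list(n_control = 100, n_poag = 100,
                mean_t1m = c(67.9, 64.6), mean_t2m = c(77.7, 79.3),
                sd_t1m = 0.8, sd_t2m = 0.8,
                noise_sigma_rel = 0.002, seed = 1)
)

## Merge a user config into the defaults, rejecting unknown keys.
.mergeConfig <- function(user, defaults = .pipelineDefaults(), path = "") {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]))
      .mergeConfig(user[[k]], defaults[[k]], paste0(path, k, "."))
    else user[[k]]
  }
  defaults
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Generates a labelled two-class cohort, extracts the (T1m, T2m) biomarker
#' from every scan, clusters the complete biomarker pairs by two-parameter
#' k-means, benchmarks the four classifiers by stratified cross-validation,
#' and writes all artifacts (cohort and truth CSV, peak table CSV, cluster
#' report CSV + JSON, evaluation CSV + JSON, and a manifest echoing the
#' resolved configuration, seeds and package version) into `outDir`.
#'
#' @param config named list overriding any subset of the default
#'   configuration (sections: grid, smoothing, peaks, kmeans, cv, cohort),
#'   or the path of a YAML file holding such a list. Unknown keys are an
#'   error and nothing is written.
#' @param outDir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the peak table, [ClusterResult-class],
#'   [EvaluationReport-class] and resolved config.
#' @export
runPipeline <- function(config = list(), outDir = ".", quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  grid <- TemperatureGrid(cfg$grid$start, cfg$grid$stop, cfg$grid$step)
  cc <- cfg$cohort
  cohortCfg <- CohortConfig(
    meanT1m = c(CONTROL = cc$mean_t1m[1], POAG = cc$mean_t1m[2]),
    meanT2m = c(CONTROL = cc$mean_t2m[1], POAG = cc$mean_t2m[2]),
    sdT1m = c(CONTROL = cc$sd_t1m, POAG = cc$sd_t1m),
    sdT2m = c(CONTROL = cc$sd_t2m, POAG = cc$sd_t2m),
    n = c(CONTROL = as.integer(cc$n_control), POAG = as.integer(cc$n_poag)),
    noiseSigmaRel = cc$noise_sigma_rel, seed = cc$seed)
  say("stage=cohort seed=%d n=%d", cc$seed, cc$n_control + cc$n_poag)
  ds <- generateCohort(cohortCfg, grid)
  writeCohort(ds, file.path(outDir, "cohort.csv"))

  say("stage=extract n=%d", length(cohortRuns(ds)))
  peaks <- extractCohort(cohortRuns(ds), grid,
                         window = cfg$smoothing$window,
                         polyorder = cfg$smoothing$polyorder,
                         minProminenceFrac = cfg$peaks$min_prominence_frac,
                         splitTemp = cfg$peaks$split_temp)
  utils::write.csv(peaks, file.path(outDir, "peaks.csv"), row.names = FALSE)

  comp <- peaks[peaks$complete, ]
  say("stage=cluster n=%d seed=%d", nrow(comp), cfg$kmeans$seed)
  cl <- kmeansTwo(comp[, c("t1m", "t2m")], nRestarts = cfg$kmeans$restarts,
                  seed = cfg$kmeans$seed, standardize = cfg$kmeans$standardize)
  ct <- crossTab(cl, comp$label)
  utils::write.csv(
    data.frame(sample_id = comp$sample_id, cluster = clusterAssignments(cl),
               poag_like = clusterAssignments(cl) == poagLikeCluster(cl)),
    file.path(outDir, "clusters.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(centers = clusterCenters(cl), inertia = cl@inertia,
         poag_like_cluster = poagLikeCluster(cl),
         contingency = as.data.frame(ct$table),
         positive_fraction = as.list(ct$positiveFraction)),
    file.path(outDir, "cluster_summary.json"), auto_unbox = TRUE, digits = NA)

  say("stage=classify seed=%d", cfg$cv$seed)
  feats <- assembleFeatures(cohortRuns(ds), gridStep = cfg$cv$grid_step,
                            grid = grid, window = cfg$smoothing$window,
                            polyorder = cfg$smoothing$polyorder)
  report <- runCV(feats, algorithms = cfg$cv$algorithms,
                  nFolds = cfg$cv$folds, seed = cfg$cv$seed)
  utils::write.csv(foldAccuracies(report),
                   file.path(outDir, "evaluation_folds.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(summary = accuracySummary(report),
         confusion = lapply(pooledConfusion(report), as.list),
         rates = confusionRates(report), seed = cfg$cv$seed),
    file.path(outDir, "evaluation.json"), auto_unbox = TRUE, digits = NA)

  jsonlite::write_json(
    list(package = "tfdp",
         version = as.character(utils::packageVersion("tfdp")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = cfg),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(list(peaks = peaks, clustering = cl, evaluation = report,
                 config = cfg))
}
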