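## End-to-end pipeline: simulate (or load) a cohort, split, train both
## task heads, evaluate per split, stratify risk groups, and write all
## artifacts under one output directory.

#' Run the full pipeline from a configuration
#'
#' Configuration fields (YAML file or list): \code{seed};
#' \code{simulate} (arguments for [simSettings()]) or \code{cohortDir}
#' (a directory written by [writeCohort()]); \code{split} (fractions,
#' stratify); \code{tasks} (any of classification / survival);
#' \code{evaluate} (aggregate, threshold, horizons); \code{heatmap}
#' (logical: render an attention heatmap for the first test slide).
#' Every artifact (manifest, checkpoints, training histories, metrics
#' JSON, tertile thresholds, log) is written under \code{outDir} and
#' stamped with the seed and a configuration echo.
#'
#' @param config list or path to a YAML file.
#' @param outDir output directory.
#' @return invisible list with the fitted models and the metrics.
#' @export
runPipeline <- function(config, outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$simulate) && is.null(config$cohortDir))
    stop("config error: either 'simulate' or 'cohortDir' is required")
  seed <- if (is.null(config$seed)) 0L else as.integer(config$seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "log.txt")
  logLine <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                sprintf(...)), file = logPath, append = TRUE)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    logLine("stage=%s elapsed=%.1fs", name, proc.time()[3] - t0)
    out
  }

  cohort <- stage("simulate", {
    if (!is.null(config$cohortDir)) readCohort(config$cohortDir)
    else do.call(simSettings,
                 modifyList(config$simulate, list(seed = seed))) |>
      simulateCohort()
  })
  logLine("cohort: %d patients, %d slides",
          length(unique(cohort@manifest$patient_id)),
          nrow(cohort@manifest))

  sp <- config$split
  cohort <- stage("split", splitCohort(
    cohort,
    fractions = if (is.null(sp$fractions)) c(0.65, 0.20, 0.15)
                else unlist(sp$fractions),
    seed = seed, stratify = isTRUE(sp$stratify)))
  writeManifest(cohort@manifest, file.path(outDir, "manifest.csv"))

  tasks <- if (is.null(config$tasks)) c("classification", "survival")
           else config$tasks
  ev <- config$evaluate
  aggregate <- if (is.null(ev$aggregate)) "mean" else ev$aggregate
  threshold <- if (is.null(ev$threshold)) 0.5 else ev$threshold
  horizons <- if (is.null(ev$horizons)) c(12, 24) else unlist(ev$horizons)

  models <- list()
  metrics <- list(seed = seed)
  for (task in tasks) {
    fit <- stage(paste0("train-", task), trainModel(
      cohort, task,
      settings = do.call(trainSettings,
                         c(list(task = task),
                           config[[paste0(task, "Settings")]])),
      config = if (is.null(config$model)) NULL else
        do.call(milConfig, c(list(inputDim = ncol(cohort@bags[[1]]@features),
                                  clinicalDim = ncol(cohort@clinical),
                                  task = task), config$model)),
      seed = seed))
    models[[task]] <- fit
    saveModel(fit, file.path(outDir, paste0(task, ".ckpt")),
              schema = cohort@schema)
    write.csv(trainingHistory(fit),
              file.path(outDir, paste0(task, "_history.csv")),
              row.names = FALSE)
    metrics[[task]] <- stage(paste0("evaluate-", task), {
      out <- list()
      for (s in c("train", "val", "test"))
        out[[s]] <- evaluateCohort(fit, cohort, split = s,
                                   aggregate = aggregate,
                                   threshold = threshold,
                                   horizons = horizons)
      out
    })
  }

  if ("survival" %in% tasks) {
    strat <- stage("stratify", {
      trainPred <- predictCohort(models$survival, cohort, "train",
                                 aggregate)
      thr <- tertileStratify(trainPred$score)
      jsonlite::write_json(thr, file.path(outDir, "thresholds.json"),
                           auto_unbox = TRUE, digits = NA)
      testPred <- predictCohort(models$survival, cohort, "test", aggregate)
      groups <- assignRiskGroup(testPred$score, thr)
      med <- vapply(levels(groups), function(g) {
        idx <- groups == g
        if (!sum(idx)) return(NA_real_)
        kmEstimate(testPred$time[idx], testPred$event[idx])$median
      }, numeric(1))
      list(thresholds = thr, testMedianPFS = as.list(med))
    })
    metrics$stratification <- strat
  }

  if (isTRUE(config$heatmap)) {
    stage("heatmap", {
      m <- cohort@manifest
      sid <- m$slide_id[m$split == "test"][1]
      bag <- cohort@bags[[sid]]
      task1 <- tasks[[1]]
      at <- attentionPool(models[[task1]], bag,
                          m$surgery_type[m$slide_id == sid])
      n <- nInstances(bag)
      side <- ceiling(sqrt(n))
      coords <- cbind(x = (seq_len(n) - 1L) %% side * 256L,
                      y = (seq_len(n) - 1L) %/% side * 256L)
      renderHeatmap(at$alpha, coords, c(side * 256L, side * 256L),
                    path = file.path(outDir, "attention_heatmap.png"))
    })
  }

  jsonlite::write_json(metrics, file.path(outDir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(config, file.path(outDir, "config_echo.json"),
                       auto_unbox = TRUE)
  invisible(list(models = models, metrics = metrics, cohort = cohort))
}
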