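#' Default pipeline configuration
#'
#' A fully synthetic end-to-end run emulating the study cohort: 103
#' patients, a 62-feature block-correlated immune panel with 3 informative
#' features, disease-control prevalence 0.41, hazard decreasing with the
#' latent score, a 6 x 9 technical-replicate variability study, and a
#' CPS-like comparator. Training sweeps the default regularization grid
#' with forward selection; scoring uses B = 1000 bootstrap iterations and
#' the median threshold.
#'
#' @param seed integer master seed; every stochastic stage derives its
#'   seed from it.
#' @return nested configuration list (YAML-serializable).
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      n_patients = 103L, n_features = 62L,
      informative_indices = c(1L, 2L, 3L),
      effect_sizes = c(2.0, 1.5, 1.0),
      target_prevalence = 0.41,
      block_correlation = 0.3,
      survival_baseline_scale = 12, survival_score_loghazard = 0.15,
      censor_rate = 0.2,
      replicates = list(n_biological = 6L, n_replicates = 9L,
                        technical_sd = 0.1),
      comparator = TRUE, comparator_noise_sd = 15
    ),
    train = list(C_grid = defaultCGrid(), k_max = 5L, cv_folds = 5L,
                 min_improve = 0.001, auc_floor = 0.76,
                 variability_ceiling = 20),
    score = list(B = 1000L, threshold = NULL),
    evaluate = list(comparator_column = "cps", cps_threshold = 20L)
  )
}

readPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      failValidation("config", sprintf("file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) failValidation("config", "must be a list or path")
  if (is.null(config$seed)) failValidation("seed", "is mandatory")
  if (is.null(config$simulate) && is.null(config$inputs$features) &&
      is.null(config$inputs$expression))
    failValidation("config",
                   "needs a simulate block, inputs$features or inputs$expression")
  if (is.null(config$simulate) && is.null(config$inputs$clinical))
    failValidation("inputs$clinical",
                   "a clinical table is required with external features")
  config
}

stageLog <- function(logLines, stage, t0, info) {
  c(logLines, sprintf("stage=%s wall_s=%.2f %s", stage,
                      as.numeric(Sys.time()) - t0, info))
}

#' Run the full biomarker pipeline
#'
#' Orchestrates simulate (or load) -> qc -> features -> train/select ->
#' score -> evaluate from a single configuration, writing every
#' intermediate artifact plus a machine-readable summary to a run
#' directory. All stage seeds derive from \code{config$seed}, so
#' re-running the same configuration reproduces every numeric output
#' bitwise. A stage failure aborts with the stage name.
#'
#' @param config configuration list or YAML path (see
#'   \code{\link{defaultPipelineConfig}}).
#' @param outputDir run directory (created; defaults to a tempdir
#'   subfolder).
#' @return invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
runPipeline <- function(config = defaultPipelineConfig(),
                        outputDir = tempfile("timescore_run_")) {
  config <- readPipelineConfig(config)
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  logLines <- character()
  t0 <- as.numeric(Sys.time())

  configPath <- file.path(outputDir, "config.yaml")
  yaml::write_yaml(config, configPath)
  configHash <- unname(tools::md5sum(configPath))

  runStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  ## ---- simulate or load ----
  replicates <- NULL
  comparator <- NULL
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    cohort <- runStage("simulate", {
      spec <- cohortSpec(
        nPatients = sim$n_patients, nFeatures = sim$n_features,
        informativeIndices = unlist(sim$informative_indices),
        effectSizes = unlist(sim$effect_sizes),
        targetPrevalence = sim$target_prevalence,
        featureBlockCorrelation = sim$block_correlation,
        survivalBaselineScale = sim$survival_baseline_scale %||% 12,
        survivalScoreLogHazard = sim$survival_score_loghazard %||% 0.5,
        censorRate = sim$censor_rate %||% 0.2,
        seed = seed)
      generateCohort(spec)
    })
    features <- cohortFeatures(cohort)
    clinical <- cohortClinical(cohort)
    clinical$sample_id <- rownames(clinical)
    if (!is.null(sim$replicates)) {
      rs <- sim$replicates
      replicates <- runStage("simulate", generateReplicates(
        features, replicateSpec(rs$n_biological, rs$n_replicates,
                                rs$technical_sd, seed = seed + 1L)))
    }
    if (isTRUE(sim$comparator)) {
      w <- numeric(ncol(features))
      idx <- unlist(sim$informative_indices)
      w[idx] <- unlist(sim$effect_sizes)
      comparator <- runStage("simulate", generateComparatorMarker(
        features, w, noiseSd = sim$comparator_noise_sd %||% 15,
        seed = seed + 2L))
      clinical$cps <- comparator[rownames(clinical)]
    }
    logLines <- stageLog(logLines, "simulate", t0,
                         sprintf("n=%d p=%d seed=%d", nrow(features),
                                 ncol(features), seed))
  } else {
    features <- if (is.null(config$inputs$expression))
      runStage("load", readFeatureMatrix(config$inputs$features))
    else NULL
    clinical <- runStage("load", readTsv(config$inputs$clinical))
    logLines <- stageLog(logLines, "load", t0,
                         sprintf("n=%d", nrow(clinical)))
  }

  ## ---- qc (only when QC metric columns are present) ----
  if (!is.null(config$qc)) {
    qcres <- runStage("qc", applySampleQC(
      clinical, utils::modifyList(defaultQCThresholds(),
                                  config$qc$thresholds %||% list())))
    writeTsv(qcres$exclusions, file.path(outputDir, "qc_exclusions.tsv"))
    clinical <- clinical[clinical$sample_id %in% qcres$retained, ,
                         drop = FALSE]
    if (!is.null(clinical$biopsy_to_treatment_months)) {
      st <- runStage("qc", applyStalenessFilter(
        clinical, config$qc$staleness_fraction %||% 0.10))
      clinical <- clinical[clinical$sample_id %in% st$retained, ,
                           drop = FALSE]
    }
    logLines <- stageLog(logLines, "qc", t0,
                         sprintf("retained=%d", nrow(clinical)))
  }

  ## ---- features (expression -> panel scores, when provided) ----
  if (!is.null(config$inputs$expression)) {
    expr <- runStage("features",
                     readExpressionMatrix(config$inputs$expression))
    panel <- runStage("features", readGeneSets(config$inputs$gene_sets))
    features <- runStage("features",
                         scoreSignatures(normalizeExpression(expr), panel))
    logLines <- stageLog(logLines, "features", t0,
                         sprintf("features=%d", ncol(features)))
  }

  joined <- runStage("assemble", assembleFeatureMatrix(features, clinical))
  features <- joined$features
  clinical <- joined$clinical
  y <- asOutcome01(clinical$outcome %||% clinical$response)
  writeFeatureMatrix(features, file.path(outputDir, "features.tsv"))
  writeClinicalTable(clinical, file.path(outputDir, "clinical.tsv"))

  ## ---- train / select ----
  tr <- config$train %||% list()
  built <- runStage("train", buildCandidateModels(
    features, y,
    Cgrid = unlist(tr$C_grid) %||% defaultCGrid(),
    kMax = tr$k_max %||% 10L, seed = seed + 3L,
    kFolds = tr$cv_folds %||% 5L,
    minImprove = tr$min_improve %||% 0.001,
    replicates = replicates))
  writeTsv(built$table, file.path(outputDir, "candidates.tsv"))
  final <- runStage("select", {
    if (is.null(replicates)) {
      cand <- built$candidates
      for (i in seq_along(cand)) cand[[i]]@variability <- 0
      selectFinalModel(cand, aucFloor = tr$auc_floor %||% 0.76,
                       variabilityCeiling = Inf)
    } else {
      selectFinalModel(built$candidates,
                       aucFloor = tr$auc_floor %||% 0.76,
                       variabilityCeiling = tr$variability_ceiling %||% 20)
    }
  })
  writeModelFile(final, file.path(outputDir, "model.yaml"))
  logLines <- stageLog(logLines, "train", t0,
                       sprintf("candidates=%d selected=%d_features",
                               length(built$candidates),
                               length(final@features)))

  ## ---- score ----
  sc <- config$score %||% list()
  B <- as.integer(sc$B %||% 1000L)
  scoreSet <- runStage("score", bootstrapOobScores(
    features, y, features = final@features, C = final@C, B = B,
    seed = seed + 4L))
  scoreSet <- runStage("score", classifyScores(scoreSet, sc$threshold))
  scoreSet <- runStage("score", assignQuartiles(scoreSet))
  writeTsv(scoreTable(scoreSet), file.path(outputDir, "scores.tsv"))
  logLines <- stageLog(logLines, "score", t0, sprintf("B=%d", B))

  ## ---- evaluate ----
  ev <- config$evaluate %||% list()
  pred <- predictedClass(scoreSet)
  cm <- runStage("evaluate", confusion(pred, outcomeLabel(y)))
  metrics <- diagnosticMetrics(cm)
  roc <- runStage("evaluate", rocAuc(patientScores(scoreSet), y))
  writeTsv(roc$curve, file.path(outputDir, "roc.tsv"))
  qd <- runStage("evaluate", quartileDcr(scoreQuartile(scoreSet), y))
  writeTsv(qd, file.path(outputDir, "quartile_dcr.tsv"))

  g <- pred == "non-progressor"
  dcr <- groupRate(c(non_progressor = sum(y[g]), progressor = sum(y[!g])),
                   c(sum(g), sum(!g)))
  # risk of progression for predicted progressors vs non-progressors
  rr <- relativeRisk(sum(y[!g] == 0), sum(!g), sum(y[g] == 0), sum(g))

  survSummary <- NULL
  if (!is.null(clinical$os_months) && !is.null(clinical$os_event)) {
    km <- runStage("evaluate", kmLogrank(clinical$os_months,
                                         clinical$os_event, pred))
    writeTsv(km$curves, file.path(outputDir, "km.tsv"))
    cox <- runStage("evaluate", coxPh(
      clinical$os_months, clinical$os_event,
      data.frame(predicted = factor(pred,
                                    c("progressor", "non-progressor")))))
    survSummary <- list(km_medians = as.list(km$medians),
                        logrank_p = km$p, cox_hr = cox$hr[1],
                        cox_p = cox$p[1])
  }

  comparatorSummary <- NULL
  compCol <- ev$comparator_column
  if (!is.null(compCol) && compCol %in% names(clinical)) {
    cps <- clinical[[compCol]]
    cpsPred <- ifelse(cps >= (ev$cps_threshold %||% 20L),
                      "non-progressor", "progressor")
    cmp <- runStage("evaluate", comparePredictors(pred, cpsPred,
                                                  outcomeLabel(y)))
    comparatorSummary <- list(
      comparator_auc = rocAuc(cps, y)$auc,
      concordant = cmp$concordant, n = cmp$n,
      discordant_errors = cmp$discordantErrors)
  }
  logLines <- stageLog(logLines, "evaluate", t0,
                       sprintf("auc=%.4f", roc$auc))

  summary <- list(
    config_hash = configHash, seed = seed, B = B,
    n_patients = nrow(features), n_features = ncol(features),
    prevalence = mean(y),
    model = list(features = final@features, C = final@C,
                 cv_auc = final@cvAUC,
                 variability_4std = final@variability),
    threshold = scoreThreshold(scoreSet),
    oob_auc = roc$auc,
    confusion = as.list(confusionCounts(cm)),
    metrics = as.list(metrics),
    dcr = list(non_progressor = dcr$rate[1], progressor = dcr$rate[2]),
    relative_risk = rr$rr,
    quartile_dcr = qd$rate,
    survival = survSummary,
    comparator = comparatorSummary
  )
  jsonlite::write_json(summary, file.path(outputDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(logLines, file.path(outputDir, "pipeline.log"))
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
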