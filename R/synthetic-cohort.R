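#' Specify a synthetic patient cohort
#'
#' Describes the statistical structure of a simulated immunotherapy cohort:
#' a correlated multivariate-normal immune-feature panel, a sparse logistic
#' outcome model whose intercept is solved numerically so that the expected
#' disease-control prevalence matches \code{targetPrevalence}, and
#' exponential (optionally Weibull) survival whose hazard decreases with the
#' latent linear predictor. The defaults emulate a cohort of 103 patients
#' with a 62-feature immune panel and prevalence 0.41.
#'
#' @param nPatients number of patients (>= 4).
#' @param nFeatures number of immune features (>= 1).
#' @param informativeIndices 1-based indices of outcome-informative
#'   features.
#' @param effectSizes log-odds effect per informative feature (recycled to
#'   the length of \code{informativeIndices}).
#' @param targetPrevalence expected fraction of non-progressors, strictly
#'   in (0, 1).
#' @param featureBlockCorrelation within-block feature correlation in
#'   [0, 1). Features are partitioned into 8 "cell-type" blocks plus an
#'   uncorrelated remainder.
#' @param survivalBaselineScale baseline survival scale in months.
#' @param survivalScoreLogHazard log-hazard decrease per unit of the latent
#'   linear predictor (positive = higher immune score, lower hazard).
#' @param censorRate expected fraction of patients censored before their
#'   event, in [0, 1).
#' @param weibullShape Weibull shape for event times (1 = exponential).
#' @param followupHorizon administrative censoring horizon in months.
#' @param seed integer seed; all generation is deterministic given the
#'   spec.
#' @return an object of class \code{CohortSpec} (a validated list).
#' @export
cohortSpec <- function(nPatients = 103, nFeatures = 62,
                       informativeIndices = integer(),
                       effectSizes = numeric(),
                       targetPrevalence = 0.41,
                       featureBlockCorrelation = 0.3,
                       survivalBaselineScale = 12,
                       survivalScoreLogHazard = 0.15,
                       censorRate = 0.2,
                       weibullShape = 1,
                       followupHorizon = 60,
                       seed = 1L) {
  assertScalar(nPatients, "nPatients", min = 4)
  assertScalar(nFeatures, "nFeatures", min = 1)
  assertScalar(targetPrevalence, "targetPrevalence",
               min = 0, max = 1, strictMin = TRUE, strictMax = TRUE)
  assertScalar(featureBlockCorrelation, "featureBlockCorrelation",
               min = 0, max = 1, strictMax = TRUE)
  assertScalar(survivalBaselineScale, "survivalBaselineScale",
               min = 0, strictMin = TRUE)
  assertScalar(survivalScoreLogHazard, "survivalScoreLogHazard")
  assertScalar(censorRate, "censorRate", min = 0, max = 1, strictMax = TRUE)
  assertScalar(weibullShape, "weibullShape", min = 0, strictMin = TRUE)
  assertScalar(followupHorizon, "followupHorizon", min = 0, strictMin = TRUE)
  assertScalar(seed, "seed")
  informativeIndices <- as.integer(informativeIndices)
  if (length(informativeIndices)) {
    if (any(informativeIndices < 1L) || any(informativeIndices > nFeatures))
      failValidation("informativeIndices",
                     sprintf("must lie in [1, %d]", nFeatures))
    if (anyDuplicated(informativeIndices))
      failValidation("informativeIndices", "must be unique")
    if (!length(effectSizes))
      failValidation("effectSizes",
                     "required when informativeIndices is non-empty")
    effectSizes <- rep_len(as.numeric(effectSizes),
                           length(informativeIndices))
  } else {
    effectSizes <- numeric()
  }
  structure(list(
    nPatients = as.integer(nPatients), nFeatures = as.integer(nFeatures),
    informativeIndices = informativeIndices, effectSizes = effectSizes,
    targetPrevalence = targetPrevalence,
    featureBlockCorrelation = featureBlockCorrelation,
    survivalBaselineScale = survivalBaselineScale,
    survivalScoreLogHazard = survivalScoreLogHazard,
    censorRate = censorRate, weibullShape = weibullShape,
    followupHorizon = followupHorizon, seed = as.integer(seed)
  ), class = "CohortSpec")
}

# Block memberships: 8 equal "cell-type" blocks of size floor(p/9) when that
# leaves at least 2 features per block, the rest uncorrelated (0 = no block).
featureBlocks <- function(nFeatures) {
  b <- nFeatures %/% 9L
  blocks <- integer(nFeatures)
  if (b >= 2L)
    blocks[seq_len(8L * b)] <- rep(seq_len(8L), each = b)
  blocks
}

# Solve the logistic intercept so the mean outcome probability over the
# realized design equals the target prevalence.
solveIntercept <- function(eta, target) {
  f <- function(b0) mean(plogis(b0 + eta)) - target
  uniroot(f, lower = -50, upper = 50, tol = 1e-10)$root
}

#' Generate a synthetic cohort
#'
#' Draws immune features from a correlated multivariate normal (8-block
#' exchangeable structure), a Bernoulli disease-control outcome from a
#' sparse logistic model calibrated to the target prevalence, and survival
#' times from a Weibull (default exponential) model whose hazard decreases
#' with the latent predictor, with independent exponential censoring plus
#' an administrative follow-up cap. Deterministic given
#' \code{spec$seed}.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return a \code{\link[SummarizedExperiment]{SummarizedExperiment}} with
#'   a \code{features} assay (features x patients) and clinical columns in
#'   \code{colData}: \code{outcome} ("non-progressor"/"progressor"),
#'   \code{response} (0/1, 1 = non-progressor), \code{os_months},
#'   \code{os_event}, and the latent predictor \code{eta}.
#' @export
generateCohort <- function(spec) {
  if (!inherits(spec, "CohortSpec"))
    failValidation("spec", "must be created with cohortSpec()")
  set.seed(spec$seed)
  n <- spec$nPatients
  p <- spec$nFeatures
  rho <- spec$featureBlockCorrelation

  blocks <- featureBlocks(p)
  nBlocks <- max(blocks, 0L)
  shared <- if (nBlocks > 0L)
    matrix(rnorm(n * nBlocks), n, nBlocks) else NULL
  X <- matrix(rnorm(n * p), n, p)
  if (rho > 0 && nBlocks > 0L) {
    inBlock <- blocks > 0L
    X[, inBlock] <- sqrt(rho) * shared[, blocks[inBlock], drop = FALSE] +
      sqrt(1 - rho) * X[, inBlock, drop = FALSE]
  }
  featNames <- sprintf("feat%02d", seq_len(p))
  sampleIds <- sprintf("P%03d", seq_len(n))
  dimnames(X) <- list(sampleIds, featNames)

  eta <- as.numeric(X[, spec$informativeIndices, drop = FALSE] %*%
                      spec$effectSizes)
  b0 <- solveIntercept(eta, spec$targetPrevalence)
  y <- rbinom(n, 1L, plogis(b0 + eta))

  # hazard_i = shape/scale_i * (t/scale_i)^(shape-1), with the score acting
  # multiplicatively on the rate: higher eta -> lower hazard.
  k <- spec$weibullShape
  scale_i <- spec$survivalBaselineScale *
    exp(spec$survivalScoreLogHazard * eta / k)
  eventTime <- stats::rweibull(n, shape = k, scale = scale_i)

  if (spec$censorRate > 0) {
    meanRate <- mean(1 / scale_i)
    crate <- uniroot(function(cr) mean(cr / (cr + 1 / scale_i)) -
                       spec$censorRate,
                     lower = 1e-10, upper = 1e4, tol = 1e-10)$root
    censTime <- rexp(n, rate = crate)
  } else {
    censTime <- rep(Inf, n)
  }
  censTime <- pmin(censTime, spec$followupHorizon)
  osMonths <- pmin(eventTime, censTime)
  osEvent <- as.integer(eventTime <= censTime)

  clinical <- S4Vectors::DataFrame(
    outcome = outcomeLabel(y),
    response = y,
    os_months = osMonths,
    os_event = osEvent,
    eta = eta,
    row.names = sampleIds
  )
  SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(X)),
    colData = clinical,
    metadata = list(spec = spec, intercept = b0,
                    featureBlocks = blocks)
  )
}

#' Cohort accessors
#'
#' Convenience accessors for cohorts produced by
#' \code{\link{generateCohort}}: \code{cohortFeatures} returns the samples
#' x features numeric matrix used by the modeling functions,
#' \code{cohortClinical} the clinical table as a plain data.frame.
#'
#' @param cohort a \code{SummarizedExperiment} from
#'   \code{\link{generateCohort}} (or of the same layout).
#' @return a matrix (samples x features) or data.frame.
#' @export
cohortFeatures <- function(cohort) {
  t(SummarizedExperiment::assay(cohort, "features"))
}

#' @rdname cohortFeatures
#' @export
cohortClinical <- function(cohort) {
  as.data.frame(SummarizedExperiment::colData(cohort))
}

#' Specify a technical-replicate experiment
#'
#' Defaults mirror an analytic-variability design of 9 technical replicates
#' from each of 6 biological samples (54 replicate profiles).
#'
#' @param nBiological number of biological samples.
#' @param nReplicates technical replicates per biological sample.
#' @param technicalSd i.i.d. Gaussian technical noise SD, in feature units.
#' @param seed integer seed.
#' @return a validated \code{ReplicateSpec} list.
#' @export
replicateSpec <- function(nBiological = 6, nReplicates = 9,
                          technicalSd = 0.1, seed = 1L) {
  assertScalar(nBiological, "nBiological", min = 1)
  assertScalar(nReplicates, "nReplicates", min = 1)
  assertScalar(technicalSd, "technicalSd", min = 0)
  assertScalar(seed, "seed")
  structure(list(nBiological = as.integer(nBiological),
                 nReplicates = as.integer(nReplicates),
                 technicalSd = technicalSd, seed = as.integer(seed)),
            class = "ReplicateSpec")
}

#' Generate technical replicates of biological samples
#'
#' Each replicate is its biological sample's feature row plus i.i.d.
#' Gaussian technical noise. Used to measure analytic variability (4*std)
#' of candidate biomarkers.
#'
#' @param baseFeatures samples x features matrix; the first
#'   \code{spec$nBiological} rows are used as the biological samples.
#' @param spec a \code{\link{replicateSpec}}.
#' @return list with \code{features} (a (nBiological*nReplicates) x
#'   features matrix) and \code{biologicalSample} (factor labelling each
#'   replicate row by its biological sample id).
#' @export
generateReplicates <- function(baseFeatures, spec) {
  if (!inherits(spec, "ReplicateSpec"))
    failValidation("spec", "must be created with replicateSpec()")
  baseFeatures <- as.matrix(baseFeatures)
  if (nrow(baseFeatures) < spec$nBiological)
    failValidation("baseFeatures",
                   sprintf("needs at least %d rows", spec$nBiological))
  set.seed(spec$seed)
  base <- baseFeatures[seq_len(spec$nBiological), , drop = FALSE]
  if (is.null(rownames(base)))
    rownames(base) <- sprintf("B%02d", seq_len(spec$nBiological))
  reps <- base[rep(seq_len(spec$nBiological), each = spec$nReplicates), ,
               drop = FALSE]
  if (spec$technicalSd > 0)
    reps <- reps + matrix(rnorm(length(reps), sd = spec$technicalSd),
                          nrow(reps), ncol(reps))
  bio <- factor(rep(rownames(base), each = spec$nReplicates),
                levels = rownames(base))
  rownames(reps) <- paste0(bio, "_r",
                           rep(seq_len(spec$nReplicates), spec$nBiological))
  list(features = reps, biologicalSample = bio)
}

#' Generate a synthetic expression layer beneath a feature matrix
#'
#' For every signature feature, member genes receive negative-binomial
#' counts whose log-mean tracks the feature value, so that signature
#' scoring on the generated counts recovers the input features. A matching
#' gene-set list (writable as GMT) is emitted.
#'
#' @param featureMatrix samples x features numeric matrix.
#' @param genesPerSignature member genes per signature (>= 1).
#' @param dispersion negative-binomial dispersion (> 0; variance =
#'   mu + dispersion * mu^2).
#' @param librarySize expected total counts per sample at baseline (> 0).
#' @param seed integer seed.
#' @param slope log-fold change in member-gene mean per unit of feature
#'   value.
#' @return list with \code{counts} (genes x samples integer matrix) and
#'   \code{geneSets} (named list of member genes per feature).
#' @export
generateExpressionLayer <- function(featureMatrix, genesPerSignature = 10,
                                    dispersion = 0.05, librarySize = 1e6,
                                    seed = 1L, slope = 0.4) {
  featureMatrix <- as.matrix(featureMatrix)
  assertScalar(genesPerSignature, "genesPerSignature", min = 1)
  assertScalar(dispersion, "dispersion", min = 0, strictMin = TRUE)
  assertScalar(librarySize, "librarySize", min = 0, strictMin = TRUE)
  assertScalar(seed, "seed")
  set.seed(seed)
  nS <- nrow(featureMatrix)
  nF <- ncol(featureMatrix)
  featNames <- colnames(featureMatrix)
  if (is.null(featNames)) featNames <- sprintf("feat%02d", seq_len(nF))
  nGenes <- nF * genesPerSignature
  baseMean <- librarySize / nGenes
  geneSets <- lapply(featNames, function(f)
    sprintf("%s_g%02d", f, seq_len(genesPerSignature)))
  names(geneSets) <- featNames
  geneIds <- unlist(geneSets, use.names = FALSE)

  counts <- matrix(0L, nGenes, nS,
                   dimnames = list(geneIds, rownames(featureMatrix)))
  for (j in seq_len(nF)) {
    mu <- baseMean * exp(slope * featureMatrix[, j])
    rows <- (j - 1L) * genesPerSignature + seq_len(genesPerSignature)
    counts[rows, ] <- matrix(
      rnbinom(genesPerSignature * nS, mu = rep(mu, each = genesPerSignature),
              size = 1 / dispersion),
      genesPerSignature, nS)
  }
  list(counts = counts, geneSets = geneSets)
}

#' Generate a CPS-like comparator marker
#'
#' A stand-in for a PD-L1 combined positive score: an integer 0-100 marker
#' obtained by a monotone (probit-rank) mapping of a weighted combination
#' of the immune features plus Gaussian noise, so that clinical categories
#' such as CPS >= 1 and CPS >= 20 are derivable.
#'
#' @param featureMatrix samples x features numeric matrix.
#' @param weights numeric weight per feature.
#' @param noiseSd Gaussian noise SD added before the monotone mapping.
#' @param seed integer seed.
#' @return integer vector in [0, 100], named by sample.
#' @export
generateComparatorMarker <- function(featureMatrix, weights, noiseSd = 1,
                                     seed = 1L) {
  featureMatrix <- as.matrix(featureMatrix)
  if (length(weights) != ncol(featureMatrix))
    failValidation("weights", "length must equal the number of features")
  assertScalar(noiseSd, "noiseSd", min = 0)
  assertScalar(seed, "seed")
  set.seed(seed)
  v <- as.numeric(featureMatrix %*% weights) +
    rnorm(nrow(featureMatrix), sd = noiseSd)
  s <- sd(v)
  cps <- if (is.na(s) || s == 0) rep(50L, length(v))
         else as.integer(round(100 * pnorm((v - mean(v)) / s)))
  names(cps) <- rownames(featureMatrix)
  cps
}
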