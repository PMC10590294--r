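test_that("cohort generation is deterministic given the spec", {
  spec <- cohortSpec(nPatients = 50, nFeatures = 20,
                     informativeIndices = c(1, 5),
                     effectSizes = c(1, -0.5), seed = 7)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(cohortFeatures(a), cohortFeatures(b))
  expect_identical(cohortClinical(a), cohortClinical(b))
})

test_that("spec validation names the offending field", {
  expect_error(cohortSpec(nPatients = 2), "nPatients")
  expect_error(cohortSpec(targetPrevalence = 0), "targetPrevalence")
  expect_error(cohortSpec(targetPrevalence = 1), "targetPrevalence")
  expect_error(cohortSpec(informativeIndices = 99, effectSizes = 1,
                          nFeatures = 10), "informativeIndices")
  expect_error(cohortSpec(informativeIndices = 1),
               "effectSizes")
  expect_error(generateCohort(list()), "spec")
})

test_that("null model realizes the target prevalence", {
  spec <- cohortSpec(nPatients = 2000, nFeatures = 5,
                     targetPrevalence = 0.41, seed = 11)
  cl <- cohortClinical(generateCohort(spec))
  binomSd <- sqrt(0.41 * 0.59 / 2000)
  expect_lt(abs(mean(cl$response) - 0.41), 3 * binomSd)
})

test_that("expected non-progressor count matches the cohort structure", {
  # n = 103 at prevalence 0.41: roughly 42 non-progressors expected
  spec <- cohortSpec(nPatients = 103, nFeatures = 10, seed = 3)
  co <- generateCohort(spec)
  expect_equal(103 * 0.41, 42.23, tolerance = 1e-9)
  # realized count within binomial variation of the expectation
  expect_lt(abs(sum(cohortClinical(co)$response) - 42.23),
            3 * sqrt(103 * 0.41 * 0.59) + 1)
})

test_that("a strongly informative feature discriminates the outcome", {
  spec <- cohortSpec(nPatients = 500, nFeatures = 4,
                     informativeIndices = 1, effectSizes = 3, seed = 1)
  co <- generateCohort(spec)
  auc <- pairCountAUC(cohortFeatures(co)[, 1],
                      cohortClinical(co)$response)
  expect_gt(auc, 0.85)
})

test_that("block correlation structures the feature covariance", {
  spec <- cohortSpec(nPatients = 3000, nFeatures = 27,
                     featureBlockCorrelation = 0.5, seed = 5)
  X <- cohortFeatures(generateCohort(spec))
  # features 1-3 share block 1 (27 features -> 8 blocks of 3)
  expect_gt(cor(X[, 1], X[, 2]), 0.4)
  # features in different blocks are uncorrelated
  expect_lt(abs(cor(X[, 1], X[, 4])), 0.1)
})

test_that("survival hazard decreases with the latent score", {
  spec <- cohortSpec(nPatients = 2000, nFeatures = 5,
                     informativeIndices = 1, effectSizes = 2,
                     survivalScoreLogHazard = 0.5, censorRate = 0,
                     followupHorizon = 1e6, seed = 8)
  cl <- cohortClinical(generateCohort(spec))
  hi <- cl$eta > median(cl$eta)
  expect_gt(median(cl$os_months[hi]), median(cl$os_months[!hi]))
  expect_true(all(cl$os_event == 1))
})

test_that("censoring rate is calibrated", {
  spec <- cohortSpec(nPatients = 4000, nFeatures = 3, censorRate = 0.3,
                     followupHorizon = 1e6, seed = 9)
  cl <- cohortClinical(generateCohort(spec))
  expect_lt(abs(mean(1 - cl$os_event) - 0.3), 0.03)
})

test_that("technical replicates follow the replicate spec", {
  base <- matrix(rnorm(12), 6, 2,
                 dimnames = list(sprintf("B%d", 1:6), c("f1", "f2")))
  # zero technical noise reproduces the base rows exactly
  r0 <- generateReplicates(base, replicateSpec(6, 9, technicalSd = 0,
                                               seed = 1))
  expect_equal(nrow(r0$features), 54)
  expect_equal(unname(r0$features[1, ]), unname(base[1, ]))
  expect_equal(unname(r0$features[54, ]), unname(base[6, ]))
  expect_equal(as.character(unique(r0$biologicalSample)), rownames(base))

  # replicate SD is consistent with the requested technical SD
  r1 <- generateReplicates(base[1, , drop = FALSE],
                           replicateSpec(1, 200, technicalSd = 1,
                                         seed = 2))
  sds <- apply(r1$features, 2, sd)
  expect_true(all(abs(sds - 1) < 0.1))

  expect_error(replicateSpec(technicalSd = -1), "technicalSd")
})

test_that("expression layer bookkeeping and round trip hold", {
  set.seed(31)
  F <- matrix(rnorm(62 * 4), 4, 62,
              dimnames = list(sprintf("S%d", 1:4),
                              sprintf("feat%02d", 1:62)))
  ex <- generateExpressionLayer(F, genesPerSignature = 10,
                                dispersion = 0.05, librarySize = 1e5,
                                seed = 1)
  expect_equal(nrow(ex$counts), 620)
  expect_equal(length(ex$geneSets), 62)
  expect_error(generateExpressionLayer(F, dispersion = 0), "dispersion")
  expect_error(generateExpressionLayer(F, librarySize = -1),
               "librarySize")

  # low dispersion: signature scoring recovers the input features
  set.seed(32)
  G <- matrix(rnorm(80 * 10), 80, 10,
              dimnames = list(sprintf("S%02d", 1:80),
                              sprintf("feat%02d", 1:10)))
  ex2 <- generateExpressionLayer(G, genesPerSignature = 8,
                                 dispersion = 0.005, librarySize = 2e5,
                                 seed = 2)
  sc <- scoreSignatures(normalizeExpression(ex2$counts), ex2$geneSets)
  for (j in seq_len(ncol(G))) {
    expect_gt(cor(G[, j], sc[rownames(G), j]), 0.8)
    expect_gt(cor(G[, j], sc[rownames(G), j], method = "spearman"), 0.8)
  }
})

test_that("comparator marker is a bounded monotone summary", {
  set.seed(21)
  X <- matrix(rnorm(200 * 4), 200, 4)
  # zero weights, zero noise: constant
  cps0 <- generateComparatorMarker(X, rep(0, 4), noiseSd = 0, seed = 1)
  expect_equal(length(unique(cps0)), 1L)
  # always integers within [0, 100]
  cps <- generateComparatorMarker(X, c(1, 0, 0, 0), noiseSd = 1, seed = 2)
  expect_true(all(cps >= 0 & cps <= 100))
  expect_true(all(cps == as.integer(cps)))
  expect_error(generateComparatorMarker(X, c(1, 0), noiseSd = 1),
               "weights")
})

test_that("a noisy comparator discriminates less than the latent score", {
  spec <- cohortSpec(nPatients = 400, nFeatures = 10,
                     informativeIndices = 1:2, effectSizes = c(2, 1.5),
                     seed = 17)
  co <- generateCohort(spec)
  X <- cohortFeatures(co)
  cl <- cohortClinical(co)
  w <- numeric(10); w[1:2] <- c(2, 1.5)
  cps <- generateComparatorMarker(X, w, noiseSd = 5, seed = 18)
  aucCps <- rocAuc(cps, cl$response)$auc
  aucScore <- rocAuc(cl$eta, cl$response)$auc
  expect_gt(aucCps, 0.5)
  expect_lt(aucCps, aucScore)
})
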