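test_that("a class-symmetric feature gets a near-zero coefficient", {
  vals <- c(-2, -1, 0, 1, 2)
  X <- matrix(c(vals, vals), ncol = 1, dimnames = list(NULL, "f1"))
  y <- rep(c(0, 1), each = 5)
  fit <- fitRegularizedLogistic(X, y, C = 1)
  expect_lt(abs(fit@coefficients["f1"]), 1e-6)
})

test_that("the L2 penalty keeps separable fits finite and accurate", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1,
              dimnames = list(NULL, "f1"))
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fitRegularizedLogistic(X, y, C = 10)
  expect_true(is.finite(fit@coefficients["f1"]))
  acc <- mean((predictModelProb(fit, X) > 0.5) == y)
  expect_equal(acc, 1.0)
})

test_that("the Newton fit matches a grid-search maximizer", {
  x <- c(-2, -1, -0.5, 0.5, 1, 2)
  y <- c(0, 0, 1, 0, 1, 1)
  fit <- fitRegularizedLogistic(matrix(x, dimnames = list(NULL, "f1")),
                                y, C = 1)
  oracle <- gridSearchLogistic1D(x, y, C = 1)
  expect_equal(unname(fit@coefficients["f1"]), unname(oracle["coef"]),
               tolerance = 1e-3)
  expect_equal(fit@intercept, unname(oracle["intercept"]),
               tolerance = 1e-3)
})

test_that("fit validation rejects degenerate inputs", {
  X <- matrix(rnorm(10), ncol = 1)
  expect_error(fitRegularizedLogistic(X, rep(1, 10), C = 1),
               "both outcome classes")
  expect_error(fitRegularizedLogistic(X, rep(0:1, 5), C = 0), "C")
  Xna <- X; Xna[1] <- NA
  expect_error(fitRegularizedLogistic(Xna, rep(0:1, 5), C = 1),
               "missing")
})

test_that("shrinking C strictly reduces the coefficient norm", {
  cohort <- makeToyCohort(n = 80, p = 4, effect = 2, seed = 10)
  norms <- vapply(c(4, 1, 0.25), function(C)
    sqrt(sum(fitRegularizedLogistic(cohort$X, cohort$y, C)@coefficients^2)),
    numeric(1))
  expect_true(norms[1] > norms[2])
  expect_true(norms[2] > norms[3])
})

test_that("cross-validated AUC behaves at the extremes", {
  set.seed(20)
  y <- rep(c(0, 1), each = 30)
  # feature equal to the label: perfect held-out ranking
  X <- matrix(as.numeric(y), ncol = 1, dimnames = list(NULL, "f1"))
  expect_equal(cvAUC(X, y, C = 100, seed = 1), 1.0)
  # feature independent of the label: near-chance
  set.seed(21)
  Xn <- matrix(rnorm(400), ncol = 1, dimnames = list(NULL, "f1"))
  yn <- rep(c(0, 1), each = 200)
  aucNull <- cvAUC(Xn, yn, C = 1, seed = 2)
  expect_gt(aucNull, 0.4)
  expect_lt(aucNull, 0.6)
})

test_that("cv AUC is invariant to relabelling the positive class", {
  # refitting on flipped labels flips every held-out probability, so the
  # pooled AUC is unchanged (a fixed score's AUC, by contrast, maps to
  # its complement under label inversion - tested on rocAuc)
  cohort <- makeToyCohort(n = 60, p = 2, effect = 1.5, seed = 30)
  folds <- rep_len(1:5, 60)
  a <- cvAUC(cohort$X, cohort$y, C = 1, folds = folds)
  b <- cvAUC(cohort$X, 1 - cohort$y, C = 1, folds = folds)
  expect_equal(b, a, tolerance = 1e-9)
  expect_gt(a, 0.6)
})

test_that("folds too small to stratify give an actionable error", {
  y <- c(rep(0, 20), rep(1, 3))
  X <- matrix(rnorm(23), ncol = 1)
  expect_error(cvAUC(X, y, C = 1, kFolds = 5), "fewer folds")
})

test_that("forward selection finds the informative feature first", {
  spec <- cohortSpec(nPatients = 300, nFeatures = 10,
                     informativeIndices = 4, effectSizes = 3, seed = 2)
  co <- generateCohort(spec)
  X <- cohortFeatures(co)
  y <- cohortClinical(co)$response
  sel <- forwardSelect(X, y, C = 1, kMax = 2, seed = 5)
  expect_equal(sel$features[1], "feat04")
  # agrees with the exhaustive marginal pair-count AUC ranking
  marginal <- apply(X, 2, function(x)
    max(pairCountAUC(x, y), 1 - pairCountAUC(x, y)))
  expect_equal(names(which.max(marginal)), "feat04")
  # the stepwise AUC path never decreases
  expect_true(all(diff(sel$auc) >= 0))
})

test_that("kMax = 1 returns exactly one feature", {
  cohort <- makeToyCohort(n = 60, p = 4, seed = 40)
  sel <- forwardSelect(cohort$X, cohort$y, C = 1, kMax = 1, seed = 1)
  expect_length(sel$features, 1L)
})

test_that("duplicated informative features: the first listed enters", {
  cohort <- makeToyCohort(n = 120, p = 1, effect = 2.5, seed = 50)
  X <- cbind(fA = cohort$X[, 1], fB = cohort$X[, 1],
             fC = rnorm(120))
  sel <- forwardSelect(X, cohort$y, C = 1, kMax = 3, seed = 3)
  expect_equal(sel$features[1], "fA")
  expect_false("fB" %in% sel$features)
})

test_that("variability pools mean-centered replicate scores (4*std)", {
  # fixed model scoring replicate rows to chosen values via the logit
  mod <- candidateModel("f1", C = 1, coefficients = 1, intercept = 0)
  toScore <- function(s) qlogis(s / 100)
  reps <- matrix(toScore(c(50, 52, 48, 30, 34, 26)), ncol = 1,
                 dimnames = list(NULL, "f1"))
  groups <- rep(c("A", "B"), each = 3)
  v <- evaluateVariability(mod, reps, groups)
  expect_equal(v, 4 * sqrt(8), tolerance = 1e-9)
  expect_equal(round(v, 4), 11.3137)

  # identical replicates: zero variability
  repsSame <- matrix(toScore(rep(40, 6)), ncol = 1,
                     dimnames = list(NULL, "f1"))
  expect_equal(evaluateVariability(mod, repsSame, groups), 0)

  # all-singleton groups are undefined
  expect_error(evaluateVariability(mod, reps, as.character(1:6)),
               "singleton")
})

test_that("final-model selection applies the dual criterion", {
  cand <- list(
    candidateModel("a", C = 1, coefficients = 1, cvAUC = 0.78,
                   variability = 15),
    candidateModel("b", C = 1, coefficients = 1, cvAUC = 0.80,
                   variability = 25),
    candidateModel("c", C = 1, coefficients = 1, cvAUC = 0.77,
                   variability = 10))
  picked <- selectFinalModel(cand)
  expect_equal(picked@cvAUC, 0.78)
  expect_equal(picked@variability, 15)

  # a single feasible candidate is returned as-is
  expect_equal(selectFinalModel(cand[3])@cvAUC, 0.77)

  # infeasible sets raise an explicit error listing the Pareto front
  low <- list(candidateModel("a", C = 1, coefficients = 1, cvAUC = 0.70,
                             variability = 10),
              candidateModel("b", C = 1, coefficients = 1, cvAUC = 0.75,
                             variability = 30))
  expect_error(selectFinalModel(low), "no model meets criteria")
  expect_error(selectFinalModel(low), "Pareto")
})

test_that("selection ties break by variability, size, then C", {
  tie <- list(
    candidateModel(c("a", "b"), C = 2, coefficients = c(1, 1),
                   cvAUC = 0.80, variability = 12),
    candidateModel("a", C = 2, coefficients = 1, cvAUC = 0.80,
                   variability = 8),
    candidateModel("a", C = 1, coefficients = 1, cvAUC = 0.80,
                   variability = 8))
  picked <- selectFinalModel(tie)
  expect_equal(picked@variability, 8)
  expect_equal(picked@C, 1)
  expect_length(picked@features, 1L)
})

test_that("models serialize to plain text and restore exactly", {
  cohort <- makeToyCohort(n = 50, p = 3, seed = 60)
  fit <- fitRegularizedLogistic(cohort$X, cohort$y, C = 0.5)
  fit@cvAUC <- 0.81
  fit@variability <- 9.5
  path <- tempfile(fileext = ".yaml")
  writeModelFile(fit, path)
  back <- readModelFile(path)
  expect_equal(back@coefficients, fit@coefficients, tolerance = 1e-12)
  expect_equal(back@intercept, fit@intercept, tolerance = 1e-12)
  expect_equal(back@C, fit@C)
  expect_equal(predictModelProb(back, cohort$X),
               predictModelProb(fit, cohort$X), tolerance = 1e-12)
})

test_that("candidate building sweeps the grid and scores variability", {
  spec <- cohortSpec(nPatients = 80, nFeatures = 6,
                     informativeIndices = 1, effectSizes = 2.5, seed = 3)
  co <- generateCohort(spec)
  X <- cohortFeatures(co)
  y <- cohortClinical(co)$response
  reps <- generateReplicates(X, replicateSpec(4, 5, technicalSd = 0.1,
                                              seed = 4))
  built <- buildCandidateModels(X, y, Cgrid = c(0.5, 2), kMax = 2,
                                seed = 6, replicates = reps)
  expect_true(length(built$candidates) >= 2)
  expect_true(all(!is.na(built$table$variability_4std)))
  expect_true(all(built$table$cv_auc >= 0 & built$table$cv_auc <= 1))
  expect_equal(nrow(built$table), length(built$candidates))
})
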