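#' Fit an L2-regularized logistic regression
#'
#' Maximizes the penalized log-likelihood
#' \deqn{\ell(w, b) - \frac{1}{2C}\|w\|^2}
#' by Newton-Raphson with step halving; the intercept is unpenalized and
#' \code{C} is the inverse penalty strength (larger C = weaker penalty).
#' Features are standardized internally with the training data's mean and
#' SD, and the standardization constants are stored on the returned model
#' so new samples are scored on the training scale. Convergence requires
#' the gradient norm to fall below \code{tol}.
#'
#' @param X samples x features numeric matrix (no missing values).
#' @param y binary outcome: 0/1 (1 = non-progressor) or outcome labels.
#' @param C inverse regularization strength (> 0).
#' @param standardize standardize columns internally (default TRUE).
#' @param maxIter,tol Newton iteration cap and gradient-norm tolerance.
#' @return a \code{\linkS4class{CandidateModel}}.
#' @export
fitRegularizedLogistic <- function(X, y, C, standardize = TRUE,
                                   maxIter = 100L, tol = 1e-6) {
  X <- as.matrix(X)
  y <- asOutcome01(y)
  if (nrow(X) != length(y))
    failValidation("y", "length must equal nrow(X)")
  if (anyNA(X))
    failValidation("X", "missing feature values are not allowed")
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present to fit", call. = FALSE)
  assertScalar(C, "C", min = 0, strictMin = TRUE)
  p <- ncol(X)
  featNames <- colnames(X)
  if (is.null(featNames)) featNames <- sprintf("x%d", seq_len(p))

  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0 | is.na(scl)] <- 1
  } else {
    center <- rep(0, p)
    scl <- rep(1, p)
  }
  Z <- cbind(1, sweep(sweep(X, 2, center, "-"), 2, scl, "/"))
  pen <- c(0, rep(1 / C, p))

  obj <- function(beta) {
    eta <- drop(Z %*% beta)
    # numerically stable -loglik: log(1+exp(eta)) - y*eta
    -sum(y * eta - log1p(exp(pmin(eta, 35))) -
           pmax(eta - 35, 0)) + 0.5 * sum(pen * beta^2)
  }
  beta <- numeric(p + 1L)
  J <- obj(beta)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    eta <- drop(Z %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(Z, mu - y)) + pen * beta
    if (sqrt(sum(grad^2)) < tol) { converged <- TRUE; break }
    W <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(Z * W, Z) + diag(pen, p + 1L)
    delta <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-8, p + 1L), grad))
    step <- 1
    repeat {
      cand <- beta - step * delta
      Jc <- obj(cand)
      if (is.finite(Jc) && Jc <= J + 1e-12) break
      step <- step / 2
      if (step < 1e-10) { cand <- beta; Jc <- J; break }
    }
    beta <- cand
    J <- Jc
  }
  if (!converged) {
    eta <- drop(Z %*% beta)
    grad <- drop(crossprod(Z, plogis(eta) - y)) + pen * beta
    if (sqrt(sum(grad^2)) >= tol)
      warning("logistic fit did not reach gradient tolerance", call. = FALSE)
  }
  candidateModel(features = featNames, C = C,
                 coefficients = beta[-1L], intercept = beta[1L],
                 center = center, scale = scl)
}

#' Predicted non-progression probability from a fitted model
#'
#' @param model a \code{\linkS4class{CandidateModel}}.
#' @param X samples x features matrix containing at least the model's
#'   features (matched by name when available).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predictModelProb <- function(model, X) {
  X <- as.matrix(X)
  if (!is.null(colnames(X))) {
    miss <- setdiff(model@features, colnames(X))
    if (length(miss))
      stop(sprintf("feature(s) missing from input: %s",
                   paste(miss, collapse = ", ")), call. = FALSE)
    X <- X[, model@features, drop = FALSE]
  } else if (ncol(X) != length(model@features)) {
    stop("unnamed input must have exactly the model's features",
         call. = FALSE)
  }
  Z <- sweep(sweep(X, 2, model@center, "-"), 2, model@scale, "/")
  plogis(drop(model@intercept + Z %*% model@coefficients))
}

# Stratified fold assignment: shuffles each class independently and deals
# round-robin, so folds depend only on (y, kFolds, seed).
stratifiedFolds <- function(y, kFolds, seed) {
  if (min(table(y)) < kFolds)
    stop(sprintf(paste("smallest class has fewer members (%d) than folds",
                       "(%d); use fewer folds"),
                 min(table(y)), kFolds), call. = FALSE)
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in sort(unique(y))) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(kFolds), length(idx))
  }
  fold
}

#' Stratified cross-validated AUC of a feature subset
#'
#' Fits the regularized logistic model on each training split (with
#' training-split standardization) and computes the AUC of the pooled
#' held-out predicted probabilities. Deterministic given \code{seed}.
#'
#' @inheritParams fitRegularizedLogistic
#' @param kFolds number of stratified folds (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param folds optional explicit fold assignment (integer vector in
#'   1..kFolds), overriding the seeded stratified assignment.
#' @return AUC in [0, 1].
#' @export
cvAUC <- function(X, y, C, kFolds = 5L, seed = 1L, folds = NULL) {
  X <- as.matrix(X)
  y <- asOutcome01(y)
  fold <- if (is.null(folds)) stratifiedFolds(y, kFolds, seed)
    else as.integer(folds)
  kFolds <- max(fold)
  for (k in seq_len(kFolds))
    if (length(unique(y[fold == k])) < 2L)
      stop("every fold must contain both classes; use fewer folds",
           call. = FALSE)
  pred <- numeric(length(y))
  for (k in seq_len(kFolds)) {
    test <- fold == k
    fit <- fitRegularizedLogistic(X[!test, , drop = FALSE], y[!test], C)
    pred[test] <- predictModelProb(fit, X[test, , drop = FALSE])
  }
  rocAuc(pred, y)$auc
}

#' Greedy forward feature selection
#'
#' At each step, adds the feature whose inclusion maximizes the stratified
#' cross-validated AUC of the augmented set; ties are broken by panel
#' order (first listed wins). Stops when the best improvement falls below
#' \code{minImprove} or \code{kMax} features are selected. The full path
#' is returned so every prefix is a candidate model.
#'
#' @inheritParams cvAUC
#' @param kMax maximum number of features to select.
#' @param minImprove minimum cv AUC improvement to continue (default
#'   0.001).
#' @return list with \code{features} (ordered selected names) and
#'   \code{auc} (stepwise cv AUC after each addition).
#' @export
forwardSelect <- function(X, y, C, kMax = 10L, seed = 1L,
                          kFolds = 5L, minImprove = 0.001) {
  X <- as.matrix(X)
  y <- asOutcome01(y)
  if (ncol(X) < 1L)
    failValidation("X", "needs at least one feature")
  kMax <- min(kMax, ncol(X))
  featNames <- colnames(X)
  if (is.null(featNames)) {
    featNames <- sprintf("x%d", seq_len(ncol(X)))
    colnames(X) <- featNames
  }
  selected <- character()
  aucPath <- numeric()
  best <- -Inf
  while (length(selected) < kMax) {
    remaining <- setdiff(featNames, selected)
    stepAuc <- vapply(remaining, function(f)
      cvAUC(X[, c(selected, f), drop = FALSE], y, C,
            kFolds = kFolds, seed = seed), numeric(1))
    # first listed wins ties (which.max keeps panel order)
    winner <- remaining[which.max(stepAuc)]
    newBest <- max(stepAuc)
    if (length(selected) && newBest - best < minImprove) break
    selected <- c(selected, winner)
    aucPath <- c(aucPath, newBest)
    best <- newBest
  }
  list(features = selected, auc = aucPath)
}

#' Analytic variability (4*std) of a candidate model
#'
#' Scores every technical replicate with the fixed model (probability x
#' 100), mean-centers the scores within each biological sample, pools all
#' centered values, and returns 4 times their sample standard deviation
#' (ddof = 1). This is the study's single-number analytic-variability
#' metric on the 0-100 score scale.
#'
#' @param model a \code{\linkS4class{CandidateModel}}.
#' @param replicateFeatures replicates x features matrix (or a list as
#'   returned by \code{\link{generateReplicates}}, in which case
#'   \code{groups} is taken from it).
#' @param groups factor/vector labelling each replicate row by its
#'   biological sample.
#' @return 4*std, a non-negative number in score units.
#' @export
evaluateVariability <- function(model, replicateFeatures, groups = NULL) {
  if (is.list(replicateFeatures) && !is.null(replicateFeatures$features)) {
    groups <- replicateFeatures$biologicalSample
    replicateFeatures <- replicateFeatures$features
  }
  replicateFeatures <- as.matrix(replicateFeatures)
  if (is.null(groups) || length(groups) != nrow(replicateFeatures))
    failValidation("groups", "must label every replicate row")
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (all(sizes < 2L))
    stop("all biological samples are singletons; replicate SD is undefined",
         call. = FALSE)
  scores <- 100 * predictModelProb(model, replicateFeatures)
  centered <- scores - ave(scores, groups)
  4 * sd(centered)
}

#' Select the final model under the dual criterion
#'
#' Among candidates with cv AUC >= \code{aucFloor} and 4*std <=
#' \code{variabilityCeiling}, returns the one with maximal cv AUC; ties
#' are broken by smaller variability, then fewer features, then smaller
#' C. If no candidate is feasible, an error lists the Pareto front
#' (candidates not dominated on AUC and variability).
#'
#' @param candidates list of \code{\linkS4class{CandidateModel}} objects
#'   with \code{cvAUC} and \code{variability} populated.
#' @param aucFloor minimum acceptable cv AUC (default 0.76).
#' @param variabilityCeiling maximum acceptable 4*std (default 20).
#' @return the selected \code{CandidateModel}.
#' @export
selectFinalModel <- function(candidates, aucFloor = 0.76,
                             variabilityCeiling = 20) {
  if (!length(candidates))
    stop("empty candidate list", call. = FALSE)
  auc <- vapply(candidates, function(m) m@cvAUC, numeric(1))
  v <- vapply(candidates, function(m) m@variability, numeric(1))
  if (anyNA(auc) || anyNA(v))
    stop("all candidates need both cvAUC and variability populated",
         call. = FALSE)
  feasible <- auc >= aucFloor & v <= variabilityCeiling
  if (!any(feasible)) {
    dominated <- vapply(seq_along(candidates), function(i)
      any(auc > auc[i] & v <= v[i]) || any(auc >= auc[i] & v < v[i]),
      logical(1))
    front <- paste(sprintf("(AUC %.3f, 4*std %.2f, %d features)",
                           auc[!dominated], v[!dominated],
                           vapply(candidates[!dominated], function(m)
                             length(m@features), integer(1))),
                   collapse = "; ")
    stop(sprintf(
      "no model meets criteria (AUC >= %g and 4*std <= %g); Pareto front: %s",
      aucFloor, variabilityCeiling, front), call. = FALSE)
  }
  nf <- vapply(candidates, function(m) length(m@features), integer(1))
  Cs <- vapply(candidates, function(m) m@C, numeric(1))
  ord <- order(-auc, v, nf, Cs)
  ord <- ord[feasible[ord]][1L]
  candidates[[ord]]
}

#' Default regularization grid
#'
#' Seventeen log2-spaced values of the inverse penalty strength C,
#' \code{2^(-10..6)}, spanning roughly 1e-3 to 1e2.
#'
#' @return numeric vector.
#' @export
defaultCGrid <- function() 2^seq(-10, 6)

#' Build candidate biomarkers across the regularization grid
#'
#' For each C in the grid, runs \code{\link{forwardSelect}} and turns
#' every prefix of the selection path into a candidate: the prefix's
#' features are refit on the full data, the stepwise cv AUC is attached,
#' and - when technical replicates are supplied - the 4*std variability is
#' evaluated.
#'
#' @inheritParams forwardSelect
#' @param Cgrid regularization values (default \code{\link{defaultCGrid}}).
#' @param replicates optional list from \code{\link{generateReplicates}}
#'   (or NULL to skip variability scoring).
#' @return list with \code{candidates} (list of
#'   \code{\linkS4class{CandidateModel}}) and \code{table} (one row per
#'   candidate: features, C, cv_auc, variability_4std, feasible flag at
#'   the default criteria).
#' @export
buildCandidateModels <- function(X, y, Cgrid = defaultCGrid(), kMax = 10L,
                                 seed = 1L, kFolds = 5L, minImprove = 0.001,
                                 replicates = NULL) {
  X <- as.matrix(X)
  y <- asOutcome01(y)
  candidates <- list()
  rows <- list()
  for (C in Cgrid) {
    path <- forwardSelect(X, y, C, kMax = kMax, seed = seed,
                          kFolds = kFolds, minImprove = minImprove)
    for (k in seq_along(path$features)) {
      feats <- path$features[seq_len(k)]
      m <- fitRegularizedLogistic(X[, feats, drop = FALSE], y, C)
      m@cvAUC <- path$auc[k]
      if (!is.null(replicates))
        m@variability <- evaluateVariability(m, replicates)
      candidates[[length(candidates) + 1L]] <- m
      rows[[length(rows) + 1L]] <- data.frame(
        features = paste(feats, collapse = ","),
        n_features = k, C = C, cv_auc = m@cvAUC,
        variability_4std = m@variability,
        feasible = !is.na(m@cvAUC) && m@cvAUC >= 0.76 &&
          (is.na(m@variability) || m@variability <= 20),
        stringsAsFactors = FALSE)
    }
  }
  list(candidates = candidates, table = do.call(rbind, rows))
}

#' Serialize / restore a fitted model
#'
#' Writes the model as a plain structured text (YAML) file holding the
#' feature names, coefficients, intercept, C, standardization constants
#' and quality scores, and reads it back.
#'
#' @param model a \code{\linkS4class{CandidateModel}}.
#' @param path file path.
#' @return \code{writeModelFile}: the path, invisibly;
#'   \code{readModelFile}: a \code{CandidateModel}.
#' @export
writeModelFile <- function(model, path) {
  yaml::write_yaml(list(
    features = as.list(model@features),
    coefficients = as.list(unname(model@coefficients)),
    intercept = model@intercept,
    C = model@C,
    center = as.list(unname(model@center)),
    scale = as.list(unname(model@scale)),
    cv_auc = model@cvAUC,
    variability_4std = model@variability
  ), path, precision = 15)
  invisible(path)
}

#' @rdname writeModelFile
#' @export
readModelFile <- function(path) {
  x <- yaml::read_yaml(path)
  candidateModel(
    features = unlist(x$features), C = x$C,
    coefficients = unlist(x$coefficients), intercept = x$intercept,
    center = unlist(x$center), scale = unlist(x$scale),
    cvAUC = if (is.null(x$cv_auc)) NA_real_ else x$cv_auc,
    variability = if (is.null(x$variability_4std)) NA_real_
      else x$variability_4std)
}
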