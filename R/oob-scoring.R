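#' Bootstrap out-of-bag ensemble scores (the 0-100 score)
#'
#' For each of \code{B} bootstrap iterations, \code{n} patients are drawn
#' with replacement and the fixed feature-set logistic model is refit on
#' the draw; every patient absent from the draw (out-of-bag) is scored as
#' 100 x the predicted non-progression probability. Each patient's final
#' score is the mean over their out-of-bag iterations. Resamples
#' containing a single outcome class are redrawn (and counted), keeping
#' exactly B contributing iterations. A single generator is seeded once,
#' and iteration i's resample consumes draws deterministically, so results
#' are reproducible bitwise given \code{seed}, \code{B} and input order.
#'
#' @param X samples x features matrix.
#' @param y binary outcome (1 = non-progressor) or outcome labels.
#' @param features model feature names (columns of X); defaults to all.
#' @param C inverse regularization strength for the per-resample fits.
#' @param B number of bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @return a \code{\linkS4class{ScoreSet}} with scores and out-of-bag
#'   appearance counts (threshold/class/quartile unset); patients never
#'   out-of-bag get an NA score with a warning. The number of redrawn
#'   single-class resamples is available as \code{attr(-, "redraws")} via
#'   the metadata slot-free attribute on the scores vector.
#' @export
bootstrapOobScores <- function(X, y, features = colnames(X), C = 1,
                               B = 1000L, seed = 1L) {
  X <- as.matrix(X)
  y <- asOutcome01(y)
  if (length(B) != 1L || is.na(B) || B < 1)
    failValidation("B", "must be a positive integer")
  B <- as.integer(B)
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  if (is.null(features)) features <- sprintf("x%d", seq_len(ncol(X)))
  if (is.null(colnames(X))) colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  miss <- setdiff(features, colnames(X))
  if (length(miss))
    stop(sprintf("model feature(s) absent from matrix: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  Xm <- X[, features, drop = FALSE]
  n <- nrow(Xm)
  ids <- rownames(Xm)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))

  set.seed(seed)
  scoreSum <- numeric(n)
  appearances <- integer(n)
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      redraws <- redraws + 1L
    }
    oob <- which(!seq_len(n) %in% idx)
    fit <- fitRegularizedLogistic(Xm[idx, , drop = FALSE], y[idx], C)
    if (length(oob)) {
      scoreSum[oob] <- scoreSum[oob] +
        100 * predictModelProb(fit, Xm[oob, , drop = FALSE])
      appearances[oob] <- appearances[oob] + 1L
    }
  }
  scores <- ifelse(appearances > 0L, scoreSum / pmax(appearances, 1L),
                   NA_real_)
  if (any(appearances == 0L))
    warning(sprintf("%d patient(s) never out-of-bag; score is missing",
                    sum(appearances == 0L)), call. = FALSE)
  names(scores) <- ids
  out <- new("ScoreSet", scores = scores, oobAppearances = appearances,
             B = B, predictedClass = rep(NA_character_, n),
             quartile = rep(NA_integer_, n))
  attr(out@scores, "redraws") <- redraws
  out
}

#' Classify patients from their scores
#'
#' Scores strictly above the threshold are predicted non-progressors;
#' scores at or below it are predicted progressors (ties go to
#' progressor). The threshold defaults to the cohort median score, the
#' study's thresholding rule, and can be overridden.
#'
#' @param scores a \code{\linkS4class{ScoreSet}} or numeric score vector
#'   (>= 2 non-missing values).
#' @param threshold classification threshold; default the median of the
#'   non-missing scores.
#' @return for a \code{ScoreSet}, the updated object; for a numeric
#'   vector, a character vector of classes with the threshold as an
#'   attribute.
#' @export
classifyScores <- function(scores, threshold = NULL) {
  isSet <- is(scores, "ScoreSet")
  s <- if (isSet) scores@scores else as.numeric(scores)
  if (sum(!is.na(s)) < 2L)
    stop("need at least 2 scored patients to classify", call. = FALSE)
  if (is.null(threshold)) threshold <- median(s, na.rm = TRUE)
  cls <- ifelse(is.na(s), NA_character_,
                ifelse(s > threshold, "non-progressor", "progressor"))
  if (isSet) {
    scores@threshold <- threshold
    scores@predictedClass <- unname(cls)
    scores
  } else {
    structure(cls, threshold = threshold)
  }
}

#' Assign score quartiles
#'
#' Patients are ranked by score and split into 4 contiguous groups of
#' size ceiling(n/4) or floor(n/4), larger groups first (lowest scores =
#' quartile 1). Ties are broken by stable input order. The three score
#' boundaries between groups are reported.
#'
#' @param scores a \code{\linkS4class{ScoreSet}} or numeric vector of at
#'   least 4 scores.
#' @return for a \code{ScoreSet}, the updated object; for a numeric
#'   vector, an integer quartile vector with a \code{breaks} attribute
#'   (the maximum score in quartiles 1-3).
#' @export
assignQuartiles <- function(scores) {
  isSet <- is(scores, "ScoreSet")
  s <- if (isSet) scores@scores else as.numeric(scores)
  ok <- which(!is.na(s))
  n <- length(ok)
  if (n < 4L)
    stop("need at least 4 scored patients for quartiles", call. = FALSE)
  base <- n %/% 4L
  sizes <- rep(base, 4L)
  extra <- n %% 4L
  if (extra > 0L) sizes[seq_len(extra)] <- base + 1L
  ord <- ok[order(s[ok], seq_along(s)[ok])]
  q <- rep(NA_integer_, length(s))
  q[ord] <- rep(1:4, times = sizes)
  breaks <- vapply(1:3, function(g) max(s[ord][rep(1:4, sizes) == g]),
                   numeric(1))
  if (isSet) {
    scores@quartile <- unname(q)
    scores@quartileBreaks <- breaks
    scores
  } else {
    structure(q, breaks = breaks)
  }
}
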