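#' @import methods
#' @importFrom stats median sd quantile rnorm rbinom rexp rnbinom pnorm
#'   plogis qlogis uniroot fisher.test pchisq qnorm runif ave rweibull
NULL

#' CandidateModel: a fitted candidate biomarker
#'
#' A candidate biomarker is an ordered subset of panel features together with
#' an L2 regularization setting \code{C} (inverse penalty strength), the
#' fitted logistic coefficients on standardized features, the
#' cross-validated AUC used during forward selection, and the analytic
#' variability of its 0-100 scores on technical replicates (the 4*std
#' metric). Variability is \code{NA} until \code{\link{evaluateVariability}}
#' has been run.
#'
#' @slot features character, ordered selected feature names.
#' @slot C numeric(1), inverse regularization strength (larger = weaker
#'   penalty).
#' @slot coefficients numeric, per-feature log-odds coefficients on the
#'   standardized scale, named by feature.
#' @slot intercept numeric(1), unpenalized intercept (log-odds).
#' @slot center,scale numeric, standardization constants recorded at fit
#'   time so the model can score new samples.
#' @slot cvAUC numeric(1), stratified cross-validation AUC in [0, 1].
#' @slot variability numeric(1), 4*std of replicate scores (0-100 scale);
#'   \code{NA} if not yet evaluated.
#'
#' @seealso \code{\link{fitRegularizedLogistic}}, \code{\link{forwardSelect}},
#'   \code{\link{selectFinalModel}}
#' @export
setClass("CandidateModel",
  representation(
    features = "character",
    C = "numeric",
    coefficients = "numeric",
    intercept = "numeric",
    center = "numeric",
    scale = "numeric",
    cvAUC = "numeric",
    variability = "numeric"
  ),
  prototype(C = 1, intercept = 0, cvAUC = NA_real_,
            variability = NA_real_)
)

#' Construct a CandidateModel
#'
#' @param features ordered feature names.
#' @param C inverse regularization strength.
#' @param coefficients per-feature coefficients (standardized scale).
#' @param intercept intercept (log-odds).
#' @param center,scale standardization constants (default identity).
#' @param cvAUC,variability quality scores (default NA, not yet
#'   evaluated).
#' @return a validated \code{CandidateModel}.
#' @export
candidateModel <- function(features, C, coefficients, intercept = 0,
                           center = NULL, scale = NULL,
                           cvAUC = NA_real_, variability = NA_real_) {
  features <- as.character(features)
  obj <- new("CandidateModel")
  obj@features <- features
  obj@C <- as.numeric(C)
  obj@coefficients <- structure(as.numeric(coefficients),
                                names = features)
  obj@intercept <- as.numeric(intercept)
  obj@center <- structure(
    if (is.null(center)) numeric(length(features)) else as.numeric(center),
    names = features)
  obj@scale <- structure(
    if (is.null(scale)) rep(1, length(features)) else as.numeric(scale),
    names = features)
  obj@cvAUC <- as.numeric(cvAUC)
  obj@variability <- as.numeric(variability)
  validObject(obj)
  obj
}

setValidity("CandidateModel", function(object) {
  msg <- character()
  if (length(object@coefficients) != length(object@features))
    msg <- c(msg, "number of coefficients must equal number of features")
  if (length(object@C) != 1L || is.na(object@C) || object@C <= 0)
    msg <- c(msg, "C must be a single positive number")
  if (!is.na(object@cvAUC) && (object@cvAUC < 0 || object@cvAUC > 1))
    msg <- c(msg, "cvAUC must lie in [0, 1]")
  if (!is.na(object@variability) && object@variability < 0)
    msg <- c(msg, "variability (4*std) must be non-negative")
  if (length(msg)) msg else TRUE
})

#' ScoreSet: per-patient ensemble scores
#'
#' Holds the bootstrap out-of-bag ensemble score (0-100) for each patient,
#' the number of bootstrap iterations in which the patient was out-of-bag,
#' and - once \code{\link{classifyScores}} / \code{\link{assignQuartiles}}
#' have been applied - the classification threshold, predicted class and
#' score quartile.
#'
#' @slot scores numeric, per-patient score in [0, 100], named by sample id.
#' @slot oobAppearances integer, per-patient count of out-of-bag
#'   appearances over the B bootstrap iterations.
#' @slot B integer(1), number of bootstrap iterations.
#' @slot threshold numeric(1), classification threshold (NA before
#'   classification).
#' @slot predictedClass character, "progressor" / "non-progressor" per
#'   patient (NA before classification).
#' @slot quartile integer, 1 (lowest scores) to 4 (NA before assignment).
#' @slot quartileBreaks numeric, the three score boundaries between the
#'   quartile groups.
#'
#' @seealso \code{\link{bootstrapOobScores}}
#' @export
setClass("ScoreSet",
  representation(
    scores = "numeric",
    oobAppearances = "integer",
    B = "integer",
    threshold = "numeric",
    predictedClass = "character",
    quartile = "integer",
    quartileBreaks = "numeric"
  ),
  prototype(threshold = NA_real_, predictedClass = character(),
            quartile = integer(), quartileBreaks = numeric())
)

setValidity("ScoreSet", function(object) {
  msg <- character()
  s <- object@scores[!is.na(object@scores)]
  if (length(s) && (min(s) < 0 || max(s) > 100))
    msg <- c(msg, "scores must lie in [0, 100]")
  if (length(object@oobAppearances) != length(object@scores))
    msg <- c(msg, "every patient must have an oobAppearances entry")
  if (length(object@quartileBreaks) && is.unsorted(object@quartileBreaks))
    msg <- c(msg, "quartile boundaries must be ordered")
  if (length(msg)) msg else TRUE
})

#' ConfusionMatrix: 2x2 classification counts
#'
#' The positive class is "non-progressor" (disease control), so TP counts
#' patients predicted and observed to be non-progressors.
#'
#' @slot tp,fp,fn,tn integer(1) counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 tn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  counts <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(is.na(counts)) || any(counts < 0))
    return("all confusion counts must be non-negative")
  if (sum(counts) < 1)
    return("confusion matrix must contain at least one sample")
  TRUE
})

setMethod("show", "CandidateModel", function(object) {
  cat("CandidateModel:", length(object@features), "feature(s), C =",
      format(object@C), "\n")
  cat("  features:", paste(object@features, collapse = ", "), "\n")
  cat("  cvAUC:", ifelse(is.na(object@cvAUC), "not evaluated",
                         format(round(object@cvAUC, 4))),
      " 4*std:", ifelse(is.na(object@variability), "not evaluated",
                        format(round(object@variability, 4))), "\n")
})

setMethod("show", "ScoreSet", function(object) {
  cat("ScoreSet:", length(object@scores), "patients, B =", object@B, "\n")
  ok <- !is.na(object@scores)
  if (any(ok))
    cat("  score range:", paste(format(round(range(object@scores[ok]), 1)),
                                collapse = " - "), "\n")
  if (!is.na(object@threshold))
    cat("  threshold:", format(round(object@threshold, 1)), "(",
        sum(object@predictedClass == "progressor", na.rm = TRUE),
        "predicted progressors /",
        sum(object@predictedClass == "non-progressor", na.rm = TRUE),
        "non-progressors )\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(predicted = c("non-progressor", "progressor"),
                              actual = c("non-progressor", "progressor")))
  cat("ConfusionMatrix (positive class = non-progressor):\n")
  print(m)
})

## ---- accessors ----

#' @describeIn CandidateModel ordered selected feature names
#' @param object a \code{CandidateModel} or \code{ScoreSet}
#' @export
selectedFeatures <- function(object) object@features

#' @describeIn CandidateModel cross-validated AUC
#' @export
modelAUC <- function(object) object@cvAUC

#' @describeIn CandidateModel analytic variability (4*std); NA if not
#'   evaluated
#' @export
variability4std <- function(object) object@variability

#' @describeIn ScoreSet named numeric vector of 0-100 scores
#' @export
patientScores <- function(object) object@scores

#' @describeIn ScoreSet classification threshold
#' @export
scoreThreshold <- function(object) object@threshold

#' @describeIn ScoreSet predicted classes
#' @export
predictedClass <- function(object) {
  structure(object@predictedClass, names = names(object@scores))
}

#' @describeIn ScoreSet per-patient out-of-bag appearance counts
#' @export
oobAppearances <- function(object) {
  structure(object@oobAppearances, names = names(object@scores))
}

#' @describeIn ScoreSet score quartile (1 = lowest) per patient
#' @export
scoreQuartile <- function(object) {
  structure(object@quartile, names = names(object@scores))
}

#' ScoreSet as a data.frame
#'
#' @param object a \code{ScoreSet}
#' @return data.frame with sample_id, score, oob_appearances,
#'   predicted_class, quartile.
#' @export
scoreTable <- function(object) {
  stopifnot(is(object, "ScoreSet"))
  data.frame(
    sample_id = names(object@scores),
    score = unname(object@scores),
    oob_appearances = unname(object@oobAppearances),
    predicted_class = if (length(object@predictedClass))
      unname(object@predictedClass) else NA_character_,
    quartile = if (length(object@quartile)) unname(object@quartile)
      else NA_integer_,
    stringsAsFactors = FALSE
  )
}

#' Confusion counts as a named vector
#'
#' @param object a \code{ConfusionMatrix}
#' @return named integer vector (TP, FP, FN, TN), positive class =
#'   non-progressor.
#' @export
confusionCounts <- function(object) {
  stopifnot(is(object, "ConfusionMatrix"))
  c(TP = object@tp, FP = object@fp, FN = object@fn, TN = object@tn)
}
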