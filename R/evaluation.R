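#' Build a confusion matrix
#'
#' The positive class is "non-progressor" (disease control) throughout:
#' TP = predicted and actual non-progressor, TN = predicted and actual
#' progressor.
#'
#' @param predicted,actual equal-length vectors of outcome labels
#'   ("non-progressor"/"progressor") or 0/1 with 1 = non-progressor; no
#'   missing entries.
#' @return a \code{\linkS4class{ConfusionMatrix}}.
#' @export
confusion <- function(predicted, actual) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have the same length", call. = FALSE)
  if (anyNA(predicted) || anyNA(actual))
    stop("missing entries are not allowed", call. = FALSE)
  p <- asOutcome01(predicted)
  a <- asOutcome01(actual)
  new("ConfusionMatrix",
      tp = sum(p == 1L & a == 1L), fp = sum(p == 1L & a == 0L),
      fn = sum(p == 0L & a == 1L), tn = sum(p == 0L & a == 0L))
}

#' @rdname confusion
#' @param tp,fp,fn,tn direct counts, as an alternative entry point.
#' @export
confusionFromCounts <- function(tp, fp, fn, tn) {
  new("ConfusionMatrix", tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), tn = as.integer(tn))
}

#' The 11 diagnostic test metrics
#'
#' Computes accuracy, sensitivity, specificity, prevalence, FPR, FNR,
#' PPV, NPV, LR+, LR- and the diagnostic odds ratio from a confusion
#' matrix, at full precision. Zero denominators yield NA values flagged in
#' the \code{undefined} attribute, never errors. The internal identities
#' FNR = 1 - sensitivity, FPR = 1 - specificity and
#' DOR = (TP*TN)/(FP*FN) hold exactly.
#'
#' @param cm a \code{\linkS4class{ConfusionMatrix}}.
#' @return named numeric vector of the 11 metrics with attribute
#'   \code{undefined} naming any metric with a zero denominator.
#' @export
diagnosticMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  tp <- cm@tp; fp <- cm@fp; fn <- cm@fn; tn <- cm@tn
  n <- tp + fp + fn + tn
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- frac(tp, tp + fn)
  spec <- frac(tn, tn + fp)
  m <- c(
    accuracy = frac(tp + tn, n),
    sensitivity = sens,
    specificity = spec,
    prevalence = frac(tp + fn, n),
    fpr = if (is.na(spec)) NA_real_ else 1 - spec,
    fnr = if (is.na(sens)) NA_real_ else 1 - sens,
    ppv = frac(tp, tp + fp),
    npv = frac(tn, tn + fn),
    lr_plus = if (is.na(sens) || is.na(spec) || spec == 1) NA_real_
      else sens / (1 - spec),
    lr_minus = if (is.na(sens) || is.na(spec) || spec == 0) NA_real_
      else (1 - sens) / spec,
    dor = if (fp == 0 || fn == 0) NA_real_ else (tp * tn) / (fp * fn)
  )
  attr(m, "undefined") <- names(m)[is.na(m)]
  m
}

#' Reconstruct an integer confusion matrix from rounded metrics
#'
#' Exhaustively searches all integer (TP, FP, FN, TN) with total \code{n}
#' for the matrix whose prevalence, sensitivity and specificity round
#' (half-up) to the printed values. Errors if no matrix or more than one
#' matrix satisfies the roundings (listing the solutions), so a unique
#' return is guaranteed to be exact. This converts a published rounded
#' metric table into exact integer counts.
#'
#' @param n total sample count.
#' @param prevalence,sensitivity,specificity the printed (rounded)
#'   values.
#' @param decimals decimals the printed values were rounded to (default
#'   2).
#' @return a \code{\linkS4class{ConfusionMatrix}}.
#' @export
reconstructConfusion <- function(n, prevalence, sensitivity, specificity,
                                 decimals = 2) {
  assertScalar(n, "n", min = 1)
  n <- as.integer(n)
  pos <- 0:n
  pos <- pos[roundHalfUp(pos / n, decimals) == prevalence]
  sols <- list()
  for (P in pos) {
    if (P == 0L) next  # sensitivity undefined for an empty positive class
    Ng <- n - P
    if (Ng == 0L) next
    tp <- (0:P)[roundHalfUp((0:P) / P, decimals) == sensitivity]
    tn <- (0:Ng)[roundHalfUp((0:Ng) / Ng, decimals) == specificity]
    for (t1 in tp) for (t2 in tn)
      sols[[length(sols) + 1L]] <- c(tp = t1, fp = Ng - t2, fn = P - t1,
                                     tn = t2)
  }
  if (!length(sols))
    stop(sprintf(
      "no integer confusion matrix with n = %d matches (prev %s, sens %s, spec %s)",
      n, prevalence, sensitivity, specificity), call. = FALSE)
  if (length(sols) > 1L)
    stop(sprintf("ambiguous reconstruction; %d matrices match: %s",
                 length(sols),
                 paste(vapply(sols, function(s)
                   sprintf("(%d,%d,%d,%d)", s["tp"], s["fp"], s["fn"],
                           s["tn"]), character(1)), collapse = " ")),
         call. = FALSE)
  s <- sols[[1L]]
  confusionFromCounts(s["tp"], s["fp"], s["fn"], s["tn"])
}

#' Per-group outcome rates (DCR / ORR)
#'
#' @param success per-group success counts (e.g. disease-control counts),
#'   named by group.
#' @param size per-group totals.
#' @return data.frame with group, successes, size, rate, and the
#'   whole-percent display value (half-up).
#' @export
groupRate <- function(success, size) {
  if (length(success) != length(size) || !length(success))
    failValidation("success/size", "must be equal-length and non-empty")
  if (any(size < 0) || any(success < 0) || any(success > size))
    failValidation("success/size", "need 0 <= successes <= size")
  grp <- names(success)
  if (is.null(grp)) grp <- as.character(seq_along(success))
  rate <- ifelse(size == 0, NA_real_, success / size)
  data.frame(group = grp, successes = as.integer(success),
             size = as.integer(size), rate = rate,
             display_pct = roundHalfUp(rate * 100, 0),
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Exact hypergeometric two-sided p-value (sum of tables at most as
#' probable as the observed one).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return the two-sided p-value.
#' @export
fisher2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    failValidation("table", "must be 2x2")
  if (any(is.na(table)) || any(table < 0) || any(table != round(table)))
    failValidation("table", "cells must be non-negative integers")
  stats::fisher.test(matrix(as.integer(table), 2, 2))$p.value
}

#' Relative risk with log-normal confidence interval
#'
#' RR = (a/n1) / (b/n2) with the standard log-scale Wald interval; the
#' association p-value is the Fisher exact test on the underlying 2x2
#' table.
#'
#' @param a,n1 event count and size in group 1.
#' @param b,n2 event count and size in group 2.
#' @param conf confidence level (default 0.95).
#' @return list with \code{rr}, \code{ci} (length 2), \code{p}. A
#'   zero-rate reference group yields \code{rr = Inf} flagged via
#'   \code{infinite = TRUE}.
#' @export
relativeRisk <- function(a, n1, b, n2, conf = 0.95) {
  if (n1 < 1 || n2 < 1)
    failValidation("n1/n2", "both groups must be non-empty")
  p <- fisher2x2(matrix(c(a, n1 - a, b, n2 - b), 2, 2, byrow = TRUE))
  if (b == 0)
    return(list(rr = Inf, ci = c(NA_real_, NA_real_), p = p,
                infinite = TRUE))
  rr <- (a / n1) / (b / n2)
  if (a == 0)
    return(list(rr = 0, ci = c(NA_real_, NA_real_), p = p,
                infinite = FALSE))
  se <- sqrt(1 / a - 1 / n1 + 1 / b - 1 / n2)
  zq <- qnorm(1 - (1 - conf) / 2)
  list(rr = rr, ci = exp(log(rr) + c(-1, 1) * zq * se), p = p,
       infinite = FALSE)
}

#' ROC curve and AUC (Mann-Whitney, ties count one half)
#'
#' The AUC equals the Mann-Whitney pair-ordering probability: the
#' fraction of (positive, negative) pairs ranked correctly, ties counted
#' 1/2. The curve reports TPR/FPR at every distinct threshold.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary outcome (1 = positive class = non-progressor) or
#'   labels.
#' @return list with \code{auc} and \code{curve} (data.frame: threshold,
#'   tpr, fpr).
#' @export
rocAuc <- function(scores, labels) {
  y <- asOutcome01(labels)
  scores <- as.numeric(scores)
  if (length(scores) != length(y))
    failValidation("scores", "length must match labels")
  if (anyNA(scores))
    failValidation("scores", "missing scores are not allowed")
  np <- sum(y == 1L)
  nn <- sum(y == 0L)
  if (np == 0L || nn == 0L)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)  # midranks handle ties as 1/2
  auc <- (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)

  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1L) / np, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0L) / nn, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr),
                      fpr = c(0, fpr))
  list(auc = auc, curve = curve)
}

#' Per-quartile disease control rates
#'
#' Computes the DCR within each score quartile and tests each quartile
#' against its complement with a Fisher exact test (unadjusted, starred
#' at 0.05 / 0.01 / 0.001).
#'
#' @param quartile integer quartile per patient (1-4), e.g. from
#'   \code{\link{assignQuartiles}}.
#' @param outcome binary disease-control outcome (1 = non-progressor) or
#'   labels.
#' @return data.frame: quartile, successes, size, rate, pooled rate,
#'   fisher p, stars.
#' @export
quartileDcr <- function(quartile, outcome) {
  y <- asOutcome01(outcome)
  if (length(quartile) != length(y))
    failValidation("quartile", "length must match outcome")
  keep <- !is.na(quartile)
  quartile <- quartile[keep]; y <- y[keep]
  pooled <- mean(y)
  rows <- lapply(sort(unique(quartile)), function(q) {
    inQ <- quartile == q
    a <- sum(y[inQ]); nq <- sum(inQ)
    b <- sum(y[!inQ]); nc <- sum(!inQ)
    p <- fisher2x2(matrix(c(a, nq - a, b, nc - b), 2, 2, byrow = TRUE))
    data.frame(quartile = q, successes = a, size = nq, rate = a / nq,
               pooled_rate = pooled, fisher_p = p,
               stars = if (p < 0.001) "***" else if (p < 0.01) "**"
                 else if (p < 0.05) "*" else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Head-to-head comparison of two predictors
#'
#' Reports each test's full metric table, the concordant-sample count,
#' and - among discordant samples, where exactly one test errs - each
#' test's false positives and false negatives. Sensitivities are compared
#' by an unpaired Fisher exact test on correct/incorrect counts among
#' actual positives, specificities likewise among actual negatives. This
#' correct/incorrect construction is this package's reading of a Fisher
#' comparison of sensitivities; published comparisons built differently
#' will not match its p-values.
#'
#' @param predA,predB predicted classes from the two tests.
#' @param actual observed classes.
#' @return list: \code{metricsA}, \code{metricsB}, \code{concordant},
#'   \code{n}, \code{discordant} (count), \code{discordantErrors}
#'   (fp/fn per test among discordant samples),
#'   \code{sensitivityComparison}, \code{specificityComparison} (each a
#'   list with the 2x2 table and p).
#' @export
comparePredictors <- function(predA, predB, actual) {
  if (length(predA) != length(actual) || length(predB) != length(actual))
    stop("all inputs must have the same length", call. = FALSE)
  a <- asOutcome01(predA); b <- asOutcome01(predB); y <- asOutcome01(actual)
  cmA <- confusion(a, y)
  cmB <- confusion(b, y)
  conc <- a == b
  disc <- !conc
  errors <- function(pred) c(
    fp = sum(disc & pred == 1L & y == 0L),
    fn = sum(disc & pred == 0L & y == 1L))
  fisherOn <- function(mask) {
    tab <- matrix(c(sum(a[mask] == y[mask]), sum(a[mask] != y[mask]),
                    sum(b[mask] == y[mask]), sum(b[mask] != y[mask])),
                  2, 2, byrow = TRUE,
                  dimnames = list(test = c("A", "B"),
                                  result = c("correct", "incorrect")))
    list(table = tab, p = fisher2x2(tab))
  }
  list(
    metricsA = diagnosticMetrics(cmA),
    metricsB = diagnosticMetrics(cmB),
    n = length(y),
    concordant = sum(conc),
    discordant = sum(disc),
    discordantErrors = list(A = errors(a), B = errors(b)),
    sensitivityComparison = fisherOn(y == 1L),
    specificityComparison = fisherOn(y == 0L)
  )
}
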