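test_that("confusion counts follow the non-progressor-positive convention", {
  np <- "non-progressor"; p <- "progressor"
  # perfect agreement
  cm <- confusion(c(np, p, np), c(np, p, np))
  expect_equal(unname(confusionCounts(cm)), c(2L, 0L, 0L, 1L))
  # complete disagreement
  cm2 <- confusion(c(np, p), c(p, np))
  expect_equal(confusionCounts(cm2)[["TP"]], 0L)
  expect_equal(confusionCounts(cm2)[["TN"]], 0L)
  # 4-sample toy
  cm3 <- confusion(c(np, np, p, p), c(np, p, p, np))
  expect_equal(unname(confusionCounts(cm3)), c(1L, 1L, 1L, 1L))
  expect_error(confusion(c(np, p), np), "length")
  expect_error(confusion(c(np, NA), c(np, p)), "missing")
})

test_that("diagnostic metrics reproduce both published columns at 2 dp", {
  biomarker <- diagnosticMetrics(confusionFromCounts(33, 18, 9, 43))
  expect_equal(TIMEscore:::roundHalfUp(unname(biomarker[
    c("accuracy", "sensitivity", "specificity", "prevalence", "fpr",
      "fnr", "ppv", "npv", "lr_plus", "lr_minus", "dor")]), 2),
    c(0.74, 0.79, 0.70, 0.41, 0.30, 0.21, 0.65, 0.83, 2.66, 0.30, 8.76))

  ihc <- diagnosticMetrics(confusionFromCounts(25, 24, 14, 37))
  expect_equal(TIMEscore:::roundHalfUp(unname(ihc[
    c("accuracy", "sensitivity", "specificity", "prevalence", "fpr",
      "fnr", "ppv", "npv", "lr_plus", "lr_minus", "dor")]), 2),
    c(0.62, 0.64, 0.61, 0.39, 0.39, 0.36, 0.51, 0.73, 1.63, 0.59, 2.75))
})

test_that("degenerate confusion cells are flagged, not fatal", {
  m <- diagnosticMetrics(confusionFromCounts(0, 0, 0, 10))
  expect_true(is.na(m["sensitivity"]))
  expect_equal(unname(m["specificity"]), 1.0)
  expect_true("sensitivity" %in% attr(m, "undefined"))
})

test_that("metric identities hold exactly for random matrices", {
  set.seed(100)
  for (i in 1:50) {
    cm <- randomConfusion()
    cc <- confusionCounts(cm)
    m <- diagnosticMetrics(cm)
    if (!is.na(m["sensitivity"]))
      expect_equal(unname(m["fnr"]), 1 - unname(m["sensitivity"]))
    if (!is.na(m["specificity"]))
      expect_equal(unname(m["fpr"]), 1 - unname(m["specificity"]))
    if (!is.na(m["dor"]))
      expect_equal(unname(m["dor"]),
                   (cc[["TP"]] * cc[["TN"]]) / (cc[["FP"]] * cc[["FN"]]))
    if (!is.na(m["dor"]) && !is.na(m["lr_plus"]) && !is.na(m["lr_minus"]))
      expect_equal(unname(m["dor"]),
                   unname(m["lr_plus"] / m["lr_minus"]))
  }
})

test_that("confusion reconstruction recovers exact integer counts", {
  cm <- reconstructConfusion(103, 0.41, 0.79, 0.70)
  expect_equal(unname(confusionCounts(cm)), c(33L, 18L, 9L, 43L))
  cm2 <- reconstructConfusion(100, 0.39, 0.64, 0.61)
  expect_equal(unname(confusionCounts(cm2)), c(25L, 24L, 14L, 37L))
  cm3 <- reconstructConfusion(10, 0.50, 1.00, 1.00)
  expect_equal(unname(confusionCounts(cm3)), c(5L, 0L, 0L, 5L))
  expect_error(reconstructConfusion(3, 0.41, 0.79, 0.70), "no integer")
  # coarse inputs at small n are ambiguous, and say so
  expect_error(reconstructConfusion(200, 0.5, 0.5, 0.5, decimals = 1),
               "ambiguous")
})

test_that("reconstruction round-trips random matrices or flags ambiguity", {
  set.seed(101)
  for (i in 1:400) {
    cm <- randomConfusion(200)
    cc <- confusionCounts(cm)
    if (cc[["TP"]] + cc[["FN"]] == 0 || cc[["FP"]] + cc[["TN"]] == 0)
      next  # prevalence 0/1: sensitivity or specificity undefined
    m <- diagnosticMetrics(cm)
    n <- sum(cc)
    res <- tryCatch(
      reconstructConfusion(n,
                           TIMEscore:::roundHalfUp(m[["prevalence"]], 2),
                           TIMEscore:::roundHalfUp(m[["sensitivity"]], 2),
                           TIMEscore:::roundHalfUp(m[["specificity"]], 2)),
      error = function(e) e)
    if (is(res, "error")) {
      expect_match(conditionMessage(res), "ambiguous")
    } else {
      expect_equal(confusionCounts(res), cc)
    }
  }
})

test_that("group rates display as whole percents", {
  gr <- groupRate(c(nonprog = 33, prog = 9), c(51, 52))
  expect_equal(gr$rate, c(33 / 51, 9 / 52), tolerance = 1e-12)
  expect_equal(gr$display_pct, c(65, 17))
  expect_equal(groupRate(0, 7)$rate, 0)
  expect_error(groupRate(5, 3), "success")
})

test_that("Fisher exact p-values match enumeration", {
  expect_equal(fisher2x2(matrix(c(3, 1, 1, 3), 2, 2)), 0.4857143,
               tolerance = 1e-6)
  expect_equal(fisher2x2(matrix(c(5, 0, 0, 5), 2, 2)), 2 / 252,
               tolerance = 1e-9)
  expect_equal(fisher2x2(matrix(c(4, 6, 4, 6), 2, 2, byrow = TRUE)), 1.0)
  expect_error(fisher2x2(matrix(c(-1, 1, 1, 1), 2, 2)), "non-negative")
})

test_that("relative risk and its interval behave", {
  rr <- relativeRisk(43, 52, 18, 51)
  expect_equal(rr$rr, (43 / 52) / (18 / 51), tolerance = 1e-12)
  expect_equal(round(rr$rr, 2), 2.34)
  expect_lt(rr$p, 0.001)
  expect_true(rr$ci[1] < rr$rr && rr$rr < rr$ci[2])

  expect_equal(relativeRisk(5, 10, 5, 10)$rr, 1.0)
  expect_equal(relativeRisk(10, 10, 5, 10)$rr, 2.0)
  z <- relativeRisk(3, 10, 0, 10)
  expect_true(is.infinite(z$rr) && z$infinite)
})

test_that("ROC AUC equals brute-force pair counting", {
  expect_equal(rocAuc(c(10, 20, 30, 40), c(0, 1, 0, 1))$auc, 0.75)
  # perfectly separated and all-tied extremes
  expect_equal(rocAuc(c(1, 2, 3, 9, 10), c(0, 0, 0, 1, 1))$auc, 1.0)
  expect_equal(rocAuc(rep(5, 8), rep(c(0, 1), 4))$auc, 0.5)
  set.seed(102)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(1:8, n, replace = TRUE)  # heavy ties
    expect_equal(rocAuc(s, y)$auc, pairCountAUC(s, y))
  }
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
  # a fixed score's AUC maps to its complement under label inversion
  set.seed(105)
  s2 <- rnorm(30); y2 <- rep(c(0, 1), 15)
  expect_equal(rocAuc(s2, 1 - y2)$auc, 1 - rocAuc(s2, y2)$auc)
})

test_that("ROC curve steps from (0,0) to (1,1) monotonically", {
  set.seed(103)
  y <- rbinom(40, 1, 0.4); y[1:2] <- c(0, 1)
  s <- rnorm(40)
  curve <- rocAuc(s, y)$curve
  expect_equal(curve$tpr[1], 0)
  expect_equal(curve$fpr[1], 0)
  expect_equal(curve$tpr[nrow(curve)], 1)
  expect_equal(curve$fpr[nrow(curve)], 1)
  expect_true(all(diff(curve$tpr) >= 0))
  expect_true(all(diff(curve$fpr) >= 0))
})

test_that("quartile DCR tests each quartile against its complement", {
  # identical outcomes: every quartile equals the pooled rate, p = 1
  q <- rep(1:4, each = 5)
  res <- quartileDcr(q, rep(1, 20))
  expect_true(all(res$rate == 1))
  expect_true(all(res$pooled_rate == 1))
  expect_true(all(res$fisher_p == 1))

  # an enriched quartile reaches significance
  outcome <- c(rep(1, 16), rep(0, 9),       # quartile 1: 16/25
               rep(1, 26), rep(0, 52))      # complement: 26/78
  qq <- c(rep(1, 25), rep(2:4, length.out = 78))
  res2 <- quartileDcr(qq, outcome)
  expect_lt(res2$fisher_p[1], 0.05)
  expect_equal(res2$successes[1], 16)
  expect_true(res2$stars[1] != "")
})

test_that("predictor comparison accounts for every discordant sample", {
  np <- "non-progressor"; p <- "progressor"
  actual <- rep(c(np, p), each = 10)
  predA <- actual
  # A equals B: full concordance, no discordant errors
  same <- comparePredictors(predA, predA, actual)
  expect_equal(same$concordant, 20L)
  expect_equal(sum(unlist(same$discordantErrors)), 0L)

  # random predictions: discordant errors partition the discordant set
  set.seed(104)
  for (i in 1:20) {
    a <- sample(c(np, p), 30, replace = TRUE)
    b <- sample(c(np, p), 30, replace = TRUE)
    act <- sample(c(np, p), 30, replace = TRUE)
    cmp <- comparePredictors(a, b, act)
    expect_equal(sum(unlist(cmp$discordantErrors)), cmp$discordant)
    expect_equal(cmp$concordant + cmp$discordant, 30L)
  }
  expect_error(comparePredictors(predA[1:3], predA, actual), "length")
})
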