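# Independent oracles used to cross-check the package's implementations.
# These deliberately use the most naive correct formulation available.

# AUC by explicit pair counting (ties count one half).
pairCountAUC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Penalized logistic log-likelihood objective on the standardized scale.
penalizedLoglik <- function(b0, b1, x, y, C) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta))) - b1^2 / (2 * C)
}

# 1-D penalized-logistic maximizer by iterative grid refinement over
# (intercept, slope); independent of Newton's method.
gridSearchLogistic1D <- function(x, y, C, rounds = 5) {
  xs <- (x - mean(x)) / sd(x)
  b0r <- c(-6, 6); b1r <- c(-6, 6)
  best <- c(0, 0)
  for (r in seq_len(rounds)) {
    g0 <- seq(b0r[1], b0r[2], length.out = 41)
    g1 <- seq(b1r[1], b1r[2], length.out = 41)
    ll <- outer(g0, g1, Vectorize(function(a, b)
      penalizedLoglik(a, b, xs, y, C)))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(g0[ij[1]], g1[ij[2]])
    w0 <- diff(b0r) / 40; w1 <- diff(b1r) / 40
    b0r <- best[1] + c(-w0, w0)
    b1r <- best[2] + c(-w1, w1)
  }
  c(intercept = best[1], coef = best[2])
}

# 1-D Cox partial log-likelihood (no ties) maximized by grid refinement.
gridSearchCox <- function(times, events, x, rounds = 5) {
  pl <- function(beta) {
    s <- 0
    for (i in which(events == 1)) {
      risk <- times >= times[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    s
  }
  br <- c(-6, 6)
  best <- 0
  for (r in seq_len(rounds)) {
    g <- seq(br[1], br[2], length.out = 81)
    vals <- vapply(g, pl, numeric(1))
    best <- g[which.max(vals)]
    w <- diff(br) / 80
    br <- best + c(-w, w)
  }
  best
}

# Plain-loop re-derivation of the bootstrap out-of-bag scoring
# bookkeeping: same RNG contract (one generator, seeded once, one
# n-with-replacement draw per iteration, single-class resamples redrawn),
# written as an explicit loop independent of the package's vectorized
# accumulation. The per-resample fit is the package's (separately
# oracle-checked) logistic fitter.
plainLoopOOB <- function(X, y, features, C, B, seed) {
  X <- X[, features, drop = FALSE]
  n <- nrow(X)
  set.seed(seed)
  tot <- numeric(n)
  cnt <- integer(n)
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    fit <- fitRegularizedLogistic(X[idx, , drop = FALSE], y[idx], C)
    oobScores <- 100 * predictModelProb(
      fit, X[setdiff(seq_len(n), idx), , drop = FALSE])
    j <- 0L
    for (i in seq_len(n)) {
      if (!(i %in% idx)) {
        j <- j + 1L
        tot[i] <- tot[i] + oobScores[j]
        cnt[i] <- cnt[i] + 1L
      }
    }
  }
  list(scores = ifelse(cnt > 0L, tot / ifelse(cnt > 0L, cnt, 1L),
                       NA_real_),
       appearances = cnt)
}

# Small labelled cohort used across modeling tests.
makeToyCohort <- function(n = 60, p = 6, effect = 2, seed = 42) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("f%02d", seq_len(p))))
  y <- rbinom(n, 1, plogis(effect * X[, 1]))
  # guard against degenerate draws in tiny cohorts
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  list(X = X, y = y)
}

randomConfusion <- function(nMax = 200) {
  n <- sample(4:nMax, 1)
  cuts <- sort(sample(0:n, 3, replace = TRUE))
  counts <- c(cuts[1], cuts[2] - cuts[1], cuts[3] - cuts[2], n - cuts[3])
  confusionFromCounts(counts[1], counts[2], counts[3], counts[4])
}
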