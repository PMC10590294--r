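#' Kaplan-Meier curves and log-rank test
#'
#' Product-limit survival estimate per group (via the survival package)
#' with the log-rank chi-square test across groups and each group's
#' median survival (NA if the curve never drops to 0.5).
#'
#' @param times follow-up times (>= 0).
#' @param events event indicator (1 = event, 0 = censored).
#' @param groups group label per subject (>= 2 groups).
#' @return list of class \code{timeSurvivalFit}: \code{curves}
#'   (data.frame: group, time, n_risk, survival), \code{medians} (named),
#'   \code{chisq}, \code{df}, \code{p}.
#' @export
kmLogrank <- function(times, events, groups) {
  if (any(times < 0)) failValidation("times", "must be >= 0")
  if (!all(events %in% c(0, 1))) failValidation("events", "must be 0/1")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L)
    stop("need at least 2 groups for a log-rank test", call. = FALSE)
  df <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups,
                           data = df)
  sf <- summary(fit)
  curves <- data.frame(
    group = sub("^groups=", "", as.character(sf$strata)),
    time = sf$time, n_risk = sf$n.risk, survival = sf$surv,
    stringsAsFactors = FALSE)
  tab <- summary(fit)$table
  medians <- if (is.matrix(tab)) {
    structure(tab[, "median"], names = sub("^groups=", "", rownames(tab)))
  } else {
    structure(tab["median"], names = levels(droplevels(groups))[1])
  }
  if (sum(events) > 0) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups,
                             data = df)
    dfree <- length(sd$n) - 1L
    chisq <- sd$chisq
    p <- pchisq(chisq, dfree, lower.tail = FALSE)
  } else {
    # no events anywhere: the log-rank statistic is undefined
    dfree <- nlevels(droplevels(groups)) - 1L
    chisq <- NA_real_
    p <- NA_real_
  }
  structure(list(curves = curves, medians = medians,
                 chisq = chisq, df = dfree, p = p),
            class = "timeSurvivalFit")
}

#' @export
print.timeSurvivalFit <- function(x, ...) {
  cat("Kaplan-Meier fit,", length(x$medians), "groups\n")
  cat("  medians:", paste(sprintf("%s = %s", names(x$medians),
                                  format(round(x$medians, 2))),
                          collapse = ", "), "\n")
  cat(sprintf("  log-rank chisq = %.3f (df %d), p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Cox proportional hazards model
#'
#' Maximizes the Cox partial likelihood (Efron tie handling, via the
#' survival package) and reports per-covariate hazard ratios with Wald
#' confidence intervals and p-values. Constant covariates are rejected by
#' name; non-convergence is an error with the fitter's diagnostics.
#'
#' @param times,events as in \code{\link{kmLogrank}} (>= 1 event
#'   required).
#' @param covariates data.frame of covariates; factors/characters are
#'   treated as categorical (use an explicit "unknown" level for missing
#'   categories).
#' @param conf confidence level.
#' @return data.frame: term, coef, hr, ci_lower, ci_upper, p.
#' @export
coxPh <- function(times, events, covariates, conf = 0.95) {
  if (sum(events) < 1) stop("need at least one event", call. = FALSE)
  covariates <- as.data.frame(covariates)
  constant <- vapply(covariates, function(v)
    length(unique(v[!is.na(v)])) < 2L, logical(1))
  if (any(constant))
    stop(sprintf("constant covariate(s): %s",
                 paste(names(covariates)[constant], collapse = ", ")),
         call. = FALSE)
  dat <- cbind(data.frame(.time = times, .event = events), covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "efron"),
    warning = function(w) {
      if (grepl("did not converge|infinite", conditionMessage(w)))
        stop("Cox fit did not converge: ", conditionMessage(w),
             call. = FALSE)
      invokeRestart("muffleWarning")
    })
  s <- summary(fit, conf.int = conf)
  data.frame(
    term = rownames(s$coefficients),
    coef = s$coefficients[, "coef"],
    hr = s$coefficients[, "exp(coef)"],
    ci_lower = s$conf.int[, 3],
    ci_upper = s$conf.int[, 4],
    p = s$coefficients[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
}
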