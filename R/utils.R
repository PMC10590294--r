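## Internal helpers shared across modules.

# Half-up rounding at `digits` decimals (printed tables round 0.295 -> 0.30,
# unlike base round()'s round-half-even). The small epsilon absorbs binary
# representation error in exact halves.
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-7) / p
}

sigmoid <- function(x) plogis(x)

# Stop with a message naming the offending field; keeps validation errors
# uniform across the user-facing operations.
failValidation <- function(field, why) {
  stop(sprintf("invalid '%s': %s", field, why), call. = FALSE)
}

assertScalar <- function(x, field, min = -Inf, max = Inf,
                         strictMin = FALSE, strictMax = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x))
    failValidation(field, "must be a single non-missing number")
  if (x < min || (strictMin && x <= min))
    failValidation(field, sprintf("must be %s %s",
                                  if (strictMin) ">" else ">=", min))
  if (x > max || (strictMax && x >= max))
    failValidation(field, sprintf("must be %s %s",
                                  if (strictMax) "<" else "<=", max))
  invisible(x)
}

# Binary outcome vectors arrive as 0/1, logical, or progressor labels;
# normalise to integer 0/1 with 1 = non-progressor (the positive class).
asOutcome01 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    bad <- setdiff(unique(y), c("non-progressor", "progressor"))
    if (length(bad))
      failValidation("labels", paste("unknown outcome label(s):",
                                     paste(bad, collapse = ", ")))
    return(as.integer(y == "non-progressor"))
  }
  y <- as.integer(y)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L)))
    failValidation("labels", "must be binary 0/1 (1 = non-progressor)")
  y
}

outcomeLabel <- function(y01) {
  ifelse(y01 == 1L, "non-progressor", "progressor")
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
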