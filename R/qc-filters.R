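#' Default sample-inclusion thresholds
#'
#' Inclusive ("at least"/"minimum"/"or greater") thresholds applied to
#' per-sample QC metrics: RNA yield >= 40 ng, DV200 >= 20%, exonic
#' alignment fraction >= 0.30, unique deduplicated counts >= 800,000,
#' tumor cellularity >= 10%. \code{allowed_specimen_sites = NULL} disables
#' the specimen-site allow-list; when given, samples whose
#' \code{specimen_site} is not listed (e.g. bone or liver metastases) are
#' excluded.
#'
#' @return named list of thresholds.
#' @export
defaultQCThresholds <- function() {
  list(
    min_rna_yield_ng = 40,
    min_dv200_pct = 20,
    min_exonic_alignment_frac = 0.30,
    min_unique_dedup_counts = 8e5,
    min_tumor_cellularity_frac = 0.10,
    allowed_specimen_sites = NULL
  )
}

# metric column -> threshold key, human-readable rule label
qcRules <- function(thresholds) {
  rules <- list(
    rna_yield_ng = c("min_rna_yield_ng", "rna_yield_ng"),
    dv200_pct = c("min_dv200_pct", "dv200_pct"),
    exonic_alignment_frac = c("min_exonic_alignment_frac",
                              "exonic_alignment"),
    unique_dedup_counts = c("min_unique_dedup_counts",
                            "unique_dedup_counts"),
    tumor_cellularity_frac = c("min_tumor_cellularity_frac",
                               "tumor_cellularity")
  )
  rules[vapply(rules, function(r)
    !is.null(thresholds[[r[1]]]), logical(1))]
}

#' Apply sample inclusion/exclusion QC rules
#'
#' A sample is retained iff it passes every threshold (all inclusive at the
#' boundary). A missing required metric excludes the sample with reason
#' "missing". When \code{thresholds$allowed_specimen_sites} is non-NULL and
#' a \code{specimen_site} column is present, samples at sites outside the
#' allow-list are excluded.
#'
#' @param records data.frame with a \code{sample_id} column and QC metric
#'   columns (\code{rna_yield_ng}, \code{dv200_pct},
#'   \code{exonic_alignment_frac}, \code{unique_dedup_counts},
#'   \code{tumor_cellularity_frac}, optionally \code{specimen_site}).
#'   Metric columns absent from the table are not checked.
#' @param thresholds list as from \code{\link{defaultQCThresholds}};
#'   individual entries may be overridden, and setting one to NULL
#'   disables that rule.
#' @return list with \code{retained} (character sample ids) and
#'   \code{exclusions} (data.frame: sample_id, rule, observed, threshold),
#'   one row per failed rule per excluded sample.
#' @export
applySampleQC <- function(records, thresholds = defaultQCThresholds()) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data.frame", call. = FALSE)
  if (is.null(records$sample_id))
    failValidation("records", "must contain a 'sample_id' column")
  defaults <- defaultQCThresholds()
  thresholds <- utils::modifyList(defaults, thresholds[
    names(thresholds) %in% names(defaults)], keep.null = TRUE)

  excl <- list()
  note <- function(id, rule, observed, threshold)
    data.frame(sample_id = id, rule = rule,
               observed = as.character(observed),
               threshold = as.character(threshold),
               stringsAsFactors = FALSE)

  rules <- qcRules(thresholds)
  for (i in seq_len(nrow(records))) {
    id <- records$sample_id[i]
    for (metric in names(rules)) {
      if (!metric %in% names(records)) next
      thr <- thresholds[[rules[[metric]][1]]]
      val <- records[[metric]][i]
      if (is.na(val)) {
        excl[[length(excl) + 1L]] <- note(id, rules[[metric]][2],
                                          "missing", thr)
      } else if (!is.numeric(val)) {
        excl[[length(excl) + 1L]] <- note(id, rules[[metric]][2],
                                          "malformed", thr)
      } else if (val < thr) {
        excl[[length(excl) + 1L]] <- note(
          id, sprintf("%s < %s", rules[[metric]][2], format(thr)), val, thr)
      }
    }
    sites <- thresholds$allowed_specimen_sites
    if (!is.null(sites) && "specimen_site" %in% names(records)) {
      site <- records$specimen_site[i]
      if (is.na(site) || !site %in% sites)
        excl[[length(excl) + 1L]] <- note(
          id, "specimen_site not allowed",
          ifelse(is.na(site), "missing", site),
          paste(sites, collapse = "|"))
    }
  }
  exclusions <- if (length(excl)) do.call(rbind, excl)
    else data.frame(sample_id = character(), rule = character(),
                    observed = character(), threshold = character(),
                    stringsAsFactors = FALSE)
  retained <- setdiff(records$sample_id, unique(exclusions$sample_id))
  list(retained = retained, exclusions = exclusions)
}

#' Remove the stalest biopsies
#'
#' Removes the \code{ceiling(fraction * n)} samples with the longest
#' biopsy-to-treatment interval; samples tied at the resulting cutoff are
#' all removed. Returns the empirical cutoff (the smallest removed value).
#'
#' @param records data.frame with \code{sample_id} and
#'   \code{biopsy_to_treatment_months} (required for all samples).
#' @param fraction fraction of samples to remove, in [0, 1); default 0.10.
#' @return list with \code{retained} ids, \code{removed} ids and
#'   \code{cutoff_months} (NA when nothing is removed).
#' @export
applyStalenessFilter <- function(records, fraction = 0.10) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("'records' must be a non-empty data.frame", call. = FALSE)
  if (length(fraction) != 1L || is.na(fraction) ||
      fraction < 0 || fraction >= 1)
    failValidation("fraction", "must lie in [0, 1)")
  gap <- records$biopsy_to_treatment_months
  if (is.null(gap) || any(is.na(gap)))
    failValidation("biopsy_to_treatment_months",
                   "must be present for every sample")
  nRemove <- ceiling(fraction * nrow(records))
  if (nRemove == 0L)
    return(list(retained = records$sample_id, removed = character(),
                cutoff_months = NA_real_))
  cutoff <- sort(gap, decreasing = TRUE)[nRemove]
  removed <- records$sample_id[gap >= cutoff]
  list(retained = records$sample_id[gap < cutoff], removed = removed,
       cutoff_months = cutoff)
}
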