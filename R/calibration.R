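#' Stratified sample of a negative set across taxonomic groups
#'
#' Samples approximately \code{fraction} of each group (default grouping:
#' the last lineage element, i.e. genus), always keeping at least one record
#' per non-empty group, to maximize phylogenetic breadth of the negative set.
#' Reproducible for a fixed seed.
#'
#' @param x a \code{\link{ProteinSet}}.
#' @param fraction in (0, 1].
#' @param groupKey function mapping a lineage vector to a group label;
#'   default takes the last element.
#' @param seed RNG seed.
#' @return the sampled \code{ProteinSet}, in input order.
#' @export
sampleNegativeSet <- function(x, fraction, groupKey = function(lin)
                              if (length(lin)) lin[length(lin)] else "",
                              seed = 1L) {
  stopifnot(is(x, "ProteinSet"))
  if (fraction <= 0) stop("fraction must be > 0")
  if (fraction > 1) stop("fraction must be <= 1")
  groups <- vapply(.splitSemi(S4Vectors::mcols(x)$taxonomy), groupKey,
                   character(1))
  set.seed(seed)
  keep <- logical(length(x))
  for (g in sort(unique(groups))) {
    idx <- which(groups == g)
    k <- max(1L, round(fraction * length(idx)))
    keep[sample(idx, min(k, length(idx)))] <- TRUE
  }
  x[keep]
}

#' Suggested inclusion cutoff from false-hit e-values
#'
#' The geometric mean of the false-hit e-values (arithmetic mean of their
#' log10 values, exponentiated); when there are no false hits, the configured
#' default is returned. For example, false hits at 1e-8 and 1e-12 suggest a
#' cutoff of 1e-10.
#'
#' @param falseHitEvalues numeric vector of e-values (possibly empty).
#' @param default cutoff used when no false hits were observed.
#' @return a single e-value.
#' @export
suggestCutoff <- function(falseHitEvalues, default = 1e-10) {
  if (!length(falseHitEvalues)) return(default)
  10^mean(log10(falseHitEvalues))
}

#' Calibrate a profile against a negative set
#'
#' Scans the negatives with the model (search-space size = number of
#' negatives), counts false hits at \code{reportingThreshold}, and derives
#' the empirical false-positive rate and a suggested e-value inclusion
#' cutoff via \code{\link{suggestCutoff}}.
#'
#' @param model a \code{\link{ProfileModel}}.
#' @param negatives an \code{AAStringSet}/\code{ProteinSet} of sequences
#'   known not to belong to the family.
#' @param reportingThreshold e-value at or below which a negative counts as
#'   a false hit (default 10, the conventional reporting threshold).
#' @param default cutoff reported when no false hits occur.
#' @return a \code{\link{CalibrationReport}}.
#' @export
calibrate <- function(model, negatives, reportingThreshold = 10,
                      default = 1e-10) {
  stopifnot(is(model, "ProfileModel"))
  if (!is(negatives, "AAStringSet"))
    negatives <- Biostrings::AAStringSet(negatives)
  if (!length(negatives)) stop("negative set is empty")
  sc <- scoreSequences(model, negatives, z = length(negatives))
  hits <- sc$evalue <= reportingThreshold
  ev <- sc$evalue[hits]
  meanLog <- if (any(hits)) mean(sc$log10Evalue[hits]) else NA_real_
  new("CalibrationReport",
      nNegatives = length(negatives), nFalseHits = sum(hits),
      fpr = sum(hits) / length(negatives),
      falseHitEvalues = as.numeric(ev),
      meanLog10Evalue = meanLog,
      suggestedCutoff = if (any(hits)) 10^meanLog else default,
      reportingThreshold = reportingThreshold)
}

#' Write a calibration report as JSON and TSV
#' @param report a \code{\link{CalibrationReport}}.
#' @param jsonPath,tsvPath output paths (either may be NULL).
#' @export
writeCalibrationReport <- function(report, jsonPath = NULL, tsvPath = NULL) {
  obj <- list(n_negatives = report@nNegatives,
              n_false_hits = report@nFalseHits,
              fpr = report@fpr,
              false_hit_evalues = report@falseHitEvalues,
              mean_log10_evalue = if (is.na(report@meanLog10Evalue)) NULL
                                  else report@meanLog10Evalue,
              suggested_cutoff = report@suggestedCutoff,
              reporting_threshold = report@reportingThreshold)
  if (!is.null(jsonPath))
    jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(tsvPath)) {
    df <- data.frame(n_negatives = report@nNegatives,
                     n_false_hits = report@nFalseHits, fpr = report@fpr,
                     mean_log10_evalue = report@meanLog10Evalue,
                     suggested_cutoff = report@suggestedCutoff,
                     reporting_threshold = report@reportingThreshold)
    utils::write.table(df, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(report)
}
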