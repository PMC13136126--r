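#' Protein reference collection
#'
#' A \code{ProteinSet} is an \linkS4class{AAStringSet} whose element metadata
#' (\code{mcols}) carries the record fields used during curation: taxonomy
#' lineage, free-text description and domain annotations. Accessions are the
#' element names and must be unique.
#'
#' @slot .Data inherited from \code{AAStringSet}.
#' @seealso \code{\link{ProteinSet}}, \code{\link{filterReferenceSet}}
#' @export
setClass("ProteinSet", contains = "AAStringSet")

setValidity("ProteinSet", function(object) {
  msg <- character(0)
  acc <- names(object)
  if (length(object) && (is.null(acc) || any(!nzchar(acc))))
    msg <- c(msg, "all records need a non-empty accession (element name)")
  if (anyDuplicated(acc))
    msg <- c(msg, "accessions must be unique within a collection")
  mc <- S4Vectors::mcols(object)
  need <- c("taxonomy", "description", "domains")
  if (is.null(mc) || !all(need %in% colnames(mc)))
    msg <- c(msg, paste("mcols must contain:", paste(need, collapse = ", ")))
  if (length(object)) {
    seqs <- as.character(object)
    bad <- grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "X]"), seqs)
    if (any(bad))
      msg <- c(msg, paste0("sequences restricted to the 20-letter alphabet plus X; offending: ",
                           paste(utils::head(acc[bad], 3), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinSet
#'
#' @param sequences named character vector or \code{AAStringSet}; names are
#'   accessions.
#' @param taxonomy character vector of semicolon-delimited lineages
#'   (e.g. \code{"Bacteria;Pseudomonadota;Brenneria"}).
#' @param description character vector of free-text product descriptions.
#' @param domains character vector of semicolon-delimited domain accessions
#'   (e.g. \code{"IPR001690"}), possibly empty strings.
#' @return a \code{ProteinSet}.
#' @examples
#' ps <- ProteinSet(c(A1 = "MKT"), "Bacteria;Vibrio", "autoinducer synthase",
#'                  "IPR001690")
#' length(ps)
#' @export
ProteinSet <- function(sequences, taxonomy = "", description = "",
                       domains = "") {
  if (!is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  n <- length(sequences)
  mc <- S4Vectors::DataFrame(
    taxonomy = rep_len(as.character(taxonomy), n),
    description = rep_len(as.character(description), n),
    domains = rep_len(as.character(domains), n)
  )
  S4Vectors::mcols(sequences) <- mc
  new("ProteinSet", sequences)
}

#' Declarative curation rule for a LuxI/LuxR reference family
#'
#' Encodes the mechanical filtering rules applied to a protein collection:
#' taxonomy membership, an inclusive length window, required domain
#' annotations, and description keywords to exclude (for LuxR, entries
#' described as two-component systems) or require.
#'
#' @slot family "LuxI" or "LuxR".
#' @slot requiredTaxon lineage element that must be present (default
#'   "Bacteria").
#' @slot lengthMin,lengthMax inclusive bounds in amino acids.
#' @slot requiredDomains at least one of these domain accessions must be
#'   annotated on a retained record.
#' @slot excludeKeywords case-insensitive substrings of the description that
#'   disqualify a record.
#' @slot includeKeywords optional: when non-empty, at least one must match.
#' @export
setClass("CurationRule",
  representation(family = "character", requiredTaxon = "character",
                 lengthMin = "integer", lengthMax = "integer",
                 requiredDomains = "character",
                 excludeKeywords = "character",
                 includeKeywords = "character"))

setValidity("CurationRule", function(object) {
  msg <- character(0)
  if (!object@family %in% c("LuxI", "LuxR"))
    msg <- c(msg, "family must be 'LuxI' or 'LuxR'")
  if (object@lengthMin > object@lengthMax)
    msg <- c(msg, "lengthMin must not exceed lengthMax")
  if (!length(object@requiredDomains))
    msg <- c(msg, "requiredDomains must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @rdname CurationRule-class
#' @param family,requiredTaxon,lengthMin,lengthMax,requiredDomains
#'   see the class slots.
#' @param excludeKeywords,includeKeywords see the class slots.
#' @export
CurationRule <- function(family, requiredTaxon = "Bacteria",
                         lengthMin = 100L, lengthMax = 500L,
                         requiredDomains = character(),
                         excludeKeywords = character(),
                         includeKeywords = character()) {
  new("CurationRule", family = family, requiredTaxon = requiredTaxon,
      lengthMin = as.integer(lengthMin), lengthMax = as.integer(lengthMax),
      requiredDomains = requiredDomains, excludeKeywords = excludeKeywords,
      includeKeywords = includeKeywords)
}

#' Default LuxI-family curation rule (IPR001690; 100-500 aa; Bacteria)
#' @export
luxIRule <- function() CurationRule("LuxI", requiredDomains = "IPR001690")

#' Default LuxR-family curation rule
#'
#' Requires any of the LuxR-family domain annotations IPR000792 (C-terminal
#' HTH), IPR005143 or IPR036693 (N-terminal autoinducer-binding domain), and
#' excludes entries described as "two-component" systems.
#' @export
luxRRule <- function() CurationRule("LuxR",
  requiredDomains = c("IPR000792", "IPR005143", "IPR036693"),
  excludeKeywords = "two-component")

#' Position-specific scoring profile for a protein family
#'
#' The built-in engine (\code{"builtin_pssm"}) holds a per-column log-odds
#' matrix derived from alignment match-column frequencies with add-0.5
#' pseudocounts, plus the parameters of a Gumbel null fitted to the window-max
#' scores of composition-shuffled sequences; e-values are computed from that
#' empirical null. The external engine (\code{"external_hmm"}) stores a
#' profile HMM text built with HMMER and delegates scoring to
#' \command{hmmsearch}, with an identical scoring contract.
#'
#' @slot family "LuxI" or "LuxR" (or a short domain name for mini-profiles).
#' @slot alignmentId free-text identifier of the source alignment.
#' @slot engine "builtin_pssm" or "external_hmm".
#' @slot modelLength number of match columns.
#' @slot inclusionCutoff e-value at or below which a scanned sequence is
#'   reported as a family member (default 1e-10).
#' @slot pssm 20 x modelLength log-odds matrix (bits), builtin engine.
#' @slot background residue background frequencies.
#' @slot nullMu,nullBeta Gumbel location/scale of the empirical null.
#' @slot nullWindows reference window count used for length correction.
#' @slot minOverlap minimum model/query overlap (columns) scored.
#' @slot hmmText HMMER model text, external engine only.
#' @export
setClass("ProfileModel",
  representation(family = "character", alignmentId = "character",
                 engine = "character", modelLength = "integer",
                 inclusionCutoff = "numeric", pssm = "matrix",
                 background = "numeric", nullMu = "numeric",
                 nullBeta = "numeric", nullWindows = "numeric",
                 minOverlap = "integer", hmmText = "character"))

setValidity("ProfileModel", function(object) {
  msg <- character(0)
  if (object@modelLength < 1L) msg <- c(msg, "modelLength must be >= 1")
  if (object@inclusionCutoff <= 0) msg <- c(msg, "inclusionCutoff must be > 0")
  if (!object@engine %in% c("builtin_pssm", "external_hmm"))
    msg <- c(msg, "engine must be 'builtin_pssm' or 'external_hmm'")
  if (object@engine == "builtin_pssm" &&
      !identical(dim(object@pssm), c(20L, object@modelLength)))
    msg <- c(msg, "pssm must be a 20 x modelLength matrix")
  if (length(msg)) msg else TRUE
})

#' Empirical false-positive calibration of a profile model
#'
#' @slot nNegatives number of negative sequences scanned.
#' @slot nFalseHits negatives scoring at or below the reporting threshold.
#' @slot fpr \code{nFalseHits / nNegatives}.
#' @slot falseHitEvalues e-values of the false hits.
#' @slot meanLog10Evalue arithmetic mean of log10 e-values over false hits
#'   (\code{NA} when there are none).
#' @slot suggestedCutoff \code{10^meanLog10Evalue} when defined, else the
#'   configured default.
#' @slot reportingThreshold e-value at which a negative counts as a hit.
#' @export
setClass("CalibrationReport",
  representation(nNegatives = "integer", nFalseHits = "integer",
                 fpr = "numeric", falseHitEvalues = "numeric",
                 meanLog10Evalue = "numeric", suggestedCutoff = "numeric",
                 reportingThreshold = "numeric"))

setValidity("CalibrationReport", function(object) {
  msg <- character(0)
  if (object@nFalseHits > object@nNegatives)
    msg <- c(msg, "nFalseHits cannot exceed nNegatives")
  if (object@suggestedCutoff <= 0)
    msg <- c(msg, "suggestedCutoff must be > 0")
  if (abs(object@fpr - object@nFalseHits / object@nNegatives) > 1e-12)
    msg <- c(msg, "fpr must equal nFalseHits / nNegatives")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProfileModel", function(object) {
  cat("ProfileModel for family", object@family,
      "| engine:", object@engine,
      "| length:", object@modelLength,
      "| inclusion cutoff:", format(object@inclusionCutoff), "\n")
})

setMethod("show", "CalibrationReport", function(object) {
  cat(sprintf(
    "CalibrationReport: %d negatives, %d false hits at E <= %g (FPR %.4g%%)\n",
    object@nNegatives, object@nFalseHits, object@reportingThreshold,
    100 * object@fpr))
  cat(sprintf("  mean log10(e-value) of false hits: %s\n",
              ifelse(is.na(object@meanLog10Evalue), "undefined",
                     format(object@meanLog10Evalue, digits = 4))))
  cat(sprintf("  suggested inclusion cutoff: %g\n", object@suggestedCutoff))
})

#' @rdname CalibrationReport-class
#' @param object a \code{CalibrationReport}.
#' @export
fpr <- function(object) object@fpr

#' @rdname CalibrationReport-class
#' @export
suggestedCutoff <- function(object) object@suggestedCutoff

#' @rdname ProfileModel-class
#' @param object a \code{ProfileModel}.
#' @export
inclusionCutoff <- function(object) object@inclusionCutoff

#' @rdname ProfileModel-class
#' @export
modelLength <- function(object) object@modelLength

#' @rdname ProfileModel-class
#' @export
profileFamily <- function(object) object@family
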