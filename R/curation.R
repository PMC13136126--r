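#' Filter a protein collection with a curation rule
#'
#' Applies the mechanical reference-set filters for a LuxI/LuxR family:
#' taxonomy membership anywhere in the lineage, inclusive length bounds,
#' presence of at least one required domain annotation, and case-insensitive
#' substring matching of description keywords. Order of the retained records
#' is input order; membership does not depend on input order. Every excluded
#' record is recorded with a machine-readable reason code in
#' \code{metadata(result)$exclusions} (codes: \code{taxonomy}, \code{length},
#' \code{domain}, \code{keyword_excluded}, \code{keyword_not_included};
#' the first failing check in that order is reported).
#'
#' @param x a \code{\link{ProteinSet}}.
#' @param rule a \code{\link{CurationRule}}.
#' @return the curated \code{ProteinSet}; the exclusion report is attached as
#'   \code{metadata(x)$exclusions}, a \code{DataFrame} of accession + reason.
#' @examples
#' ps <- ProteinSet(c(a = paste(rep("M", 120), collapse = ""),
#'                    b = "MK"),
#'                  taxonomy = "Bacteria;Vibrio",
#'                  description = "autoinducer synthase",
#'                  domains = "IPR001690")
#' curated <- filterReferenceSet(ps, luxIRule())
#' names(curated)                       # "a" (b fails the length filter)
#' S4Vectors::metadata(curated)$exclusions
#' @export
filterReferenceSet <- function(x, rule) {
  stopifnot(is(x, "ProteinSet"), is(rule, "CurationRule"))
  validObject(rule)
  if (!length(x)) {
    S4Vectors::metadata(x)$exclusions <-
      S4Vectors::DataFrame(accession = character(0), reason = character(0))
    return(x)
  }
  mc <- S4Vectors::mcols(x)
  lineages <- .splitSemi(mc$taxonomy)
  domains <- .splitSemi(mc$domains)
  len <- Biostrings::width(x)
  desc <- tolower(mc$description)

  okTax <- vapply(lineages, function(v) rule@requiredTaxon %in% v, logical(1))
  okLen <- len >= rule@lengthMin & len <= rule@lengthMax
  okDom <- vapply(domains, function(v) any(rule@requiredDomains %in% v),
                  logical(1))
  hitExcl <- if (length(rule@excludeKeywords)) {
    Reduce(`|`, lapply(tolower(rule@excludeKeywords),
                       function(k) grepl(k, desc, fixed = TRUE)))
  } else rep(FALSE, length(x))
  okIncl <- if (length(rule@includeKeywords)) {
    Reduce(`|`, lapply(tolower(rule@includeKeywords),
                       function(k) grepl(k, desc, fixed = TRUE)))
  } else rep(TRUE, length(x))

  reason <- rep(NA_character_, length(x))
  reason[!okIncl] <- "keyword_not_included"
  reason[hitExcl] <- "keyword_excluded"
  reason[!okDom] <- "domain"
  reason[!okLen] <- "length"
  reason[!okTax] <- "taxonomy"

  keep <- is.na(reason)
  out <- x[keep]
  S4Vectors::metadata(out)$exclusions <- S4Vectors::DataFrame(
    accession = names(x)[!keep], reason = reason[!keep])
  out
}

#' Remove duplicate records
#'
#' Drops records sharing an accession or an identical sequence string with an
#' earlier record (first occurrence wins). Idempotent.
#'
#' @param x a \code{ProteinSet} (or any \code{AAStringSet} with names).
#' @return the deduplicated object.
#' @export
deduplicateRecords <- function(x) {
  if (!length(x)) return(x)
  keep <- !duplicated(names(x)) & !duplicated(as.character(x))
  x[keep]
}

#' Assign a family label from domain annotations
#'
#' Returns \code{"LuxI"} iff IPR001690 is annotated, \code{"LuxR"} iff any
#' LuxR-family domain (IPR000792, IPR005143, IPR036693) is annotated,
#' \code{"ambiguous"} (with a message) when both, and \code{"none"} otherwise.
#' Records without domain metadata are never guessed at; a sequence-based
#' assignment is available downstream via a profile scan.
#'
#' @param x a \code{ProteinSet}, or a character vector of semicolon-delimited
#'   domain accessions.
#' @param luxIDomains,luxRDomains domain accession sets defining each family.
#' @return character vector of labels, one per record.
#' @examples
#' assignFamily(c("IPR001690", "IPR000792", "", "IPR001690;IPR000792"))
#' @export
assignFamily <- function(x,
                         luxIDomains = "IPR001690",
                         luxRDomains = c("IPR000792", "IPR005143",
                                         "IPR036693")) {
  domains <- if (is(x, "AAStringSet")) S4Vectors::mcols(x)$domains else x
  doms <- .splitSemi(domains)
  isI <- vapply(doms, function(v) any(luxIDomains %in% v), logical(1))
  isR <- vapply(doms, function(v) any(luxRDomains %in% v), logical(1))
  out <- rep("none", length(doms))
  out[isI] <- "LuxI"
  out[isR] <- "LuxR"
  out[isI & isR] <- "ambiguous"
  if (any(isI & isR))
    message(sum(isI & isR), " record(s) carry both LuxI and LuxR domains; ",
            "labelled 'ambiguous'")
  out
}

#' Read / write a protein collection as FASTA + metadata TSV
#'
#' The TSV carries columns \code{accession}, \code{taxonomy},
#' \code{description}, \code{length}, \code{domains} (semicolon-separated).
#' A round trip through \code{writeProteinSet}/\code{readProteinSet}
#' reproduces the collection exactly.
#'
#' @param fasta,tsv file paths.
#' @param x a \code{ProteinSet}.
#' @return \code{readProteinSet} returns a \code{ProteinSet};
#'   \code{writeProteinSet} returns the paths invisibly.
#' @export
readProteinSet <- function(fasta, tsv) {
  seqs <- Biostrings::readAAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- utils::read.delim(tsv, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (!all(names(seqs) %in% meta$accession))
    stop("metadata TSV is missing accessions present in the FASTA")
  meta <- meta[match(names(seqs), meta$accession), ]
  ProteinSet(seqs, taxonomy = meta$taxonomy,
             description = meta$description, domains = meta$domains)
}

#' @rdname readProteinSet
#' @export
writeProteinSet <- function(x, fasta, tsv) {
  stopifnot(is(x, "ProteinSet"))
  Biostrings::writeXStringSet(x, fasta)
  mc <- S4Vectors::mcols(x)
  df <- data.frame(accession = names(x), taxonomy = mc$taxonomy,
                   description = mc$description,
                   length = Biostrings::width(x), domains = mc$domains,
                   stringsAsFactors = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Write the exclusion report of a curated set to TSV
#' @param x a curated \code{ProteinSet} returned by
#'   \code{\link{filterReferenceSet}}.
#' @param path output TSV path.
#' @export
writeExclusionReport <- function(x, path) {
  excl <- S4Vectors::metadata(x)$exclusions
  if (is.null(excl))
    excl <- S4Vectors::DataFrame(accession = character(0),
                                 reason = character(0))
  utils::write.table(as.data.frame(excl), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
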