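#' Read a genome FASTA plus GFF3 annotation
#'
#' @param fasta nucleotide FASTA path.
#' @param gff GFF3 path; only \code{CDS} features are retained.
#' @return list with \code{genome} (\code{DNAStringSet}) and \code{features}
#'   (\code{GRanges} with \code{locus_tag} and \code{product} columns).
#' @export
readGenomeAnnotation <- function(fasta, gff) {
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  gr <- rtracklayer::import(gff)
  gr <- gr[gr$type == "CDS"]
  if (is.null(gr$locus_tag)) {
    gr$locus_tag <- gr$ID %||% paste0("cds", seq_along(gr))
  }
  gr$locus_tag <- as.character(gr$locus_tag)
  if (is.null(gr$product)) gr$product <- ""
  gr$product <- as.character(gr$product)
  GenomeInfoDb::seqlevels(gr) <-
    union(GenomeInfoDb::seqlevels(gr), names(genome))
  GenomeInfoDb::seqlengths(gr)[names(genome)] <- Biostrings::width(genome)
  list(genome = genome, features = gr)
}

#' Extract a proteome from an annotated genome
#'
#' Translates every CDS feature with the bacterial/archaeal code (table 11):
#' minus-strand features are reverse-complemented first, codons are
#' translated literally (no special initiation-codon handling), a trailing
#' stop is removed, features whose length is not divisible by 3 are excluded as
#' \code{partial}, and features with internal stop codons are excluded as
#' \code{pseudogene}; all exclusions are logged in the result. When the
#' annotation supplies a \code{translation} column it is trusted (a mismatch
#' with the computed translation raises a warning). Coordinates are 1-based
#' inclusive throughout.
#'
#' @param genome a named \code{DNAStringSet} of contigs.
#' @param features a \code{GRanges} of CDS features with \code{locus_tag}
#'   (and optionally \code{product}, \code{translation}) columns.
#' @return an \code{AAStringSet} named by locus tag, with \code{mcols}
#'   \code{seqId}, \code{start}, \code{end}, \code{strand}, \code{product};
#'   excluded features are reported in \code{metadata(x)$excluded}
#'   (locus_tag + reason).
#' @examples
#' g <- Biostrings::DNAStringSet(c(ctg = "ATGAAATAA"))
#' f <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1, 9), "+",
#'                             locus_tag = "g1", product = "demo")
#' as.character(extractProteome(g, f))   # "MK"
#' @export
extractProteome <- function(genome, features) {
  stopifnot(is(genome, "DNAStringSet"), is(features, "GRanges"))
  if (length(features)) {
    contigLen <- Biostrings::width(genome)[
      match(as.character(GenomicRanges::seqnames(features)), names(genome))]
    if (anyNA(contigLen) ||
        any(GenomicRanges::start(features) < 1L) ||
        any(GenomicRanges::end(features) > contigLen))
      stop("CDS features must lie within their contig")
  }
  tags <- features$locus_tag %||% paste0("cds", seq_along(features))
  prods <- features$product %||% rep("", length(features))
  supplied <- features$translation

  code <- Biostrings::getGeneticCode("11")
  prot <- character(length(features))
  reason <- rep(NA_character_, length(features))
  for (i in seq_along(features)) {
    if (GenomicRanges::width(features)[i] %% 3L != 0L) {
      reason[i] <- "partial"; next
    }
    dna <- Biostrings::subseq(
      genome[[as.character(GenomicRanges::seqnames(features))[i]]],
      GenomicRanges::start(features)[i], GenomicRanges::end(features)[i])
    if (as.character(GenomicRanges::strand(features))[i] == "-")
      dna <- Biostrings::reverseComplement(dna)
    aa <- as.character(Biostrings::translate(dna, genetic.code = code,
                                             no.init.codon = TRUE,
                                             if.fuzzy.codon = "X"))
    aa <- sub("\\*$", "", aa)
    if (grepl("*", aa, fixed = TRUE)) {
      reason[i] <- "pseudogene"; next
    }
    if (!is.null(supplied) && !is.na(supplied[i]) && nzchar(supplied[i])) {
      if (!identical(as.character(supplied[i]), aa))
        warning("supplied translation differs from computed for ", tags[i])
      aa <- as.character(supplied[i])
    }
    prot[i] <- aa
  }
  keep <- is.na(reason)
  out <- Biostrings::AAStringSet(prot[keep])
  names(out) <- tags[keep]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    seqId = as.character(GenomicRanges::seqnames(features))[keep],
    start = GenomicRanges::start(features)[keep],
    end = GenomicRanges::end(features)[keep],
    strand = as.character(GenomicRanges::strand(features))[keep],
    product = prods[keep])
  S4Vectors::metadata(out)$excluded <- S4Vectors::DataFrame(
    locus_tag = tags[!keep], reason = reason[!keep])
  out
}

#' Scan a proteome with a family profile
#'
#' Scores every protein (search-space size = proteome size) and reports the
#' features whose e-value is at or below the model's inclusion cutoff, as a
#' coordinate-anchored \code{GRanges} sorted by ascending e-value. At most
#' one hit per (feature, family).
#'
#' @param proteome an \code{AAStringSet} from \code{\link{extractProteome}}.
#' @param model a calibrated \code{\link{ProfileModel}}.
#' @param cutoff e-value inclusion cutoff; defaults to the model's.
#' @return \code{GRanges} with mcols \code{locus_tag}, \code{family},
#'   \code{evalue}, \code{bitscore}, \code{proteinLength},
#'   \code{lengthClass}, \code{product}.
#' @export
scanProteome <- function(proteome, model, cutoff = inclusionCutoff(model)) {
  emptyHits <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      locus_tag = character(0), family = character(0), evalue = numeric(0),
      bitscore = numeric(0), proteinLength = integer(0),
      lengthClass = character(0), product = character(0))
    gr
  }
  if (!length(proteome)) return(emptyHits())
  sc <- scoreSequences(model, proteome, z = length(proteome))
  keep <- which(sc$evalue <= cutoff)
  if (!length(keep)) return(emptyHits())
  mc <- S4Vectors::mcols(proteome)[keep, , drop = FALSE]
  len <- Biostrings::width(proteome)[keep]
  gr <- GenomicRanges::GRanges(mc$seqId,
                               IRanges::IRanges(mc$start, mc$end),
                               strand = mc$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locus_tag = names(proteome)[keep],
    family = profileFamily(model),
    evalue = sc$evalue[keep], bitscore = sc$bitscore[keep],
    proteinLength = len,
    lengthClass = flagLengthClass(profileFamily(model), len),
    product = mc$product)
  gr[order(S4Vectors::mcols(gr)$evalue)]
}

#' Flag protein length as typical or atypical for its family
#'
#' LuxI proteins are typically 157-257 aa and canonical LuxR proteins
#' 210-272 aa (inclusive bounds). This is a flag only; it never filters.
#'
#' @param family "LuxI" or "LuxR" (vectorized).
#' @param length protein length(s) in aa.
#' @return character vector, "typical" or "atypical".
#' @export
flagLengthClass <- function(family, length) {
  lo <- ifelse(family == "LuxI", 157L, 210L)
  hi <- ifelse(family == "LuxI", 257L, 272L)
  ifelse(length >= lo & length <= hi, "typical", "atypical")
}

#' Write homolog hits as TSV and GFF3
#' @param hits a hits \code{GRanges} from \code{\link{scanProteome}}.
#' @param tsv,gff output paths (either may be NULL).
#' @export
writeHits <- function(hits, tsv = NULL, gff = NULL) {
  df <- data.frame(seq_id = as.character(GenomicRanges::seqnames(hits)),
                   start = GenomicRanges::start(hits),
                   end = GenomicRanges::end(hits),
                   strand = as.character(GenomicRanges::strand(hits)),
                   as.data.frame(S4Vectors::mcols(hits)),
                   stringsAsFactors = FALSE)
  if (!is.null(tsv))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(gff)) {
    gr <- hits
    gr$type <- "CDS"
    gr$source <- "ahlqs"
    gr$phase <- 0L
    rtracklayer::export(gr, gff, format = "gff3")
  }
  invisible(df)
}

#' Read a hits table written by \code{\link{writeHits}}
#' @param tsv path.
#' @return hits \code{GRanges}.
#' @export
readHits <- function(tsv) {
  df <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df$seq_id,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    df[setdiff(names(df), c("seq_id", "start", "end", "strand"))])
  gr
}
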