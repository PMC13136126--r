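## Domain sets defining the two halves of a canonical LuxR-family protein.
## Built-in mini-profile scans label hits "ABD"/"HTH" directly.
ABD_DOMAINS <- c("IPR005143", "IPR036693", "PF03472", "ABD")
HTH_DOMAINS <- c("IPR000792", "HTH")

#' Classify a LuxR-family protein's domain architecture
#'
#' Canonical LuxR-family proteins carry an N-terminal autoinducer-binding
#' domain (ABD) and a C-terminal helix-turn-helix (HTH) DNA-binding domain;
#' many homologs retain only the HTH. Classification is on domain presence
#' (ABD evidence: IPR005143, IPR036693, PF03472; HTH evidence: IPR000792):
#' \code{CANONICAL}, \code{HTH_ONLY}, \code{ABD_ONLY} or \code{NONE}. An
#' advisory anomaly flag is raised when the ABD midpoint lies C-terminal of
#' the HTH midpoint; it never changes the class.
#'
#' @param proteinLength protein length in aa.
#' @param domainHits data.frame with columns \code{domain}, \code{start},
#'   \code{end}, \code{evalue} for this protein (possibly 0 rows).
#' @param evalueThreshold domain presence threshold (default 1e-5).
#' @return list with \code{architecture} and \code{anomaly} (logical).
#' @examples
#' hits <- data.frame(domain = c("IPR005143", "IPR000792"),
#'                    start = c(10, 175), end = c(160, 230),
#'                    evalue = c(1e-20, 1e-15))
#' classifyArchitecture(240, hits)$architecture   # "CANONICAL"
#' @export
classifyArchitecture <- function(proteinLength, domainHits,
                                 evalueThreshold = 1e-5) {
  if (is.null(domainHits) || !nrow(domainHits)) {
    return(list(architecture = "NONE", anomaly = FALSE))
  }
  if (any(domainHits$start < 1L) || any(domainHits$end > proteinLength) ||
      any(domainHits$start > domainHits$end))
    stop("domain hit coordinates must satisfy 1 <= start <= end <= protein length")
  keep <- domainHits$evalue <= evalueThreshold
  domainHits <- domainHits[keep, , drop = FALSE]
  abd <- domainHits[domainHits$domain %in% ABD_DOMAINS, , drop = FALSE]
  hth <- domainHits[domainHits$domain %in% HTH_DOMAINS, , drop = FALSE]
  cls <- if (nrow(abd) && nrow(hth)) "CANONICAL"
         else if (nrow(hth)) "HTH_ONLY"
         else if (nrow(abd)) "ABD_ONLY"
         else "NONE"
  anomaly <- FALSE
  if (cls == "CANONICAL") {
    abdMid <- min((abd$start + abd$end) / 2)
    hthMid <- max((hth$start + hth$end) / 2)
    anomaly <- abdMid > hthMid
  }
  list(architecture = cls, anomaly = anomaly)
}

#' Scan proteins with built-in domain mini-profiles
#'
#' Scores each protein against mini-profiles of the ABD and HTH regions
#' (built by \code{\link{buildProfile}} from curated sub-domain sequences)
#' and reports, per (protein, domain), the best window position and its
#' e-value. Removes the dependency on an external domain-annotation service.
#'
#' @param proteins an \code{AAStringSet}.
#' @param models named list of \code{\link{ProfileModel}}s, e.g.
#'   \code{list(ABD = ..., HTH = ...)}.
#' @param evalueThreshold report hits at or below this e-value.
#' @return data.frame with \code{proteinId}, \code{domain}, \code{start},
#'   \code{end}, \code{evalue}, plus a \code{source} attribute
#'   ("builtin_profile").
#' @export
domainScan <- function(proteins, models, evalueThreshold = 1e-5) {
  stopifnot(is.list(models), !is.null(names(models)))
  if (!is(proteins, "AAStringSet"))
    proteins <- Biostrings::AAStringSet(proteins)
  rows <- list()
  for (dom in names(models)) {
    m <- models[[dom]]
    sc <- scoreSequences(m, proteins, z = 1)
    for (i in which(sc$evalue <= evalueThreshold)) {
      pos <- .bestWindowPosition(as.character(proteins[[i]]), m)
      rows[[length(rows) + 1L]] <- data.frame(
        proteinId = names(proteins)[i], domain = dom,
        start = pos[1], end = pos[2], evalue = sc$evalue[i],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(proteinId = character(0), domain = character(0),
                         start = integer(0), end = integer(0),
                         evalue = numeric(0))
  attr(out, "source") <- "builtin_profile"
  out
}

## Protein coordinates (1-based inclusive) of the best-scoring segment.
.bestWindowPosition <- function(seq, model) {
  seg <- .bestLocalSegment(.encodeAA(seq), model@pssm, model@minOverlap)
  c(seg$start, seg$end)
}

#' Parse an InterProScan-style domain TSV
#'
#' Consumes the standard tab-separated InterProScan output (no header;
#' columns: protein accession, MD5, length, analysis, signature accession,
#' signature description, start, stop, score, status, date, InterPro
#' accession, ...). Both the member-database signature and the InterPro
#' accession (when present) are emitted as evidence rows.
#'
#' @param path TSV path.
#' @return data.frame with \code{proteinId}, \code{domain}, \code{start},
#'   \code{end}, \code{evalue}; \code{source} attribute "interproscan_tsv".
#' @export
readDomainTsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  ev <- suppressWarnings(as.numeric(df[[9]]))
  ev[is.na(ev)] <- 0
  base <- data.frame(proteinId = df[[1]], domain = df[[5]],
                     start = as.integer(df[[7]]), end = as.integer(df[[8]]),
                     evalue = ev, stringsAsFactors = FALSE)
  out <- base
  if (ncol(df) >= 12) {
    ipr <- as.character(df[[12]])
    has <- !is.na(ipr) & nzchar(ipr) & ipr != "-"
    if (any(has)) {
      extra <- base[has, ]
      extra$domain <- ipr[has]
      out <- rbind(base, extra)
    }
  }
  attr(out, "source") <- "interproscan_tsv"
  out
}

#' Classify architectures for a table of hits
#'
#' @param hits hits \code{GRanges} (LuxR rows are classified; LuxI rows get
#'   \code{NA}).
#' @param domainHits data.frame as returned by \code{\link{domainScan}} or
#'   \code{\link{readDomainTsv}}.
#' @param evalueThreshold domain presence threshold.
#' @return the hits with added mcols \code{architecture} and
#'   \code{archAnomaly}.
#' @export
annotateArchitecture <- function(hits, domainHits, evalueThreshold = 1e-5) {
  arch <- rep(NA_character_, length(hits))
  anom <- rep(FALSE, length(hits))
  isR <- S4Vectors::mcols(hits)$family == "LuxR"
  for (i in which(isR)) {
    tag <- S4Vectors::mcols(hits)$locus_tag[i]
    dh <- domainHits[domainHits$proteinId == tag, , drop = FALSE]
    res <- classifyArchitecture(S4Vectors::mcols(hits)$proteinLength[i], dh,
                                evalueThreshold)
    arch[i] <- res$architecture
    anom[i] <- res$anomaly
  }
  S4Vectors::mcols(hits)$architecture <- arch
  S4Vectors::mcols(hits)$archAnomaly <- anom
  hits
}

#' Per-genome homolog count summary
#'
#' @param hits hits \code{GRanges} with \code{family} and (for LuxR rows)
#'   \code{architecture} mcols; may span several contigs of one genome.
#' @param genomeId label for the summary row.
#' @return one-row data.frame: \code{genome}, \code{n_luxI}, \code{n_luxR},
#'   \code{n_canonical}, \code{n_hth_only}, \code{n_other}
#'   (\code{n_luxR == n_canonical + n_hth_only + n_other}).
#' @export
summarizeCounts <- function(hits, genomeId = "genome") {
  fam <- S4Vectors::mcols(hits)$family
  arch <- S4Vectors::mcols(hits)$architecture
  nR <- sum(fam == "LuxR")
  nCan <- sum(fam == "LuxR" & arch %in% "CANONICAL")
  nHth <- sum(fam == "LuxR" & arch %in% "HTH_ONLY")
  data.frame(genome = genomeId,
             n_luxI = sum(fam == "LuxI"), n_luxR = nR,
             n_canonical = nCan, n_hth_only = nHth,
             n_other = nR - nCan - nHth,
             stringsAsFactors = FALSE)
}

#' Export an iTOL-compatible binary annotation dataset for architectures
#' @param labels leaf labels.
#' @param architecture architecture per leaf.
#' @param path output path.
#' @export
writeItolArchitecture <- function(labels, architecture, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("DATASET_BINARY", "SEPARATOR TAB",
               "DATASET_LABEL\tLuxR architecture", "COLOR\t#d62728",
               "FIELD_SHAPES\t2\t3", "FIELD_LABELS\tABD\tHTH", "DATA"), con)
  abd <- ifelse(architecture %in% c("CANONICAL", "ABD_ONLY"), 1, 0)
  hth <- ifelse(architecture %in% c("CANONICAL", "HTH_ONLY"), 1, 0)
  writeLines(paste(labels, abd, hth, sep = "\t"), con)
  invisible(path)
}
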