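#' Signed intergenic distance between two features
#'
#' Positive values are the bp gap between disjoint features (0 = abutting),
#' negative values the length of their overlap; \code{NA} when the features
#' lie on different contigs. Symmetric in its arguments. Coordinates are
#' 1-based inclusive.
#'
#' @param a,b length-1 \code{GRanges} (or parallel \code{GRanges} vectors).
#' @return integer vector of signed distances (NA across contigs).
#' @examples
#' a <- GenomicRanges::GRanges("c", IRanges::IRanges(1, 100))
#' intergenicDistance(a, GenomicRanges::GRanges("c", IRanges::IRanges(150, 200)))  # 49
#' intergenicDistance(a, GenomicRanges::GRanges("c", IRanges::IRanges(80, 180)))   # -21
#' @export
intergenicDistance <- function(a, b) {
  sameCtg <- as.character(GenomicRanges::seqnames(a)) ==
             as.character(GenomicRanges::seqnames(b))
  maxStart <- pmax(GenomicRanges::start(a), GenomicRanges::start(b))
  minEnd <- pmin(GenomicRanges::end(a), GenomicRanges::end(b))
  d <- ifelse(maxStart > minEnd, maxStart - minEnd - 1L,
              -(minEnd - maxStart + 1L))
  ifelse(sameCtg, as.integer(d), NA_integer_)
}

#' Relative transcriptional orientation of two same-contig features
#'
#' The positionally upstream feature (smaller start) determines the class:
#' equal strands are \code{co_directional}; upstream on \code{+} with
#' downstream on \code{-} is \code{convergent} (3' ends facing); upstream on
#' \code{-} with downstream on \code{+} is \code{divergent} (5' ends facing).
#'
#' @param a,b length-1 \code{GRanges}.
#' @return one of "co_directional", "convergent", "divergent".
#' @export
classifyOrientation <- function(a, b) {
  if (GenomicRanges::start(b) < GenomicRanges::start(a)) { tmp <- a; a <- b; b <- tmp }
  sa <- as.character(GenomicRanges::strand(a))
  sb <- as.character(GenomicRanges::strand(b))
  if (sa == sb) "co_directional"
  else if (sa == "+") "convergent"
  else "divergent"
}

#' Call cognate luxI/luxR pairs and solos
#'
#' A luxI and a luxR form a cognate pair when they share a contig and their
#' signed intergenic distance satisfies \code{|distance| <= windowBp}
#' (default 3000 bp, the conventional local-neighborhood radius). Each luxI
#' pairs with at most one luxR and vice versa; among candidates the selection
#' prefers CANONICAL architecture, then smallest |distance|, then smallest
#' e-value. Every unpaired hit becomes a solo carrying the exact distance to
#' the nearest opposite-family hit on its contig (\code{NA} when none), plus
#' a \code{withinWindow} flag.
#'
#' @param hits hits \code{GRanges} with mcols \code{locus_tag},
#'   \code{family}, \code{evalue} and (for LuxR) \code{architecture}.
#' @param windowBp pairing window (bp).
#' @return list of two data.frames, \code{pairs} (seq_id, luxI, luxR,
#'   distance, orientation, luxR_architecture) and \code{solos} (seq_id,
#'   locus_tag, family, partner_family, nearest_partner_distance,
#'   withinWindow).
#' @export
findCognatePairs <- function(hits, windowBp = 3000L) {
  ord <- order(as.character(GenomicRanges::seqnames(hits)),
               GenomicRanges::start(hits))
  hits <- hits[ord]
  mc <- S4Vectors::mcols(hits)
  iIdx <- which(mc$family == "LuxI")
  rIdx <- which(mc$family == "LuxR")
  arch <- if ("architecture" %in% colnames(mc)) mc$architecture
          else rep(NA_character_, length(hits))

  taken <- logical(length(hits))
  pairs <- list()
  for (i in iIdx) {
    cand <- rIdx[!taken[rIdx]]
    if (!length(cand)) next
    d <- vapply(cand, function(j) intergenicDistance(hits[i], hits[j]),
                integer(1))
    ok <- !is.na(d) & abs(d) <= windowBp
    cand <- cand[ok]; d <- d[ok]
    if (!length(cand)) next
    pref <- order(arch[cand] != "CANONICAL", abs(d), mc$evalue[cand])
    j <- cand[pref[1]]
    taken[i] <- taken[j] <- TRUE
    pairs[[length(pairs) + 1L]] <- data.frame(
      seq_id = as.character(GenomicRanges::seqnames(hits))[i],
      luxI = mc$locus_tag[i], luxR = mc$locus_tag[j],
      distance = d[pref[1]],
      orientation = classifyOrientation(hits[i], hits[j]),
      luxR_architecture = arch[j], stringsAsFactors = FALSE)
  }
  pairsDf <- if (length(pairs)) do.call(rbind, pairs)
             else data.frame(seq_id = character(0), luxI = character(0),
                             luxR = character(0), distance = integer(0),
                             orientation = character(0),
                             luxR_architecture = character(0))

  solo <- which(!taken)
  solos <- lapply(solo, function(i) {
    other <- if (mc$family[i] == "LuxI") rIdx else iIdx
    other <- setdiff(other, i)
    d <- if (length(other))
      vapply(other, function(j) intergenicDistance(hits[i], hits[j]),
             integer(1)) else integer(0)
    d <- d[!is.na(d)]
    nearest <- if (length(d)) min(abs(d)) else NA_integer_
    data.frame(seq_id = as.character(GenomicRanges::seqnames(hits))[i],
               locus_tag = mc$locus_tag[i], family = mc$family[i],
               partner_family = ifelse(mc$family[i] == "LuxI", "LuxR", "LuxI"),
               nearest_partner_distance = nearest,
               withinWindow = !is.na(nearest) && nearest <= windowBp,
               stringsAsFactors = FALSE)
  })
  solosDf <- if (length(solos)) do.call(rbind, solos)
             else data.frame(seq_id = character(0), locus_tag = character(0),
                             family = character(0),
                             partner_family = character(0),
                             nearest_partner_distance = integer(0),
                             withinWindow = logical(0))
  list(pairs = pairsDf, solos = solosDf)
}

#' Inventory of the genomic neighborhood of a focal hit
#'
#' Lists every annotated gene intersecting
#' \code{[start(focal) - flankBp, end(focal) + flankBp]} in positional order,
#' with a signed offset from the focal feature (the signed intergenic
#' distance, negative for genes upstream of the focal feature in genome
#' coordinates, 0 for genes overlapping it), strand, relative orientation
#' and a functional category tag from \code{\link{categorizeProduct}}.
#'
#' @param focal length-1 \code{GRanges}.
#' @param features annotation \code{GRanges} with \code{locus_tag} and
#'   \code{product}.
#' @param flankBp flank radius in bp (the two reporting scales are 3000 and
#'   10000).
#' @return data.frame: \code{locus_tag}, \code{start}, \code{end},
#'   \code{strand}, \code{offset}, \code{orientation}, \code{product},
#'   \code{category}.
#' @export
neighborhoodInventory <- function(focal, features, flankBp = 3000L) {
  stopifnot(length(focal) == 1L)
  win <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(focal),
    IRanges::IRanges(max(1L, GenomicRanges::start(focal) - flankBp),
                     GenomicRanges::end(focal) + flankBp))
  sel <- features[as.character(GenomicRanges::seqnames(features)) ==
                    as.character(GenomicRanges::seqnames(focal))]
  ov <- IRanges::overlapsAny(IRanges::ranges(sel), IRanges::ranges(win))
  sel <- sel[ov]
  sel <- sel[order(GenomicRanges::start(sel))]
  d <- vapply(seq_along(sel),
              function(i) intergenicDistance(focal, sel[i]), integer(1))
  upstream <- GenomicRanges::end(sel) < GenomicRanges::start(focal)
  offset <- ifelse(d < 0L, 0L, ifelse(upstream, -d, d))
  samestrand <- as.character(GenomicRanges::strand(sel)) ==
    as.character(GenomicRanges::strand(focal))
  prod <- sel$product %||% rep("", length(sel))
  data.frame(locus_tag = as.character(sel$locus_tag),
             start = GenomicRanges::start(sel),
             end = GenomicRanges::end(sel),
             strand = as.character(GenomicRanges::strand(sel)),
             offset = offset,
             orientation = ifelse(samestrand, "same", "opposite"),
             product = prod,
             category = categorizeProduct(prod),
             stringsAsFactors = FALSE)
}

## Ordered keyword map; first match wins.
PRODUCT_CATEGORIES <- list(
  redox_electron_transfer = c("electron transfer flavoprotein", "etf",
                              "ferredoxin", "oxidoreductase", "fixb"),
  sulfur_trna = c("cysteine desulfurase", "2-thiouridylase", "iscs", "mnma",
                  "trna"),
  secondary_metabolism = c("monooxygenase", "dehydrogenase",
                           "methyltransferase", "polyketide", "synthase"),
  stress_sensing = c("histidine kinase", "sensor", "chemotaxis"),
  regulator = c("transcriptional regulator", "regulator", "repressor",
                "activator"),
  transport = c("abc transporter", "transporter", "permease", "efflux"),
  hypothetical = c("hypothetical")
)

#' Categorize a gene product description
#'
#' Deterministic first-match lookup over a configurable keyword map
#' (case-insensitive substrings), mirroring the functional vocabulary seen in
#' luxI neighborhoods: redox/electron-transfer genes (etfA, etfB, fixB),
#' sulfur/tRNA-modification genes (iscS, mnmA), secondary metabolism,
#' stress/sensing, regulators, transport, hypothetical proteins. Anything
#' unmatched is \code{"other"}.
#'
#' @param x character vector of product descriptions.
#' @param map named list of keyword vectors, in priority order.
#' @return character vector of categories.
#' @examples
#' categorizeProduct("electron transfer flavoprotein subunit A")
#' @export
categorizeProduct <- function(x, map = PRODUCT_CATEGORIES) {
  lx <- tolower(x)
  out <- rep("other", length(x))
  for (i in seq_along(lx)) {
    for (cat in names(map)) {
      if (any(vapply(map[[cat]], grepl, logical(1), x = lx[i],
                     fixed = TRUE))) {
        out[i] <- cat
        break
      }
    }
  }
  out
}

#' Write pair/solo/inventory tables
#' @param topo list returned by \code{\link{findCognatePairs}}.
#' @param pairsTsv,solosTsv output paths.
#' @export
writeTopology <- function(topo, pairsTsv, solosTsv) {
  utils::write.table(topo$pairs, pairsTsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(topo$solos, solosTsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(topo)
}
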