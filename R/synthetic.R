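#' Generate a synthetic protein family from a common ancestor
#'
#' Draws a random ancestor of the stated length from the uniform residue
#' background, then emits \code{n} members, each an i.i.d. mutated copy:
#' every position is substituted with probability \code{mutationRate} by a
#' residue drawn from the other 19. Pure function of its arguments and seed.
#'
#' @param n number of members.
#' @param length ancestor length in aa.
#' @param mutationRate per-position substitution probability in [0, 0.5).
#' @param seed RNG seed.
#' @param ancestor optional amino-acid string to mutate instead of a random
#'   ancestor.
#' @param prefix name prefix for the members.
#' @return an \code{AAStringSet}; the ancestor is kept in
#'   \code{metadata()$ancestor} and all members carry
#'   \code{mcols()$label == "positive"}.
#' @export
generateFamily <- function(n, length = 200L, mutationRate = 0.1, seed = 1L,
                           ancestor = NULL, prefix = "fam") {
  if (mutationRate < 0 || mutationRate >= 0.5)
    stop("mutationRate must be in [0, 0.5)")
  set.seed(seed)
  anc <- if (is.null(ancestor))
    sample(AA_ALPHABET20, length, replace = TRUE)
  else strsplit(ancestor, "")[[1]]
  members <- vapply(seq_len(n), function(i) {
    m <- anc
    mut <- runif(base::length(m)) < mutationRate
    if (any(mut))
      m[mut] <- vapply(m[mut], function(a)
        sample(setdiff(AA_ALPHABET20, a), 1), character(1))
    paste(m, collapse = "")
  }, character(1))
  out <- Biostrings::AAStringSet(members)
  names(out) <- sprintf("%s_%03d", prefix, seq_len(n))
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(label = "positive")
  S4Vectors::metadata(out)$ancestor <- paste(anc, collapse = "")
  out
}

#' Generate unrelated decoy proteins
#'
#' Residues are drawn i.i.d. from the uniform background, independent of any
#' family profile; members are labelled negatives.
#'
#' @param n number of decoys.
#' @param lengths recycled vector of decoy lengths.
#' @param seed RNG seed.
#' @return an \code{AAStringSet} with \code{mcols()$label == "negative"}.
#' @export
generateDecoys <- function(n, lengths = 200L, seed = 2L) {
  set.seed(seed)
  lens <- rep_len(lengths, max(n, 0L))
  out <- Biostrings::AAStringSet(vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET20, lens[i], replace = TRUE), collapse = ""),
    character(1)))
  names(out) <- sprintf("decoy_%04d", seq_len(n))
  if (n > 0)
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(label = "negative")
  out
}

#' Synthetic LuxI/LuxR protein families for pipeline tests
#'
#' Generates the protein raw material of a planted-genome study: a LuxI
#' synthase family (200 aa, inside the typical 157-257 aa range), an
#' autoinducer-binding-domain (ABD) sub-family (160 aa) and a
#' helix-turn-helix (HTH) sub-family (80 aa). Canonical LuxR members are the
#' N-terminal ABD concatenated with the C-terminal HTH (240 aa, inside
#' 210-272); HTH-only members are an unrelated random N-terminal region
#' (120 aa) followed by an HTH member.
#'
#' @param seed RNG seed.
#' @param n members per family.
#' @param mutationRate per-position substitution probability.
#' @return list with \code{AAStringSet}s \code{luxI}, \code{abd},
#'   \code{hth}, \code{luxRCanonical}, \code{luxRHthOnly}.
#' @export
qsFamilySet <- function(seed = 42L, n = 30L, mutationRate = 0.1) {
  luxI <- generateFamily(n, 200L, mutationRate, seed = seed, prefix = "luxI")
  abd <- generateFamily(n, 160L, mutationRate, seed = seed + 1L,
                        prefix = "abd")
  hth <- generateFamily(n, 80L, mutationRate, seed = seed + 2L,
                        prefix = "hth")
  canon <- Biostrings::AAStringSet(paste0(as.character(abd),
                                          as.character(hth)))
  names(canon) <- sprintf("luxR_%03d", seq_len(n))
  set.seed(seed + 3L)
  linkers <- vapply(seq_len(n), function(i)
    paste(sample(AA_ALPHABET20, 120L, replace = TRUE), collapse = ""),
    character(1))
  hthOnly <- Biostrings::AAStringSet(paste0(linkers, as.character(hth)))
  names(hthOnly) <- sprintf("luxRhth_%03d", seq_len(n))
  list(luxI = luxI, abd = abd, hth = hth, luxRCanonical = canon,
       luxRHthOnly = hthOnly)
}

## Synonymous codons of the bacterial/archaeal code, uniform choice.
.backTranslate <- function(aa) {
  code <- Biostrings::getGeneticCode("11")
  byAA <- split(names(code), code)
  res <- strsplit(aa, "")[[1]]
  codons <- vapply(res, function(a) {
    ch <- byAA[[a]]
    if (is.null(ch)) stop("cannot back-translate residue ", a)
    ch[sample.int(length(ch), 1L)]
  }, character(1))
  paste(c(codons, "TAA"), collapse = "")
}

.randomCds <- function(lengthNt) {
  code <- Biostrings::getGeneticCode("11")
  sense <- names(code)[code != "*"]
  stopifnot(lengthNt %% 3L == 0L, lengthNt >= 6L)
  paste(c(sample(sense, lengthNt / 3L - 1L, replace = TRUE), "TAA"),
        collapse = "")
}

#' Assemble a synthetic annotated genome from a gene plan
#'
#' The plan is a data.frame with one row per gene, columns: \code{contig},
#' \code{locus_tag}, \code{type} (\code{luxI}, \code{luxR} or
#' \code{neighbor}), \code{architecture} (for luxR rows), \code{product},
#' \code{strand}, \code{gap} (signed bp between this gene's start and the
#' previous gene's end on the contig; negative values plant an overlap; for
#' the first gene, the bp preceding it), \code{protein} (amino-acid string
#' for lux genes; \code{NA} for neighbors) and \code{length_nt} (CDS length
#' for neighbor rows; multiple of 3). Lux proteins are back-translated with
#' uniform synonymous codon choice (table 11) and a TAA stop; minus-strand
#' genes are written as the reverse complement. Intergenic space is random
#' background sequence.
#'
#' The emitted truth table carries the planned coordinates; by construction
#' the declared \code{gap} equals the signed intergenic distance between
#' consecutive genes on the emitted annotation.
#'
#' @param plan the gene plan (see above).
#' @param seed RNG seed.
#' @param contigPad random bp appended after the last gene of each contig.
#' @return list with \code{genome} (\code{DNAStringSet}), \code{features}
#'   (\code{GRanges}) and \code{truth} (data.frame: plan columns plus
#'   \code{start}, \code{end}).
#' @export
generateGenome <- function(plan, seed = 7L, contigPad = 500L) {
  set.seed(seed)
  need <- c("contig", "locus_tag", "type", "product", "strand", "gap")
  stopifnot(all(need %in% names(plan)))
  if (is.null(plan$protein)) plan$protein <- NA_character_
  if (is.null(plan$length_nt)) plan$length_nt <- NA_integer_
  if (is.null(plan$architecture)) plan$architecture <- NA_character_
  plan$start <- NA_integer_; plan$end <- NA_integer_
  plan$cds <- NA_character_

  contigs <- unique(plan$contig)
  seqs <- setNames(character(length(contigs)), contigs)
  for (ctg in contigs) {
    rows <- which(plan$contig == ctg)
    cursor <- 0L
    for (r in rows) {
      cds <- if (!is.na(plan$protein[r])) .backTranslate(plan$protein[r])
             else .randomCds(plan$length_nt[r])
      start <- cursor + plan$gap[r] + 1L
      if (start < 1L) stop("plan places a gene before the contig start")
      end <- start + nchar(cds) - 1L
      plan$start[r] <- start; plan$end[r] <- end; plan$cds[r] <- cds
      cursor <- max(cursor, end)
    }
    total <- cursor + contigPad
    bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    for (r in rows) {
      cds <- plan$cds[r]
      if (plan$strand[r] == "-")
        cds <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds)))
      substr_range <- plan$start[r]:plan$end[r]
      bases[substr_range] <- strsplit(cds, "")[[1]]
    }
    seqs[ctg] <- paste(bases, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(seqs)
  gr <- GenomicRanges::GRanges(plan$contig,
                               IRanges::IRanges(plan$start, plan$end),
                               strand = plan$strand,
                               locus_tag = plan$locus_tag,
                               product = plan$product, type = "CDS",
                               phase = 0L)
  GenomeInfoDb::seqlengths(gr)[names(genome)] <- Biostrings::width(genome)
  truth <- plan[setdiff(names(plan), "cds")]
  list(genome = genome, features = gr, truth = truth)
}

#' Fig-2-style demonstration genome plan
#'
#' Builds a two-contig plan mirroring the canonical neighborhood layouts
#' seen in AHL-QS genomes: a contig with three cognate luxI/luxR pairs (a
#' convergent pair with a 77 bp intergenic region, and two co-directional
#' pairs whose regulators sit 82 bp and 92 bp upstream of their synthases)
#' plus scattered HTH-only luxR genes, and a contig with a solitary luxI
#' embedded in a redox/sulfur neighborhood (cysteine desulfurase,
#' tRNA-2-thiouridylase upstream; an electron-transfer-flavoprotein gene
#' 124 bp downstream whose partner subunit overlaps it by 46 bp), the
#' nearest luxR lying tens of kb away.
#'
#' @param families output of \code{\link{qsFamilySet}}.
#' @param nScatteredHth number of scattered HTH-only luxR genes (default 18),
#'   all placed > 3 kb from any luxI.
#' @return a plan data.frame for \code{\link{generateGenome}}.
#' @export
demoGenomePlan <- function(families, nScatteredHth = 18L) {
  luxI <- as.character(families$luxI)
  canon <- as.character(families$luxRCanonical)
  hthOnly <- as.character(families$luxRHthOnly)
  stopifnot(length(luxI) >= 4, length(canon) >= 3,
            length(hthOnly) >= nScatteredHth + 1L)
  g <- function(contig, tag, type, product, strand, gap,
                protein = NA_character_, length_nt = NA_integer_,
                architecture = NA_character_, pair_id = NA_character_)
    data.frame(contig = contig, locus_tag = tag, type = type,
               product = product, strand = strand, gap = gap,
               protein = protein, length_nt = length_nt,
               architecture = architecture, pair_id = pair_id,
               stringsAsFactors = FALSE)
  rows <- list(
    g("ctg1", "c1g01", "neighbor", "sensor histidine kinase RcsC", "+", 400L,
      length_nt = 1200L),
    g("ctg1", "c1g02", "luxR", "LuxR family transcriptional regulator", "+",
      3600L, protein = hthOnly[1], architecture = "HTH_ONLY"),
    g("ctg1", "c1g03", "neighbor", "hypothetical protein", "+", 450L,
      length_nt = 600L),
    g("ctg1", "c1g04", "luxI", "acyl-homoserine-lactone synthase", "+",
      3500L, protein = luxI[1], pair_id = "pair77"),
    g("ctg1", "c1g05", "luxR", "LuxR family transcriptional regulator", "-",
      77L, protein = canon[1], architecture = "CANONICAL",
      pair_id = "pair77"),
    g("ctg1", "c1g06", "neighbor", "hypothetical protein", "-", 350L,
      length_nt = 450L),
    g("ctg1", "c1g07", "neighbor", "methionine sulfoxide reductase YedZ1",
      "+", 250L, length_nt = 660L),
    g("ctg1", "c1g08", "luxR", "LuxR family transcriptional regulator", "+",
      4200L, protein = hthOnly[2], architecture = "HTH_ONLY"),
    g("ctg1", "c1g09", "luxR", "LuxR family transcriptional regulator", "+",
      4800L, protein = canon[2], architecture = "CANONICAL",
      pair_id = "pair82"),
    g("ctg1", "c1g10", "luxI", "acyl-homoserine-lactone synthase", "+",
      82L, protein = luxI[2], pair_id = "pair82"),
    g("ctg1", "c1g11", "neighbor", "KdgT 2-keto-3-deoxygluconate permease",
      "+", 500L, length_nt = 990L),
    g("ctg1", "c1g12", "neighbor", "transcriptional regulator DmlR", "+",
      4500L, length_nt = 900L),
    g("ctg1", "c1g13", "luxR", "LuxR family transcriptional regulator", "+",
      298L, protein = canon[3], architecture = "CANONICAL",
      pair_id = "pair92"),
    g("ctg1", "c1g14", "luxI", "acyl-homoserine-lactone synthase", "+",
      92L, protein = luxI[3], pair_id = "pair92"),
    g("ctg2", "c2g01", "neighbor", "cysteine desulfurase IscS", "+", 600L,
      length_nt = 1200L),
    g("ctg2", "c2g02", "neighbor", "tRNA-specific 2-thiouridylase MnmA",
      "+", 200L, length_nt = 1080L),
    g("ctg2", "c2g03", "luxI", "acyl-homoserine-lactone synthase", "-",
      800L, protein = luxI[4], pair_id = NA_character_),
    g("ctg2", "c2g04", "neighbor",
      "electron transfer flavoprotein subunit A", "-", 124L,
      length_nt = 930L),
    g("ctg2", "c2g05", "neighbor",
      "electron transfer flavoprotein subunit B", "-", -46L,
      length_nt = 780L),
    g("ctg2", "c2g06", "neighbor", "electron transfer flavoprotein FixB",
      "-", 150L, length_nt = 840L),
    g("ctg2", "c2g07", "neighbor",
      "S-adenosylmethionine-dependent methyltransferase", "+", 300L,
      length_nt = 750L),
    g("ctg2", "c2g08", "neighbor", "hypothetical protein", "+", 420L,
      length_nt = 360L),
    g("ctg2", "c2g09", "luxR", "LuxR family transcriptional regulator", "+",
      30000L, protein = hthOnly[3], architecture = "HTH_ONLY")
  )
  scatter <- lapply(seq_len(nScatteredHth - 3L), function(k)
    g("ctg1", sprintf("c1s%02d", k), "luxR",
      "LuxR family transcriptional regulator",
      ifelse(k %% 2L == 0L, "+", "-"), 4000L,
      protein = hthOnly[3L + k], architecture = "HTH_ONLY"))
  do.call(rbind, c(rows, scatter))
}

#' Generate a synthetic MRM peak list with ground truth
#'
#' True analyte peaks are emitted at the standard's [M+H]+ and retention
#' time, jittered within the stated tolerances, with the diagnostic product
#' ion at m/z 102. Optional planted "unknown AHL" peaks carry the 102
#' product ion but a precursor away from every standard window; noise peaks
#' have product ions far from 102.
#'
#' @param analytes data.frame with columns \code{sample} and \code{name}
#'   (a standard name from \code{\link{ahlStandards}}).
#' @param nNoise,nUnknown number of noise / planted-unknown peaks.
#' @param mzJitter,rtJitter maximum absolute jitter applied to true peaks.
#' @param seed RNG seed.
#' @param standards standards table.
#' @return list with \code{peaks} (data.frame: sample, precursor_mz,
#'   product_mz, rt, area) and \code{truth} (character vector per peak:
#'   the analyte name, "unknown" or "noise").
#' @export
generatePeaklist <- function(analytes, nNoise = 0L, nUnknown = 0L,
                             mzJitter = 0.1, rtJitter = 0.05, seed = 5L,
                             standards = ahlStandards()) {
  set.seed(seed)
  jit <- function(n, a) runif(n, -a, a)
  rows <- list(); truth <- character(0)
  if (nrow(analytes)) {
    i <- match(analytes$name, standards$name)
    if (anyNA(i)) stop("unknown analyte name(s) in plan")
    rows[[1]] <- data.frame(
      sample = analytes$sample,
      precursor_mz = standards$mz[i] + jit(nrow(analytes), mzJitter),
      product_mz = 102 + jit(nrow(analytes), mzJitter),
      rt = standards$rt[i] + jit(nrow(analytes), rtJitter),
      area = runif(nrow(analytes), 1e4, 1e6), stringsAsFactors = FALSE)
    truth <- c(truth, analytes$name)
  }
  samples <- unique(c(as.character(analytes$sample), "blank"))
  offGrid <- function() {
    repeat {
      mz <- runif(1, 150, 400)
      if (min(abs(mz - standards$mz)) > 1.5) return(mz)
    }
  }
  if (nUnknown > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sample(samples, nUnknown, replace = TRUE),
      precursor_mz = vapply(seq_len(nUnknown), function(k) offGrid(),
                            numeric(1)),
      product_mz = 102 + jit(nUnknown, mzJitter),
      rt = runif(nUnknown, 1, 8),
      area = runif(nUnknown, 1e3, 1e5), stringsAsFactors = FALSE)
    truth <- c(truth, rep("unknown", nUnknown))
  }
  if (nNoise > 0) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample = sample(samples, nNoise, replace = TRUE),
      precursor_mz = runif(nNoise, 150, 400),
      product_mz = runif(nNoise, 110, 300),
      rt = runif(nNoise, 1, 8),
      area = runif(nNoise, 1e2, 1e4), stringsAsFactors = FALSE)
    truth <- c(truth, rep("noise", nNoise))
  }
  peaks <- if (length(rows)) do.call(rbind, rows)
           else data.frame(sample = character(0), precursor_mz = numeric(0),
                           product_mz = numeric(0), rt = numeric(0),
                           area = numeric(0))
  rownames(peaks) <- NULL
  list(peaks = peaks, truth = truth)
}

#' Write a generated genome to FASTA + GFF3 + truth JSON
#' @param gen list from \code{\link{generateGenome}}.
#' @param fasta,gff,truthJson output paths (truthJson may be NULL).
#' @export
writeGenome <- function(gen, fasta, gff, truthJson = NULL) {
  Biostrings::writeXStringSet(gen$genome, fasta)
  rtracklayer::export(gen$features, gff, format = "gff3")
  if (!is.null(truthJson))
    jsonlite::write_json(gen$truth, truthJson, auto_unbox = TRUE,
                         digits = NA, na = "null")
  invisible(c(fasta = fasta, gff = gff))
}
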