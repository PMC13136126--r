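# Shared fixtures, built once per test run. The family/genome seeds are the
# study conditions of the synthetic benchmark, fixed here and documented in
# the methods vignette.
.fx <- new.env(parent = emptyenv())

fxFamilies <- function() {
  if (is.null(.fx$fam)) .fx$fam <- qsFamilySet(seed = 42L)
  .fx$fam
}

fxLuxIModel <- function() {
  if (is.null(.fx$luxI)) .fx$luxI <- buildProfile(fxFamilies()$luxI, "LuxI",
                                                  seed = 111L)
  .fx$luxI
}

fxLuxRModel <- function() {
  if (is.null(.fx$luxR))
    .fx$luxR <- buildProfile(fxFamilies()$luxRCanonical, "LuxR", seed = 112L)
  .fx$luxR
}

fxAbdModel <- function() {
  if (is.null(.fx$abd)) .fx$abd <- buildProfile(fxFamilies()$abd, "ABD",
                                                seed = 113L)
  .fx$abd
}

fxHthModel <- function() {
  if (is.null(.fx$hth)) .fx$hth <- buildProfile(fxFamilies()$hth, "HTH",
                                                seed = 114L)
  .fx$hth
}

fxGenome <- function() {
  if (is.null(.fx$genome))
    .fx$genome <- generateGenome(demoGenomePlan(fxFamilies()), seed = 7L)
  .fx$genome
}

fxDecoys <- function() {
  if (is.null(.fx$decoys)) .fx$decoys <- generateDecoys(1000L, 200L,
                                                        seed = 2L)
  .fx$decoys
}

# Calibration family of the sensitivity/FPR benchmark (30 members, seed 1).
fxCalFamily <- function() {
  if (is.null(.fx$calFam)) .fx$calFam <- generateFamily(30L, 200L, 0.1,
                                                        seed = 1L)
  .fx$calFam
}

fxCalModel <- function() {
  if (is.null(.fx$calModel)) .fx$calModel <- buildProfile(fxCalFamily(),
                                                          "LuxI",
                                                          seed = 115L)
  .fx$calModel
}

# Simple GRanges helper for topology tests.
gr1 <- function(start, end, strand = "+", seq = "ctg",
                tag = paste0("g", start)) {
  GenomicRanges::GRanges(seq, IRanges::IRanges(start, end), strand = strand,
                         locus_tag = tag)
}

# Brute-force signed intergenic distance, independent of the package.
oracleDistance <- function(s1, e1, s2, e2) {
  if (max(s1, s2) > min(e1, e2)) max(s1, s2) - min(e1, e2) - 1L
  else -(min(e1, e2) - max(s1, s2) + 1L)
}

# Brute-force bipartition enumeration of an unrooted tree: for every
# internal edge, the leaf set on one side (flood fill over the adjacency
# list with the edge removed).
oracleBipartitions <- function(tree) {
  nTip <- length(tree$tip.label)
  adj <- lapply(seq_len(max(tree$edge)), function(i) integer(0))
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  splits <- list()
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    seen <- rep(FALSE, length(adj)); seen[a] <- TRUE
    queue <- b; seen[b] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (!seen[w] && !(v == b && w == a)) { seen[w] <- TRUE
          queue <- c(queue, w) }
      }
    }
    side <- which(seen[seq_len(nTip)])
    splits[[length(splits) + 1L]] <- sort(side)
  }
  unique(splits)
}
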