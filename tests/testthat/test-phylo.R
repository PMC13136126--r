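randAln <- function(nrow = 10L, ncol = 60L, gapProb = 0.3, seed = 50L) {
  set.seed(seed)
  M <- matrix(sample(c("A", "C", "D", "E", "-"), nrow * ncol, TRUE,
                     prob = c(rep((1 - gapProb) / 4, 4), gapProb)),
              nrow, ncol)
  out <- Biostrings::AAStringSet(apply(M, 1, paste, collapse = ""))
  names(out) <- sprintf("s%02d", seq_len(nrow))
  out
}

test_that("gap-threshold trimming keeps columns by coverage with an inclusive boundary", {
  aln <- Biostrings::AAStringSet(c(a = "A-CA", b = "A-CA", c = "A--A",
                                   d = "A-TA"))
  names(aln) <- letters[1:4]
  tr <- trimAlignment(aln, 0.5)
  expect_equal(tr$mask, c(TRUE, FALSE, TRUE, TRUE))  # 3/4 coverage kept
  expect_equal(as.character(tr$alignment[["a"]]), "ACA")
  # column with exactly half coverage is kept at threshold 0.5
  aln2 <- Biostrings::AAStringSet(c("AC", "A-", "AC", "A-"))
  names(aln2) <- letters[1:4]
  expect_equal(trimAlignment(aln2, 0.5)$mask, c(TRUE, TRUE))
})

test_that("trimming agrees with brute-force column coverage and is idempotent and monotone", {
  aln <- randAln()
  M <- do.call(rbind, strsplit(as.character(aln), ""))
  kept <- integer(0)
  for (gt in c(0.1, 0.5, 0.9)) {
    tr <- trimAlignment(aln, gt)
    oracle <- apply(M, 2, function(col) mean(col != "-") >= gt)
    expect_equal(tr$mask, unname(oracle))
    expect_length(tr$mask, ncol(M))
    again <- trimAlignment(tr$alignment, gt)
    expect_equal(as.character(again$alignment), as.character(tr$alignment))
    kept <- c(kept, sum(tr$mask))
  }
  expect_true(all(diff(kept) <= 0))
})

test_that("removing every column is a warning, not an error", {
  aln <- Biostrings::AAStringSet(c(a = "--", b = "--"))
  names(aln) <- c("a", "b")
  expect_warning(tr <- trimAlignment(aln, 0.5), "all columns")
  expect_equal(sum(tr$mask), 0L)
})

test_that("pairwise distances ignore gapped columns and can be Poisson corrected", {
  aln <- Biostrings::AAStringSet(c(x = "A-AA", y = "AATA", z = "AAAA"))
  names(aln) <- c("x", "y", "z")
  d <- as.matrix(alignmentDistances(aln, "p_distance"))
  expect_equal(d["x", "y"], 1 / 3)   # comparable columns 1,3,4
  expect_equal(d["x", "z"], 0)
  dp <- as.matrix(alignmentDistances(aln, "poisson_corrected"))
  expect_equal(dp["x", "y"], -log(1 - 1 / 3))
  bad <- Biostrings::AAStringSet(c(p = "A---", q = "-AAA"))
  names(bad) <- c("p", "q")
  expect_error(alignmentDistances(bad), "no comparable columns")
})

test_that("identical sequences form a zero-distance cherry", {
  aln <- Biostrings::AAStringSet(c(t1 = "ACDEFG", t2 = "ACDEFG",
                                   t3 = "AAAEEE", t4 = "CCDDFF"))
  names(aln) <- paste0("t", 1:4)
  d <- as.matrix(alignmentDistances(aln))
  expect_equal(d["t1", "t2"], 0)
  tree <- buildDistanceTree(aln)
  expect_true(checkMonophyly(tree, c("t1", "t2"))$monophyletic)
})

test_that("neighbor joining recovers the generating topology from additive matrices (4-8 leaves)", {
  for (n in 4:8) {
    set.seed(n)
    true <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    d <- stats::as.dist(ape::cophenetic.phylo(true))
    rec <- buildDistanceTree(d)
    expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(rec),
                                method = "PH85"), 0,
                 ignore_attr = TRUE)
  }
})

test_that("monophyly testing agrees with exhaustive bipartition enumeration", {
  set.seed(63)
  tree <- ape::unroot(ape::rtree(6))
  tips <- tree$tip.label
  splits <- oracleBipartitions(tree)
  idx <- seq_along(tips)
  for (k in 1:4) {
    combos <- utils::combn(idx, k, simplify = FALSE)
    for (sub in combos) {
      expected <- k == 1 ||
        any(vapply(splits, function(s)
          identical(s, sort(sub)) ||
          identical(s, sort(setdiff(idx, sub))), logical(1)))
      got <- checkMonophyly(tree, tips[sub])$monophyletic
      expect_identical(got, expected)
    }
  }
  expect_true(checkMonophyly(tree, tips)$monophyletic)
  expect_error(checkMonophyly(tree, "nope"), "unknown leaf")
})

test_that("sequences simulated as one clade are recovered as monophyletic", {
  set.seed(80)
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  mutate <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    hit <- runif(length(v)) < rate
    v[hit] <- vapply(v[hit], function(x) sample(setdiff(aa, x), 1),
                     character(1))
    paste(v, collapse = "")
  }
  root <- paste(sample(aa, 120, TRUE), collapse = "")
  cladeA <- mutate(root, 0.35)   # deep split
  leaves <- c(vapply(1:4, function(i) mutate(cladeA, 0.05), character(1)),
              vapply(1:4, function(i) mutate(root, 0.05), character(1)))
  aln <- Biostrings::AAStringSet(leaves)
  names(aln) <- c(paste0("actino", 1:4), paste0("proteo", 1:4))
  tree <- buildDistanceTree(aln)
  expect_true(checkMonophyly(tree, paste0("actino", 1:4))$monophyletic)
})

test_that("annotated trees export to round-trippable Newick with a leaf dataset", {
  set.seed(5)
  tree <- ape::rtree(5)
  ann <- data.frame(label = tree$tip.label,
                    family = "LuxR",
                    architecture = c("CANONICAL", rep("HTH_ONLY", 4)))
  nwk <- tempfile(fileext = ".nwk"); ds <- tempfile(fileext = ".tsv")
  exportAnnotatedTree(tree, ann, nwk, ds)
  back <- ape::read.tree(nwk)
  expect_equal(ape::dist.topo(ape::unroot(tree), ape::unroot(back)), 0,
               ignore_attr = TRUE)
  tab <- read.delim(ds)
  expect_equal(tab$architecture[match(tree$tip.label, tab$label)],
               ann$architecture)
  expect_error(exportAnnotatedTree(tree,
    data.frame(label = "missing_leaf", family = "x"), nwk, ds),
    "unknown leaves")
  dup <- tree; dup$tip.label[2] <- dup$tip.label[1]
  expect_error(exportAnnotatedTree(dup, ann[1, ], nwk, ds), "duplicate")
})
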