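test_that("CDS translation follows strand and the bacterial code", {
  g <- Biostrings::DNAStringSet(c(ctg = "ATGAAATAA"))
  f <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1, 9), "+",
                              locus_tag = "plus", product = "p")
  expect_equal(as.character(extractProteome(g, f)[["plus"]]), "MK")

  g2 <- Biostrings::DNAStringSet(c(ctg = "TTACATTTT"))
  f2 <- GenomicRanges::GRanges("ctg", IRanges::IRanges(1, 9), "-",
                               locus_tag = "minus", product = "p")
  expect_equal(as.character(extractProteome(g2, f2)[["minus"]]), "KM")
})

test_that("partial and pseudogene CDS are excluded with logged reasons", {
  g <- Biostrings::DNAStringSet(c(ctg = paste0("ATGAAATAA", "ATGTAAAAATAA",
                                               "ATGAAAA")))
  f <- GenomicRanges::GRanges("ctg",
        IRanges::IRanges(c(1, 10, 22), c(9, 21, 28)), "+",
        locus_tag = c("good", "stopinside", "notriplet"),
        product = "p")
  prot <- extractProteome(g, f)
  expect_equal(names(prot), "good")
  excl <- S4Vectors::metadata(prot)$excluded
  expect_setequal(excl$locus_tag, c("stopinside", "notriplet"))
  expect_equal(excl$reason[excl$locus_tag == "stopinside"], "pseudogene")
  expect_equal(excl$reason[excl$locus_tag == "notriplet"], "partial")
  expect_error(extractProteome(g, GenomicRanges::GRanges("ctg",
    IRanges::IRanges(20, 40), "+", locus_tag = "x", product = "p")),
    "within")
})

test_that("a planted multi-gene genome yields proteins at the planned coordinates", {
  set.seed(70)
  prots <- vapply(1:12, function(i)
    paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q",
                   "R","S","T","V","W","Y"), 80, replace = TRUE),
          collapse = ""), character(1))
  plan <- data.frame(contig = "c1", locus_tag = sprintf("g%02d", 1:12),
                     type = "luxI", product = "synthase",
                     strand = rep(c("+", "-"), 6),
                     gap = c(100L, rep(200L, 11)),
                     protein = prots, length_nt = NA_integer_,
                     stringsAsFactors = FALSE)
  gen <- generateGenome(plan, seed = 7)
  prot <- extractProteome(gen$genome, gen$features)
  expect_length(prot, 12L)
  expect_identical(as.character(prot), setNames(prots, plan$locus_tag))
  mc <- S4Vectors::mcols(prot)
  expect_equal(mc$start, gen$truth$start)
  expect_equal(mc$end, gen$truth$end)
})

test_that("scanning recovers exactly one planted family gene among neutral genes", {
  fams <- fxFamilies()
  set.seed(110)
  plan <- rbind(
    data.frame(contig = "c1", locus_tag = sprintf("n%02d", 1:10),
               type = "neighbor", product = "hypothetical protein",
               strand = "+", gap = 300L, protein = NA_character_,
               length_nt = 600L, stringsAsFactors = FALSE),
    data.frame(contig = "c1", locus_tag = "planted", type = "luxI",
               product = "synthase", strand = "-", gap = 250L,
               protein = as.character(fams$luxI[[7]]),
               length_nt = NA_integer_, stringsAsFactors = FALSE),
    data.frame(contig = "c1", locus_tag = sprintf("n%02d", 11:20),
               type = "neighbor", product = "hypothetical protein",
               strand = "-", gap = 300L, protein = NA_character_,
               length_nt = 600L, stringsAsFactors = FALSE))
  gen <- generateGenome(plan, seed = 11)
  prot <- extractProteome(gen$genome, gen$features)
  hits <- scanProteome(prot, fxLuxIModel())
  expect_length(hits, 1L)
  expect_equal(hits$locus_tag, "planted")
  truthRow <- gen$truth[gen$truth$locus_tag == "planted", ]
  expect_equal(GenomicRanges::start(hits), truthRow$start)
  expect_equal(GenomicRanges::end(hits), truthRow$end)
  expect_equal(as.character(GenomicRanges::strand(hits)), "-")
  expect_true(all(hits$evalue <= inclusionCutoff(fxLuxIModel())))
})

test_that("an empty proteome scans to an empty hit table", {
  hits <- scanProteome(Biostrings::AAStringSet(character(0)), fxLuxIModel())
  expect_length(hits, 0L)
  expect_true(all(c("locus_tag", "family", "evalue") %in%
                  colnames(S4Vectors::mcols(hits))))
})

test_that("length typicality flags use the family-specific inclusive ranges", {
  expect_equal(flagLengthClass("LuxI", c(156, 157, 257, 258)),
               c("atypical", "typical", "typical", "atypical"))
  expect_equal(flagLengthClass("LuxR", c(209, 210, 272, 273, 300)),
               c("atypical", "typical", "typical", "atypical", "atypical"))
})

test_that("hits round-trip through TSV and export valid GFF3", {
  fams <- fxFamilies()
  gen <- fxGenome()
  prot <- extractProteome(gen$genome, gen$features)
  hits <- scanProteome(prot, fxLuxIModel())
  tsv <- tempfile(fileext = ".tsv"); gff <- tempfile(fileext = ".gff3")
  writeHits(hits, tsv, gff)
  back <- readHits(tsv)
  expect_equal(length(back), length(hits))
  expect_equal(back$locus_tag, hits$locus_tag)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(hits))
  reimported <- rtracklayer::import(gff)
  expect_equal(length(reimported), length(hits))
})
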