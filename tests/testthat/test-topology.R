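test_that("signed intergenic distances: gap, abutting, overlap, cross-contig", {
  a <- gr1(1, 100)
  expect_equal(intergenicDistance(a, gr1(101, 200)), 0L)
  expect_equal(intergenicDistance(a, gr1(150, 200)), 49L)
  expect_equal(intergenicDistance(a, gr1(80, 180)), -21L)
  expect_true(is.na(intergenicDistance(a, gr1(150, 200, seq = "other"))))
})

test_that("intergenic distance is symmetric and matches a brute-force oracle on random layouts", {
  set.seed(31)
  for (k in 1:60) {
    s1 <- sample(1:500, 1); e1 <- s1 + sample(0:300, 1)
    s2 <- sample(1:500, 1); e2 <- s2 + sample(0:300, 1)
    a <- gr1(s1, e1); b <- gr1(s2, e2)
    expect_equal(intergenicDistance(a, b), oracleDistance(s1, e1, s2, e2))
    expect_equal(intergenicDistance(a, b), intergenicDistance(b, a))
  }
})

test_that("orientation classes derive from the strands of the positionally ordered pair", {
  expect_equal(classifyOrientation(gr1(1, 100, "+"), gr1(200, 300, "+")),
               "co_directional")
  expect_equal(classifyOrientation(gr1(1, 100, "-"), gr1(200, 300, "-")),
               "co_directional")
  expect_equal(classifyOrientation(gr1(1, 100, "+"), gr1(200, 300, "-")),
               "convergent")
  expect_equal(classifyOrientation(gr1(1, 100, "-"), gr1(200, 300, "+")),
               "divergent")
  # argument order must not matter; position decides who is upstream
  expect_equal(classifyOrientation(gr1(200, 300, "-"), gr1(1, 100, "+")),
               "convergent")
})

mkHit <- function(start, end, strand, tag, family, evalue = 1e-30,
                  architecture = NA_character_, seq = "ctg") {
  gr <- GenomicRanges::GRanges(seq, IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    locus_tag = tag, family = family, evalue = evalue,
    bitscore = 100, proteinLength = 200L, lengthClass = "typical",
    product = "", architecture = architecture)
  gr
}

test_that("pairing prefers canonical architecture over a nearer HTH-only candidate", {
  hits <- c(mkHit(1000, 1900, "+", "I1", "LuxI"),
            mkHit(1950, 2500, "+", "R_hth", "LuxR",
                  architecture = "HTH_ONLY"),
            mkHit(2591, 3100, "+", "R_can", "LuxR",
                  architecture = "CANONICAL"))
  topo <- findCognatePairs(hits)
  expect_equal(nrow(topo$pairs), 1L)
  expect_equal(topo$pairs$luxR, "R_can")
  expect_equal(topo$pairs$distance, 690L)
  # the losing HTH-only candidate is a solo with its exact distance
  expect_equal(topo$solos$locus_tag, "R_hth")
  expect_equal(topo$solos$nearest_partner_distance, 49L)
  expect_true(topo$solos$withinWindow)
})

test_that("pairs never form across contigs or beyond the window; solos keep exact distances", {
  hits <- suppressWarnings(
    c(mkHit(1000, 1900, "+", "I1", "LuxI"),
      mkHit(314901, 315500, "+", "R_far", "LuxR",
            architecture = "CANONICAL"),
      mkHit(500, 1200, "-", "R_other", "LuxR",
            architecture = "CANONICAL", seq = "ctg2")))
  topo <- findCognatePairs(hits)
  expect_equal(nrow(topo$pairs), 0L)
  solos <- topo$solos
  expect_equal(solos$nearest_partner_distance[solos$locus_tag == "I1"],
               313000L)
  expect_false(any(solos$withinWindow))
  expect_true(is.na(
    solos$nearest_partner_distance[solos$locus_tag == "R_other"]))
})

test_that("pair calls are stable under hit-order permutation", {
  fams <- fxFamilies()
  gen <- fxGenome()
  prot <- extractProteome(gen$genome, gen$features)
  hits <- c(scanProteome(prot, fxLuxIModel()),
            scanProteome(prot, fxLuxRModel()))
  dh <- domainScan(prot[hits$locus_tag[hits$family == "LuxR"]],
                   list(ABD = fxAbdModel(), HTH = fxHthModel()))
  hits <- annotateArchitecture(hits, dh)
  t1 <- findCognatePairs(hits)
  set.seed(77)
  t2 <- findCognatePairs(hits[sample(length(hits))])
  expect_equal(t1$pairs, t2$pairs)
  expect_equal(t1$solos[order(t1$solos$locus_tag), ],
               t2$solos[order(t2$solos$locus_tag), ],
               ignore_attr = TRUE)
})

test_that("neighborhood inventories match a brute-force interval scan", {
  set.seed(91)
  starts <- sort(sample(seq(1, 60000, by = 200), 25))
  feats <- GenomicRanges::GRanges("c1",
    IRanges::IRanges(starts, starts + sample(200:900, 25, replace = TRUE)),
    strand = sample(c("+", "-"), 25, TRUE),
    locus_tag = sprintf("g%02d", 1:25),
    product = sample(c("hypothetical protein", "monooxygenase",
                       "ABC transporter"), 25, TRUE))
  focal <- feats[13]
  for (flank in c(0L, 3000L, 10000L)) {
    inv <- neighborhoodInventory(focal, feats, flank)
    lo <- GenomicRanges::start(focal) - flank
    hi <- GenomicRanges::end(focal) + flank
    expectIdx <- which(GenomicRanges::start(feats) <= hi &
                       GenomicRanges::end(feats) >= lo)
    expect_setequal(inv$locus_tag, feats$locus_tag[expectIdx])
    expect_false(is.unsorted(inv$start))
  }
  inv0 <- neighborhoodInventory(focal, feats, 0L)
  expect_true(all(inv0$offset == 0L))
})

test_that("the planted redox neighborhood reports its ETF gene at +124 with a -46 internal overlap", {
  gen <- fxGenome()
  truth <- gen$truth
  luxI <- gen$features[gen$features$locus_tag == "c2g03"]
  inv <- neighborhoodInventory(luxI, gen$features, 3000L)
  etfA <- inv[inv$locus_tag == "c2g04", ]
  expect_equal(etfA$offset, 124L)
  expect_equal(etfA$category, "redox_electron_transfer")
  expect_true("sulfur_trna" %in% inv$category)
  fA <- gen$features[gen$features$locus_tag == "c2g04"]
  fB <- gen$features[gen$features$locus_tag == "c2g05"]
  expect_equal(intergenicDistance(fA, fB), -46L)
})

test_that("product categorization is a deterministic first-match keyword lookup", {
  expect_equal(categorizeProduct("electron transfer flavoprotein subunit A"),
               "redox_electron_transfer")
  expect_equal(categorizeProduct(c("cysteine desulfurase IscS",
                                   "tRNA-specific 2-thiouridylase MnmA")),
               c("sulfur_trna", "sulfur_trna"))
  expect_equal(categorizeProduct("cyclohexanone monooxygenase"),
               "secondary_metabolism")
  expect_equal(categorizeProduct("sensor histidine kinase RcsC"),
               "stress_sensing")
  expect_equal(categorizeProduct("ABC transporter permease"), "transport")
  expect_equal(categorizeProduct("hypothetical protein"), "hypothetical")
  expect_equal(categorizeProduct(""), "other")
})
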