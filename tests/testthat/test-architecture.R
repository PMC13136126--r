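test_that("architecture classes follow the 2x2 domain presence table", {
  canonical <- data.frame(domain = c("IPR005143", "IPR000792"),
                          start = c(10, 175), end = c(160, 230),
                          evalue = c(1e-20, 1e-15))
  expect_equal(classifyArchitecture(240, canonical)$architecture, "CANONICAL")
  expect_false(classifyArchitecture(240, canonical)$anomaly)

  hth <- data.frame(domain = "IPR000792", start = 150, end = 210,
                    evalue = 1e-12)
  expect_equal(classifyArchitecture(220, hth)$architecture, "HTH_ONLY")

  abd <- data.frame(domain = "PF03472", start = 5, end = 150, evalue = 1e-9)
  expect_equal(classifyArchitecture(200, abd)$architecture, "ABD_ONLY")

  expect_equal(classifyArchitecture(200, NULL)$architecture, "NONE")
  expect_equal(classifyArchitecture(200,
    data.frame(domain = character(0), start = integer(0),
               end = integer(0), evalue = numeric(0)))$architecture, "NONE")
})

test_that("a C-terminal ABD raises the advisory anomaly flag without changing the class", {
  swapped <- data.frame(domain = c("IPR000792", "IPR036693"),
                        start = c(10, 150), end = c(70, 230),
                        evalue = c(1e-15, 1e-15))
  res <- classifyArchitecture(240, swapped)
  expect_equal(res$architecture, "CANONICAL")
  expect_true(res$anomaly)
})

test_that("weak hits are ignored and bad coordinates are an input error", {
  weak <- data.frame(domain = "IPR000792", start = 10, end = 60,
                     evalue = 1e-3)
  expect_equal(classifyArchitecture(100, weak)$architecture, "NONE")
  bad <- data.frame(domain = "IPR000792", start = 10, end = 300,
                    evalue = 1e-15)
  expect_error(classifyArchitecture(100, bad), "protein length")
})

test_that("classification is invariant to domain-hit order", {
  hits <- data.frame(domain = c("IPR005143", "IPR000792", "PF03472"),
                     start = c(10, 175, 12), end = c(160, 230, 155),
                     evalue = c(1e-20, 1e-15, 1e-8))
  a <- classifyArchitecture(240, hits)
  b <- classifyArchitecture(240, hits[c(3, 1, 2), ])
  expect_identical(a, b)
})

test_that("built-in mini-profiles locate the ABD and HTH regions on canonical LuxR proteins", {
  fams <- fxFamilies()
  prot <- fams$luxRCanonical[1:5]
  dh <- domainScan(prot, list(ABD = fxAbdModel(), HTH = fxHthModel()))
  expect_equal(attr(dh, "source"), "builtin_profile")
  for (id in names(prot)) {
    sub <- dh[dh$proteinId == id, ]
    expect_setequal(sub$domain, c("ABD", "HTH"))
    abdMid <- mean(unlist(sub[sub$domain == "ABD", c("start", "end")]))
    hthMid <- mean(unlist(sub[sub$domain == "HTH", c("start", "end")]))
    expect_lt(abdMid, hthMid)   # N-terminal ABD, C-terminal HTH
  }
  # HTH-only members must show HTH but no ABD evidence
  dh2 <- domainScan(fams$luxRHthOnly[1:3],
                    list(ABD = fxAbdModel(), HTH = fxHthModel()))
  expect_true(all(dh2$domain == "HTH"))
})

test_that("InterProScan-style TSV parsing emits signature and InterPro evidence", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(paste(
    c("prot1\tmd5\t240\tPfam\tPF03472\tAutoind_bind\t8\t160\t3.2E-40\tT\t01-01-2020\tIPR005143\tdesc",
      "prot1\tmd5\t240\tPfam\tPF00196\tGerE\t175\t230\t1.1E-20\tT\t01-01-2020\tIPR000792\tdesc",
      "prot2\tmd5\t210\tPfam\tPF00196\tGerE\t150\t208\t2.0E-18\tT\t01-01-2020\t-\tdesc"),
    collapse = "\n"), tsv)
  dh <- readDomainTsv(tsv)
  expect_equal(attr(dh, "source"), "interproscan_tsv")
  p1 <- dh[dh$proteinId == "prot1", ]
  expect_setequal(p1$domain, c("PF03472", "PF00196", "IPR005143",
                               "IPR000792"))
  expect_equal(classifyArchitecture(240, p1)$architecture, "CANONICAL")
  p2 <- dh[dh$proteinId == "prot2", ]
  expect_equal(classifyArchitecture(210, p2)$architecture, "NONE")
  # PF00196 alone is not in the HTH evidence set; the IPR row is
  expect_equal(classifyArchitecture(240,
    p1[p1$domain == "IPR000792", ])$architecture, "HTH_ONLY")
})

test_that("per-genome count summaries are additive over contigs", {
  gen <- fxGenome()
  prot <- extractProteome(gen$genome, gen$features)
  hits <- c(scanProteome(prot, fxLuxIModel()),
            scanProteome(prot, fxLuxRModel()))
  dh <- domainScan(prot[hits$locus_tag[hits$family == "LuxR"]],
                   list(ABD = fxAbdModel(), HTH = fxHthModel()))
  hits <- annotateArchitecture(hits, dh)
  total <- summarizeCounts(hits, "demo")
  expect_equal(total$n_luxR,
               total$n_canonical + total$n_hth_only + total$n_other)
  perContig <- lapply(unique(GenomicRanges::seqnames(hits)), function(ctg)
    summarizeCounts(hits[GenomicRanges::seqnames(hits) == ctg], "part"))
  summed <- Reduce(`+`, lapply(perContig, function(d) d[, -1]))
  expect_equal(summed, total[, -1])
  expect_equal(summarizeCounts(hits[0], "empty")$n_luxR, 0L)
})
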