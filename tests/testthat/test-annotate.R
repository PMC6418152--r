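test_that("fold enrichment matches the worked arithmetic", {
  # genome 3 Mb, HIRs cover 24 kb (0.8%), 1000 features of which 40 overlap
  hirs <- gr0("chr1", seq(0, 23 * 1e5, by = 1e5)[1:24],
              seq(0, 23 * 1e5, by = 1e5)[1:24] + 1000, name = paste0("h", 1:24))
  inHIR <- gr0("chr1", GenomicRanges::start(hirs)[1:20] - 1 + 500,
               GenomicRanges::start(hirs)[1:20] - 1 + 501)
  inHIR <- c(inHIR, GenomicRanges::shift(inHIR, 100))   # 40 overlapping
  out <- gr0("chr1", seq(2.4e6, 2.9e6, length.out = 960),
             seq(2.4e6, 2.9e6, length.out = 960) + 1)
  feats <- c(inHIR, out)
  rep <- overlapCount(hirs, feats, genomeSize = 3e6)
  expect_equal(rep$nFeatures, 1000)
  expect_equal(rep$observed, 40)
  expect_equal(rep$expected, 8)
  expect_equal(rep$fold, 5)
  expect_equal(rep$fraction, 0.04)
  expect_error(overlapCount(hirs, feats, genomeSize = 0), "positive")
})

test_that("features identical to the HIRs are all overlapped", {
  hirs <- gr0("chr1", c(0, 1e5), c(5e4, 1.5e5), name = c("a", "b"))
  rep <- overlapCount(hirs, hirs, genomeSize = 1e6)
  expect_equal(rep$fraction, 1)
})

test_that("uniformly placed features show no enrichment", {
  set.seed(61)
  hirs <- gr0("chr1", seq(0, 2.9e6, length.out = 25)[1:24],
              seq(0, 2.9e6, length.out = 25)[1:24] + 1000,
              name = paste0("h", 1:24))
  folds <- replicate(20, {
    pos <- sort(sample.int(3e6 - 1, 1e4))
    feats <- gr0("chr1", pos, pos + 1)
    overlapCount(hirs, feats, genomeSize = 3e6)$fold
  })
  expect_gt(mean(folds), 0.8)
  expect_lt(mean(folds), 1.2)
})

test_that("TAD position labels follow the border/inside/outside rule", {
  tads <- gr0("chr1", 100000, 300000)
  hirs <- gr0("chr1", c(95000, 150000, 400000),
              c(105000, 160000, 440000), name = paste0("h", 1:3))
  expect_equal(tadPosition(hirs, tads), c("border", "inside", "outside"))
  # a HIR whose 0-based end equals a boundary coordinate does not cover it
  edge <- gr0("chr1", 80000, 100000, name = "edge")
  expect_equal(tadPosition(edge, tads), "outside")
  # labels are exhaustive and mutually exclusive by construction
  set.seed(62)
  pos <- sort(sample.int(9e5, 50))
  rnd <- gr0("chr1", pos, pos + 5000, name = paste0("r", 1:50))
  expect_true(all(tadPosition(rnd, tads) %in%
                  c("border", "inside", "outside")))
})

test_that("expression summaries average genes assigned by overlap", {
  hirs <- gr0("chr1", c(0, 2e5), c(1e5, 3e5), name = c("h1", "h2"))
  genes <- gr0("chr1", c(5e4, 6e4, 5e5, 6e5), c(5.5e4, 9e4, 5.2e5, 6.8e5),
               rpkm = c(10, 30, 100, 2))
  res <- expressionSummary(hirs, genes)
  expect_equal(res$perHIR$meanRPKM, c(20, NA))
  expect_equal(res$perHIR$nGenes, c(2L, 0L))
  expect_equal(res$baseline$meanRPKM, mean(c(10, 30, 100, 2)))
  expect_equal(res$perHIR$meanGeneLength[1], mean(c(5000, 30000)))
  # per-class aggregation
  res2 <- expressionSummary(hirs, genes, classes = c(1L, 2L))
  expect_equal(res2$perClass$meanRPKM[res2$perClass$class == 1], 20)
  expect_equal(res2$perClass$nGenes[res2$perClass$class == 2], 0L)
})

test_that("class contacts pick up planted between-hub enrichment", {
  sim <- simulateMap(seed = 63, beta = 3)
  map <- maskZeroRows(sim$map)
  oe <- normalizeMap(map, kind = "oe_divide")
  classes <- rep(1L, length(sim$truth))
  res <- classContacts(oe, sim$truth, classes, nRandom = 2000, seed = 64)
  within <- res$summary[res$summary$pair == "1_vs_1", ]
  rnd <- res$summary[res$summary$pair == "1_vs_random", ]
  # between-hub pairs dominate class 1 vs itself: median near the 3x boost
  expect_gt(within$median, 2)
  expect_lt(within$median, 4)
  expect_lt(rnd$median, 1.5)
})

test_that("class contacts exclude self pairs and respect the seed", {
  sim <- simulateMap(nBins = 80, seed = 65,
                     hubs = list(c(10, 17), c(50, 57)))
  oe <- normalizeMap(maskZeroRows(sim$map), kind = "oe_divide")
  classes <- c(1L, 2L)
  r1 <- classContacts(oe, sim$truth, classes, nRandom = 100, seed = 7)
  r2 <- classContacts(oe, sim$truth, classes, nRandom = 100, seed = 7)
  expect_identical(r1$distributions, r2$distributions)
  # a single-bin class against itself has no pairs
  one <- gr0("chrS", 200000, 205000, name = "solo")
  r3 <- classContacts(oe, one, 1L, nRandom = 10, seed = 1)
  expect_length(r3$distributions[["1_vs_1"]], 0)
})
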