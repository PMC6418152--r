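test_that("percentile threshold uses linear interpolation", {
  v <- c(rep(0, 86), rep(3, 4), rep(5, 10))
  expect_equal(percentileThreshold(v, 90), 3.2)
  expect_equal(percentileThreshold(0:99, 90), 89.1)
  expect_equal(percentileThreshold(rep(2.5, 10), 37), 2.5)
  expect_error(percentileThreshold(rep(NA_real_, 5), 90), "masked")
})

test_that("HIR calling finds exactly the qualifying run", {
  hirs <- callHIRs(profile100(), q = 90, minBins = 5)
  expect_length(hirs, 1)
  # bins 40-46 (0-based) at 5 kb: [200000, 235000)
  expect_equal(GenomicRanges::start(hirs), 200001)
  expect_equal(GenomicRanges::end(hirs), 235000)
  expect_equal(S4Vectors::mcols(hirs)$nBins, 7L)
  expect_equal(S4Vectors::mcols(hirs)$meanStat, 5 / 62)  # profile sums to 62
})

test_that("constant profiles yield no HIRs; minBins = 1 allows single bins", {
  expect_length(callHIRs(makeProfile(rep(2, 50))), 0)
  v <- numeric(50); v[20] <- 1
  one <- callHIRs(makeProfile(v), q = 90, minBins = 1)
  expect_length(one, 1)
  expect_equal(S4Vectors::mcols(one)$nBins, 1L)
})

test_that("a masked bin terminates a run", {
  v <- numeric(100)
  v[41:50] <- 5
  v[45] <- NA          # masked bin splits the 10-run into 4 + 5
  p <- makeProfile(v)
  hirs <- callHIRs(p, q = 90, minBins = 5)
  expect_length(hirs, 1)
  expect_equal(GenomicRanges::start(hirs), 45 * 5000 + 1)
  expect_equal(S4Vectors::mcols(hirs)$nBins, 5L)
})

test_that("at q = 90 no more than 10% of bins (plus ties) exceed threshold", {
  set.seed(21)
  for (rep in 1:10) {
    v <- rexp(sample(50:500, 1))
    thr <- percentileThreshold(v, 90)
    expect_lte(sum(v > thr), length(v) * 0.10 + 1)
  }
})

test_that("tier bands apply the same run rule inside percentile bands", {
  p <- makeProfile(0:99)
  band <- tierRegions(p, 0, 30)
  expect_length(band, 1)
  expect_equal(S4Vectors::mcols(band)$nBins, 30L)  # values 0..29 <= 29.7
  # (90, 100] band reproduces the HIR call on the constructed profile
  p100 <- profile100()
  expect_equal(GenomicRanges::ranges(tierRegions(p100, 90, 100)),
               GenomicRanges::ranges(callHIRs(p100)))
  # empty band
  expect_length(tierRegions(makeProfile(rep(1, 20)), 30, 50), 0)
})

test_that("flank arithmetic matches the stated rule", {
  hir <- gr0("chrT", 200000, 235000, seqlen = 1e6, name = "h1")
  S4Vectors::metadata(hir)$binSize <- 5000
  fl <- makeFlanks(hir, offset = 1e5)
  df <- data.frame(flank = S4Vectors::mcols(fl)$flank,
                   side = S4Vectors::mcols(fl)$side,
                   start0 = GenomicRanges::start(fl) - 1,
                   end0 = GenomicRanges::end(fl))
  expect_equal(df[df$flank == "F1" & df$side == "left", c("start0", "end0")],
               data.frame(start0 = 165000, end0 = 200000),
               ignore_attr = TRUE)
  expect_equal(df[df$flank == "F1" & df$side == "right", c("start0", "end0")],
               data.frame(start0 = 235000, end0 = 270000),
               ignore_attr = TRUE)
  expect_equal(df[df$flank == "F2" & df$side == "left", c("start0", "end0")],
               data.frame(start0 = 65000, end0 = 100000),
               ignore_attr = TRUE)
  expect_equal(df[df$flank == "F2" & df$side == "right", c("start0", "end0")],
               data.frame(start0 = 335000, end0 = 370000),
               ignore_attr = TRUE)
  expect_false(any(S4Vectors::mcols(fl)$clipped))
})

test_that("flanks at the chromosome start are clipped and flagged", {
  hir <- gr0("chrT", 10000, 45000, seqlen = 1e6, name = "h1")
  fl <- makeFlanks(hir, offset = 1e5)
  mc <- S4Vectors::mcols(fl)
  f1l <- fl[mc$flank == "F1" & mc$side == "left"]
  expect_equal(GenomicRanges::start(f1l), 1)  # clipped at chromosome start
  expect_true(S4Vectors::mcols(f1l)$clipped)
  # the F2 left flank would lie entirely before the chromosome: dropped
  expect_length(fl[mc$flank == "F2" & mc$side == "left"], 0)
})

test_that("offset 0 collapses F2 onto F1", {
  hir <- gr0("chrT", 200000, 235000, seqlen = 1e6, name = "h1")
  fl <- makeFlanks(hir, offset = 0)
  mc <- S4Vectors::mcols(fl)
  expect_equal(GenomicRanges::ranges(fl[mc$flank == "F1"]),
               GenomicRanges::ranges(fl[mc$flank == "F2"]))
})

test_that("HIR calls are reproducible bit-exactly", {
  m <- simulateMap(nBins = 100, seed = 3)$map
  call1 <- callHIRs(stationaryDistribution(
    buildTransitionMatrix(normalizeMap(maskZeroRows(m)))))
  call2 <- callHIRs(stationaryDistribution(
    buildTransitionMatrix(normalizeMap(maskZeroRows(m)))))
  expect_identical(call1, call2)
})
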