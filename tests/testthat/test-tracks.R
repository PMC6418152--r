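test_that("downsampling averages constituent bins and keeps NA semantics", {
  tr <- SignalTrack(c(1, 3, 5, 7), binSize = 2500)
  expect_equal(binValues(downsampleTrack(tr, 5000)), c(2, 6))
  expect_equal(binValues(downsampleTrack(SignalTrack(c(1, NA), binSize = 2500),
                                         5000)), 1)
  expect_equal(binValues(downsampleTrack(SignalTrack(c(NA, NA),
                                         binSize = 2500), 5000)), NA_real_)
  expect_error(downsampleTrack(tr, 6000), "multiple")
})

test_that("percentile normalization maps background to 0 and max to 100", {
  expect_equal(binValues(normalizeTrack(SignalTrack(0:9))),
               c(0, 0, 0, 0, 0, 20, 40, 60, 80, 100))
  expect_equal(binValues(normalizeTrack(SignalTrack(rep(4, 8)))), rep(0, 8))
  # a single above-average value maps to 100
  expect_equal(binValues(normalizeTrack(SignalTrack(c(1, 1, 1, 9)))),
               c(0, 0, 0, 100))
  # ties take the max rank: mean 8, above-mean values (10, 10, 20)
  expect_equal(binValues(normalizeTrack(SignalTrack(c(0, 4, 4, 10, 10, 20)))),
               c(0, 0, 0, 200 / 3, 200 / 3, 100))
  # missing stays missing
  expect_equal(binValues(normalizeTrack(SignalTrack(c(0, NA, 10)))),
               c(0, NA, 100))
  expect_error(normalizeTrack(SignalTrack(rep(NA_real_, 4))), "no data")
})

test_that("normalization is invariant to rank-preserving transforms", {
  set.seed(31)
  for (rep in 1:5) {
    v <- rexp(200)
    mu <- mean(v)
    # strictly increasing transform that fixes the mean-crossing set
    w <- v + 100 * (v > mu)
    expect_true(all(w[v > mu] > mean(w)) && all(w[v <= mu] <= mean(w)))
    expect_equal(binValues(normalizeTrack(SignalTrack(v))),
                 binValues(normalizeTrack(SignalTrack(w))))
  }
})

test_that("re-normalizing keeps zeros at zero and preserves positive ranks", {
  set.seed(33)
  v <- binValues(normalizeTrack(SignalTrack(rexp(100))))
  tr2 <- normalizeTrack(SignalTrack(v, normalized = FALSE))
  v2 <- binValues(tr2)
  expect_true(all(v2[v == 0] == 0))
  pos <- v2 > 0
  expect_equal(order(v[pos]), order(v2[pos]))
})

test_that("dataset exclusion applies the missing-data and enrichment rules", {
  hirs <- gr0("chrT", 0, 50000, name = "h1")   # bins 1..10 at 5 kb
  mk <- function(vals, name) SignalTrack(vals, name = name, chrom = "chrT",
                                         binSize = 5000, normalized = TRUE)
  n <- 100
  mostlyMissing <- mk(c(runif(40, 0, 100), rep(NA, 60)), "mostlyMissing")
  flat <- mk(rep(c(1.5, 0), c(10, 90)), "lowAtHIRs")
  good <- mk(rep(c(30, 0), c(10, 90)), "good")
  res <- excludeDatasets(list(mostlyMissing, flat, good), hirs)
  expect_equal(vapply(res$kept, function(t) t@name, ""), "good")
  expect_equal(res$dropped$reason[res$dropped$name == "mostlyMissing"],
               "missing>50%")
  expect_equal(res$dropped$reason[res$dropped$name == "lowAtHIRs"],
               "low enrichment")
})

test_that("region enrichment separates a maximal HIR signal from flanks", {
  hirs <- gr0("chrT", c(200000, 400000, 600000), c(235000, 435000, 635000),
              seqlen = 1e6, name = paste0("h", 1:3))
  fl <- makeFlanks(hirs, offset = 1e5)
  set.seed(34)
  v <- runif(200)      # near-zero background with some spread
  for (k in seq_along(hirs))
    v[(GenomicRanges::start(hirs)[k] %/% 5000 + 1):
        (GenomicRanges::end(hirs)[k] %/% 5000)] <- 100 - k
  tr <- SignalTrack(v, chrom = "chrT", binSize = 5000, normalized = TRUE)
  res <- regionEnrichment(tr, hirs, fl)
  expect_equal(res$means$mean[res$means$set == "HIR"], c(99, 98, 97))
  expect_true(all(res$means$mean[res$means$set != "HIR"] < 1))
  expect_true(all(res$tests$p < 1e-3))   # Welch df is tiny with 3 regions
  expect_true(all(res$tests$meanDiff > 95))
})

test_that("a single HIR leaves the t statistic undefined", {
  hirs <- gr0("chrT", 200000, 235000, seqlen = 1e6, name = "h1")
  fl <- makeFlanks(hirs)
  tr <- SignalTrack(runif(200, 0, 100), chrom = "chrT", binSize = 5000,
                    normalized = TRUE)
  res <- regionEnrichment(tr, hirs, fl)
  expect_true(all(is.na(res$tests$t)))
})

test_that("Spearman correlation behaves on monotone, self and null inputs", {
  x <- as.numeric(1:10)
  st <- function(v) SignalTrack(v, chrom = "chrT", binSize = 1e5)
  p <- makeProfile(x, binSize = 1e5)
  expect_equal(spearmanVsProfile(st(2 * x), p, window = 1e5)$rho, 1)
  expect_equal(spearmanVsProfile(st(-x), p, window = 1e5)$rho, -1)
  # profile against itself
  set.seed(32)
  v <- rexp(50)
  pv <- makeProfile(v, binSize = 1e5)
  expect_equal(spearmanVsProfile(st(v), pv, window = 1e5)$rho, 1)
  # independent pairs: |rho| small
  null <- spearmanVsProfile(st(rnorm(1000)), makeProfile(rexp(1000),
                            binSize = 1e5), window = 1e5)
  expect_lt(abs(null$rho), 0.1)
  expect_error(spearmanVsProfile(st(c(1, 2)),
                                 makeProfile(c(1, 2), binSize = 1e5),
                                 window = 1e5), "3 paired")
})

test_that("windows are averaged and pooled across chromosomes", {
  tr1 <- SignalTrack(c(1, 3, 5, 7, 9, 11), chrom = "chrA", binSize = 50000)
  p1 <- makeProfile(c(2, 4, 6, 8, 10, 12), chrom = "chrA", binSize = 50000)
  tr2 <- SignalTrack(c(10, 20), chrom = "chrB", binSize = 50000)
  p2 <- makeProfile(c(30, 10), chrom = "chrB", binSize = 50000)
  res <- spearmanVsProfile(list(tr1, tr2), list(p1, p2), window = 1e5)
  expect_equal(res$n, 4)
  # chroms filter restricts to the named chromosomes
  res2 <- spearmanVsProfile(list(tr1, tr2), list(p1, p2), window = 1e5,
                            chroms = "chrA")
  expect_equal(res2$n, 3)
  expect_equal(res2$rho, 1)
})

test_that("bedGraph tracks round-trip through read and write", {
  tr <- SignalTrack(c(1.5, NA, 3.25, 0), name = "t", chrom = "chrT",
                    binSize = 5000)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  writeBedGraphTrack(tr, f)
  back <- readBedGraphTrack(f, chrom = "chrT", binSize = 5000, nBins = 4)
  expect_equal(binValues(back), c(1.5, NA, 3.25, 0))
})
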