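# Shared fixtures, all built in code.

# 4x4 worked micro-example map: expected profile (10.5, 5, 2, 1); after
# subtract-normalization and clamping only bins 2 and 3 survive, with
# stationary distribution (0.625, 0.375).
microMap <- function() {
  v <- rbind(c(10, 5, 2, 1),
             c(5, 12, 6, 2),
             c(2, 6, 11, 4),
             c(1, 2, 4, 9))
  ContactMap(v, chrom = "chrT", binSize = 5000)
}

# StationaryProfile from raw values (normalized to sum to one; HIR calling
# is scale-invariant).
makeProfile <- function(values, chrom = "chrT", binSize = 5000,
                        method = "rowsum") {
  p <- values / sum(values, na.rm = TRUE)
  new("StationaryProfile", chrom = chrom, binSize = binSize, p = p,
      method = method)
}

# 100-bin constructed profile: 86 zeros, bins 10-13 (0-based) = 3,
# bins 40-46 = 5, bins 60-62 = 5.  90th percentile threshold 3.2; the only
# qualifying run of >= 5 bins is 40-46.
profile100 <- function() {
  v <- numeric(100)
  v[11:14] <- 3
  v[41:47] <- 5
  v[61:63] <- 5
  makeProfile(v)
}

# NormalizedMap wrapper around a symmetric non-negative weight matrix, so
# stationary-method tests can feed weights directly.
weightsAsNormalizedMap <- function(A, chrom = "chrW", binSize = 5000,
                                   mask = integer(0)) {
  new("NormalizedMap", chrom = chrom, binSize = binSize,
      values = unname(A), mask = as.integer(mask), kind = "oe_subtract")
}

# Random symmetric connected weight matrix: positive super/subdiagonal
# guarantees connectivity.
randomConnectedWeights <- function(n) {
  A <- matrix(stats::runif(n * n), n)
  A[A < 0.3] <- 0
  A <- (A + t(A)) / 2
  if (n > 1) {
    band <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
    A[band] <- A[band[, c(2, 1), drop = FALSE]] <- stats::runif(n - 1) + 0.1
  }
  A
}

stationaryFromWeights <- function(A, method = "eig", ...) {
  tm <- buildTransitionMatrix(weightsAsNormalizedMap(A))
  binValues(stationaryDistribution(tm, method = method, ...))
}

# Plain Rand index between two partitions.
randIndex <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  sameA <- outer(a, a, "==")[upper.tri(diag(n))]
  sameB <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(sameA == sameB)
}

# GRanges shorthand on a synthetic genome (0-based half-open inputs).
gr0 <- function(chrom, start0, end0, seqlen = NULL, ...) {
  sq <- if (is.null(seqlen)) NULL else
    GenomeInfoDb::Seqinfo(seqnames = unique(chrom), seqlengths = seqlen)
  g <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1, end = end0), seqinfo = sq)
  mc <- list(...)
  for (nm in names(mc)) S4Vectors::mcols(g)[[nm]] <- mc[[nm]]
  g
}
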