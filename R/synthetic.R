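#' Default planted hub layout
#'
#' Five disjoint 8-bin hub blocks spread along a 500-bin chromosome
#' (1-based inclusive bin intervals).
#'
#' @param nBins chromosome length in bins.
#' @return list of `c(startBin, endBin)` pairs.
#' @export
defaultHubs <- function(nBins = 500) {
  starts <- round(seq(0.12, 0.88, length.out = 5) * nBins)
  lapply(starts, function(s) c(s, min(s + 7L, nBins)))
}

#' Simulate a Hi-C contact map with planted interaction hubs
#'
#' Contacts follow the canonical power-law distance decay of intra-
#' chromosomal Hi-C: the mean contact frequency between bins `i` and `j`
#' is `lambda0 * (1 + |i - j|)^(-alpha)`, multiplied by the hub boost
#' `beta` whenever `i` and `j` lie in two *different* hub blocks (the
#' planted structure is excess long-range contact between hubs, the
#' signature picked up by the stationary distribution).  Observed counts
#' are Poisson draws around these means, symmetrized by mirroring the
#' upper triangle.
#'
#' The defaults describe a deeply sequenced 5 kb map: ~1000 counts in
#' diagonal bins, decay exponent 1, five 8-bin hubs boosted five-fold.
#'
#' @param nBins number of bins, default 500.
#' @param binSize bin width in bp, default 5000.
#' @param chrom chromosome name for the synthetic chromosome.
#' @param alpha distance-decay exponent, `> 0`.
#' @param lambda0 base intensity (mean diagonal count), `> 0`.
#' @param hubs list of 1-based `c(startBin, endBin)` hub blocks (disjoint),
#'   or a `GRanges`; default [defaultHubs()].
#' @param beta hub boost multiplier, `>= 1`.
#' @param seed RNG seed.
#' @return list with `map` (a [ContactMap-class]) and `truth` (`GRanges`
#'   of the hub blocks with metadata column `hub`).
#' @export
simulateMap <- function(nBins = 500, binSize = 5000, chrom = "chrS",
                        alpha = 1, lambda0 = 1000, hubs = defaultHubs(nBins),
                        beta = 5, seed = NULL) {
  stopifnot(alpha > 0, lambda0 >= 0, beta >= 1)
  if (is(hubs, "GRanges"))
    hubs <- lapply(seq_along(hubs), function(k)
      c((GenomicRanges::start(hubs)[k] - 1) %/% binSize + 1,
        (GenomicRanges::end(hubs)[k] - 1) %/% binSize + 1))
  hubId <- integer(nBins)
  for (k in seq_along(hubs)) {
    b <- hubs[[k]]
    if (any(hubId[b[1]:b[2]] != 0L))
      stop("hub blocks must be disjoint")
    hubId[b[1]:b[2]] <- k
  }
  if (!is.null(seed))
    set.seed(seed)
  d <- abs(outer(seq_len(nBins), seq_len(nBins), "-"))
  mu <- lambda0 * (1 + d)^(-alpha)
  cross <- outer(hubId, hubId, function(a, b) a > 0L & b > 0L & a != b)
  mu[cross] <- mu[cross] * beta
  x <- matrix(0, nBins, nBins)
  up <- upper.tri(x, diag = TRUE)
  x[up] <- stats::rpois(sum(up), mu[up])
  x <- x + t(x) - diag(diag(x))
  truth <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(
      start = vapply(hubs, function(b) (b[1] - 1) * binSize + 1, numeric(1)),
      end = vapply(hubs, function(b) b[2] * binSize, numeric(1))),
    seqinfo = GenomeInfoDb::Seqinfo(chrom, nBins * binSize))
  S4Vectors::mcols(truth)$hub <- seq_along(hubs)
  S4Vectors::mcols(truth)$name <- paste0("hub", seq_along(hubs))
  list(map = ContactMap(x, chrom = chrom, binSize = binSize), truth = truth)
}

#' Simulate signal tracks with planted enrichment archetypes
#'
#' Every hub block carries a class label; bins inside a hub of class `c`
#' get, on track `t`, the archetype level `archetypes[c, t]` plus Gaussian
#' noise, while background bins get `baseline` plus noise.  This emulates
#' a panel of ChIP-seq-like tracks whose joint enrichment pattern
#' distinguishes functional classes of hubs.
#'
#' @param truth hub `GRanges` from [simulateMap()].
#' @param archetypes classes x tracks matrix of enrichment levels.
#' @param classOf integer class (row of `archetypes`) per hub; default
#'   cycles through the classes.
#' @param nBins,binSize track geometry (defaults taken from `truth`'s
#'   seqlengths).
#' @param noiseSd Gaussian noise standard deviation, default 5.
#' @param baseline background level, default 0.
#' @param seed RNG seed.
#' @return list with `tracks` (list of raw [SignalTrack-class]),
#'   `classOf` (class per hub) and `binClass` (class per bin, 0 =
#'   background).
#' @export
simulateTracks <- function(truth, archetypes, classOf = NULL,
                           nBins = NULL, binSize = NULL,
                           noiseSd = 5, baseline = 0, seed = NULL) {
  if (is.null(binSize))
    binSize <- S4Vectors::metadata(truth)$binSize
  sqlen <- GenomeInfoDb::seqlengths(truth)[1]
  if (is.null(binSize))
    binSize <- 5000
  if (is.null(nBins))
    nBins <- as.integer(sqlen / binSize)
  nClass <- nrow(archetypes)
  if (is.null(classOf))
    classOf <- rep_len(seq_len(nClass), length(truth))
  stopifnot(length(classOf) == length(truth), all(classOf %in% seq_len(nClass)))
  if (!is.null(seed))
    set.seed(seed)
  binClass <- integer(nBins)
  for (k in seq_along(truth)) {
    lo <- (GenomicRanges::start(truth)[k] - 1) %/% binSize + 1
    hi <- (GenomicRanges::end(truth)[k] - 1) %/% binSize + 1
    binClass[lo:hi] <- classOf[k]
  }
  chromName <- as.character(GenomicRanges::seqnames(truth))[1]
  tracks <- lapply(seq_len(ncol(archetypes)), function(t) {
    mu <- ifelse(binClass > 0L, archetypes[pmax(binClass, 1L), t], baseline)
    SignalTrack(mu + stats::rnorm(nBins, sd = noiseSd),
                name = if (!is.null(colnames(archetypes)))
                  colnames(archetypes)[t] else sprintf("track%02d", t),
                chrom = chromName, binSize = binSize)
  })
  list(tracks = tracks, classOf = classOf, binClass = binClass)
}

#' Recovery of planted hubs by called HIRs
#'
#' @param hirs called HIR `GRanges`.
#' @param truth planted hub `GRanges`.
#' @return list with `recall` (fraction of planted blocks overlapped by at
#'   least one HIR), `precision` (fraction of called HIR bp lying inside
#'   planted blocks) and `binRecall` (fraction of planted bp covered by
#'   HIRs).
#' @export
hubRecovery <- function(hirs, truth) {
  recall <- if (length(truth))
    mean(GenomicRanges::countOverlaps(truth, hirs) > 0) else NA_real_
  hirBp <- sum(GenomicRanges::width(GenomicRanges::reduce(hirs)))
  inter <- GenomicRanges::intersect(GenomicRanges::reduce(hirs),
                                    GenomicRanges::reduce(truth),
                                    ignore.strand = TRUE)
  interBp <- sum(GenomicRanges::width(inter))
  truthBp <- sum(GenomicRanges::width(GenomicRanges::reduce(truth)))
  list(recall = recall,
       precision = if (hirBp > 0) interBp / hirBp else NA_real_,
       binRecall = if (truthBp > 0) interBp / truthBp else NA_real_)
}
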