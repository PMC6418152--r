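#' Overlap a feature set with HIRs against a uniform-genome expectation
#'
#' A feature counts as overlapped if it shares at least one bp with any
#' HIR.  The expected number of overlapped features under the assumption
#' that features are evenly distributed throughout the genome is
#' `n_features * (total HIR bp / genome bp)`; the fold enrichment is
#' observed over expected.
#'
#' @param hirs HIR `GRanges` (any region set works).
#' @param features annotation `GRanges`.
#' @param chromLengths named vector of chromosome lengths; the genome size
#'   is their sum.  Alternatively give `genomeSize` directly.
#' @param genomeSize total genome size in bp (overrides `chromLengths`).
#' @return one-row data.frame with `nFeatures`, `observed`, `expected`,
#'   `fold` and `fraction` (of features overlapped).
#' @examples
#' hirs <- GenomicRanges::GRanges("chr1",
#'         IRanges::IRanges(start = 1, width = 24000))
#' feats <- GenomicRanges::GRanges("chr1",
#'         IRanges::IRanges(start = seq(1, 3e6, length.out = 1000), width = 1))
#' overlapCount(hirs, feats, genomeSize = 3e6)
#' @export
overlapCount <- function(hirs, features, chromLengths = NULL,
                         genomeSize = NULL) {
  if (is.null(genomeSize)) {
    if (is.null(chromLengths))
      stop("either 'chromLengths' or 'genomeSize' is required")
    genomeSize <- sum(as.numeric(chromLengths))
  }
  if (genomeSize <= 0)
    stop("genome size must be positive")
  nf <- length(features)
  observed <- sum(GenomicRanges::countOverlaps(features, hirs) > 0)
  cov <- sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(hirs))))
  expected <- nf * cov / genomeSize
  data.frame(nFeatures = nf, observed = observed, expected = expected,
             fold = if (expected > 0) observed / expected else NA_real_,
             fraction = if (nf > 0) observed / nf else NA_real_)
}

#' Position of HIRs relative to TADs
#'
#' A HIR overlapping a TAD start or stop coordinate is at a TAD `border`;
#' a HIR falling entirely within a TAD is `inside`; anything else is
#' `outside`.  Coordinates follow the 0-based half-open convention: a
#' boundary at position `b` lies within a HIR covering `[start, end)` iff
#' `start <= b < end`.
#'
#' @param hirs HIR `GRanges`.
#' @param tads TAD `GRanges` (start/stop intervals).
#' @return character vector, one of `"border"`, `"inside"`, `"outside"`
#'   per HIR.
#' @export
tadPosition <- function(hirs, tads) {
  if (!length(hirs))
    return(character(0))
  # TAD boundaries as 1-bp points: the bases at 0-based positions
  # start-1 (i.e. GRanges start) and end.
  bpts <- c(
    GenomicRanges::GRanges(GenomicRanges::seqnames(tads),
      IRanges::IRanges(start = GenomicRanges::start(tads), width = 1)),
    GenomicRanges::GRanges(GenomicRanges::seqnames(tads),
      IRanges::IRanges(start = GenomicRanges::end(tads) + 1, width = 1)))
  atBorder <- GenomicRanges::countOverlaps(hirs, bpts,
                                           ignore.strand = TRUE) > 0
  within <- GenomicRanges::countOverlaps(hirs, tads, type = "within",
                                         ignore.strand = TRUE) > 0
  ifelse(atBorder, "border", ifelse(within, "inside", "outside"))
}

#' Gene expression summary over HIRs
#'
#' Genes are assigned to a HIR by at least 1 bp of overlap.  Reports the
#' per-HIR mean expression, gene count and mean gene length, optionally
#' aggregated per HIR class, together with the genome-wide baselines (the
#' means over all genes in the table).
#'
#' @param hirs HIR `GRanges`.
#' @param genes `GRanges` with a numeric `rpkm` metadata column.
#' @param classes optional per-HIR class labels (as from [classifyHIRs()]).
#' @return list with `perHIR` (data.frame: `hir`, `nGenes`, `meanRPKM`,
#'   `meanGeneLength`), `perClass` (or `NULL`) and `baseline` (list with
#'   `meanRPKM`, `meanGeneLength`, `nGenes`).
#' @export
expressionSummary <- function(hirs, genes, classes = NULL) {
  rpkm <- S4Vectors::mcols(genes)$rpkm
  if (is.null(rpkm))
    stop("'genes' must carry an 'rpkm' metadata column")
  glen <- GenomicRanges::width(genes)
  hits <- GenomicRanges::findOverlaps(genes, hirs, ignore.strand = TRUE)
  gi <- S4Vectors::queryHits(hits)
  hi <- S4Vectors::subjectHits(hits)
  perHIR <- data.frame(
    hir = S4Vectors::mcols(hirs)$name,
    nGenes = 0L, meanRPKM = NA_real_, meanGeneLength = NA_real_,
    stringsAsFactors = FALSE)
  if (length(hits)) {
    cnt <- table(factor(hi, levels = seq_along(hirs)))
    perHIR$nGenes <- as.integer(cnt)
    mr <- tapply(rpkm[gi], factor(hi, levels = seq_along(hirs)), mean)
    ml <- tapply(glen[gi], factor(hi, levels = seq_along(hirs)), mean)
    perHIR$meanRPKM <- as.numeric(mr)
    perHIR$meanGeneLength <- as.numeric(ml)
  }
  perClass <- NULL
  if (!is.null(classes)) {
    stopifnot(length(classes) == length(hirs))
    cls <- classes[hi]
    perClass <- data.frame(
      class = sort(unique(classes)),
      nGenes = as.integer(table(factor(cls, levels = sort(unique(classes))))),
      meanRPKM = as.numeric(tapply(rpkm[gi],
                 factor(cls, levels = sort(unique(classes))), mean)),
      meanGeneLength = as.numeric(tapply(glen[gi],
                 factor(cls, levels = sort(unique(classes))), mean)))
  }
  list(perHIR = perHIR, perClass = perClass,
       baseline = list(meanRPKM = mean(rpkm), meanGeneLength = mean(glen),
                       nGenes = length(genes)))
}

#' Contact distributions between HIR classes
#'
#' From an observed/expected map, extracts the contact values for all
#' same-chromosome bin pairs with one bin in class A and the other in
#' class B (self-pairs excluded), for every ordered class pair, and for
#' each class against `nRandom` randomly selected unmasked loci that do
#' not overlap that class.  Values above one indicate more frequent
#' contact than expected at that distance.
#'
#' @param oe a [NormalizedMap-class] of kind `"oe_divide"` at the HIR bin
#'   size.
#' @param hirs HIR `GRanges` on the same chromosome as `oe`.
#' @param classes per-HIR integer class labels.
#' @param nRandom number of random background loci per class, default
#'   10000 (drawn with replacement if fewer eligible bins exist).
#' @param seed RNG seed for the background draw.
#' @return list with `distributions` (named list of numeric vectors,
#'   names `"A_vs_B"` and `"A_vs_random"`) and `summary` (data.frame with
#'   `pair`, `n`, `q25`, `median`, `q75`).
#' @export
classContacts <- function(oe, hirs, classes, nRandom = 10000, seed = NULL) {
  stopifnot(is(oe, "NormalizedMap"))
  if (oe@kind != "oe_divide")
    stop("class contacts require an observed/expected (oe_divide) map")
  stopifnot(length(classes) == length(hirs))
  if (!is.null(seed))
    set.seed(seed)
  v <- as.matrix(oe)
  n <- nrow(v)
  sameChrom <- as.character(GenomicRanges::seqnames(hirs)) == chrom(oe)
  binsOf <- lapply(sort(unique(classes)), function(cl) {
    sel <- classes == cl & sameChrom
    if (!any(sel)) integer(0)
    else .regionBins(hirs[sel], binSize(oe), n)
  })
  names(binsOf) <- as.character(sort(unique(classes)))
  unmasked <- setdiff(seq_len(n), maskedBins(oe))
  dists <- list()
  rows <- list()
  grab <- function(ia, ib) {
    pair <- expand.grid(i = ia, j = ib)
    pair <- pair[pair$i != pair$j, , drop = FALSE]
    x <- v[cbind(pair$i, pair$j)]
    x[!is.na(x)]
  }
  for (a in names(binsOf)) {
    ia <- binsOf[[a]]
    if (!length(ia)) {
      warning("class ", a, " has no bins on ", chrom(oe), "; skipped")
      next
    }
    for (b in names(binsOf)) {
      ib <- binsOf[[b]]
      if (!length(ib)) next
      key <- paste0(a, "_vs_", b)
      dists[[key]] <- grab(ia, ib)
    }
    pool <- setdiff(unmasked, ia)
    draw <- sample(pool, nRandom, replace = nRandom > length(pool))
    key <- paste0(a, "_vs_random")
    dists[[key]] <- grab(ia, draw)
  }
  summ <- do.call(rbind, lapply(names(dists), function(k) {
    x <- dists[[k]]
    qs <- if (length(x)) stats::quantile(x, c(.25, .5, .75), names = FALSE)
          else rep(NA_real_, 3)
    data.frame(pair = k, n = length(x), q25 = qs[1], median = qs[2],
               q75 = qs[3], stringsAsFactors = FALSE)
  }))
  list(distributions = dists, summary = summ)
}
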