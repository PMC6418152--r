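#' Percentile threshold of a stationary profile
#'
#' Linear-interpolation quantile (the standard type-7 definition, index
#' `h = q/100 * (m - 1)` into the sorted vector) of the unmasked profile
#' values of one chromosome.
#'
#' @param p a [StationaryProfile-class] (or any numeric vector; `NA`s are
#'   treated as masked bins).
#' @param q percentile in `[0, 100]`.
#' @return the threshold value.
#' @export
percentileThreshold <- function(p, q) {
  x <- if (is(p, "StationaryProfile")) binValues(p) else as.numeric(p)
  x <- x[!is.na(x)]
  if (!length(x))
    stop("all bins are masked: percentile threshold undefined")
  stopifnot(q >= 0, q <= 100)
  stats::quantile(x, q / 100, type = 7, names = FALSE)
}

.runsToGRanges <- function(sel, p, binSize, chromName, tier, minBins) {
  sel[is.na(sel)] <- FALSE
  r <- rle(sel)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- r$values & r$lengths >= minBins
  starts <- starts[ok]
  ends <- ends[ok]
  n <- length(p)
  sq <- GenomeInfoDb::Seqinfo(seqnames = chromName,
                              seqlengths = as.integer(n * binSize))
  gr <- GenomicRanges::GRanges(
    seqnames = if (length(starts)) chromName else character(0),
    ranges = IRanges::IRanges(start = (starts - 1) * binSize + 1,
                              end = ends * binSize),
    seqinfo = sq)
  S4Vectors::mcols(gr)$name <- if (length(starts))
    sprintf("%s_%s_%03d", toupper(sub("^sd", "SD", tier)), chromName,
            seq_along(starts)) else character(0)
  S4Vectors::mcols(gr)$meanStat <- vapply(seq_along(starts), function(k)
    mean(p[starts[k]:ends[k]]), numeric(1))
  S4Vectors::mcols(gr)$nBins <- ends - starts + 1L
  S4Vectors::mcols(gr)$tier <- rep(tier, length(starts))
  S4Vectors::metadata(gr)$binSize <- binSize
  gr
}

#' Call Highly Interacting Regions (HIRs)
#'
#' HIRs are maximal runs of at least `minBins` consecutive bins whose
#' stationary-distribution value strictly exceeds the chromosome's `q`-th
#' percentile (computed over unmasked bins).  A masked bin terminates a
#' run: no evidence of interactivity is assumed across unmappable gaps.
#'
#' With the defaults (`q = 90`, `minBins = 5`) and a 5 kb profile this is
#' a run of five or more consecutive 5 kb bins above the per-chromosome
#' 90th percentile.
#'
#' @param p a [StationaryProfile-class].
#' @param q percentile threshold, default 90.
#' @param minBins minimum run length in bins, default 5.
#' @return a `GRanges` with metadata columns `name`, `meanStat` (mean
#'   stationary value of the region), `nBins` and `tier` (`"hir_top10"`
#'   for the default call).  May be empty.
#' @seealso [tierRegions()], [makeFlanks()], [writeRegionsBed()]
#' @export
callHIRs <- function(p, q = 90, minBins = 5) {
  stopifnot(is(p, "StationaryProfile"))
  v <- binValues(p)
  thr <- percentileThreshold(p, q)
  tier <- if (q == 90) "hir_top10" else sprintf("hir_top%g", 100 - q)
  .runsToGRanges(v > thr, v, binSize(p), chrom(p), tier, minBins)
}

#' Call percentile-band region tiers
#'
#' Applies the same run rule as [callHIRs()] to bins whose value lies in
#' the percentile band `(threshold(loPct), threshold(hiPct)]`; `loPct = 0`
#' includes the minimum.  Used for intermediate-interactivity control
#' tiers (e.g. bands 0-30, 30-50 and 50-80).
#'
#' @param p a [StationaryProfile-class].
#' @param loPct,hiPct band limits as percentiles, `0 <= lo < hi <= 100`.
#' @param minBins minimum run length in bins.
#' @return a `GRanges` as in [callHIRs()], `tier` set to `"sd_<lo>_<hi>"`.
#' @export
tierRegions <- function(p, loPct, hiPct, minBins = 5) {
  stopifnot(is(p, "StationaryProfile"), loPct >= 0, hiPct <= 100,
            loPct < hiPct)
  v <- binValues(p)
  hi <- percentileThreshold(p, hiPct)
  sel <- if (loPct == 0) v <= hi else {
    lo <- percentileThreshold(p, loPct)
    v > lo & v <= hi
  }
  .runsToGRanges(sel, v, binSize(p), chrom(p),
                 sprintf("sd_%g_%g", loPct, hiPct), minBins)
}

#' Flanking control regions for HIRs
#'
#' For every HIR of length `L` two flank pairs are produced:
#' * `F1`: the two immediately adjacent intervals of length `L`;
#' * `F2`: two intervals of length `L` whose proximal edges sit
#'   `offset` bp away from the HIR edges (default 100 kb).
#'
#' Flanks are clipped to chromosome bounds and flagged if clipped or if
#' they overlap another HIR; with `offset = 0`, `F2` coincides with `F1`.
#'
#' @param hirs a `GRanges` from [callHIRs()].
#' @param offset F2 offset in bp, default `1e5`.
#' @param chromLengths named vector of chromosome lengths; defaults to
#'   `seqlengths(hirs)`.
#' @return a `GRanges` with metadata columns `hir` (parent HIR name),
#'   `flank` (`"F1"`/`"F2"`), `side` (`"left"`/`"right"`), `clipped` and
#'   `overlapsHIR`.  Flanks falling entirely outside the chromosome are
#'   dropped.
#' @export
makeFlanks <- function(hirs, offset = 1e5, chromLengths = NULL) {
  if (is.null(chromLengths))
    chromLengths <- GenomeInfoDb::seqlengths(hirs)
  if (anyNA(chromLengths))
    stop("chromosome lengths are required to clip flanks")
  L <- GenomicRanges::width(hirs)
  s <- GenomicRanges::start(hirs)
  e <- GenomicRanges::end(hirs)
  chr <- as.character(GenomicRanges::seqnames(hirs))
  nm <- S4Vectors::mcols(hirs)$name
  piece <- function(start, end, flank, side) {
    data.frame(chr = chr, start = start, end = end, hir = nm,
               flank = flank, side = side)
  }
  df <- rbind(
    piece(s - L, s - 1, "F1", "left"),
    piece(e + 1, e + L, "F1", "right"),
    piece(s - offset - L, s - offset - 1, "F2", "left"),
    piece(e + offset + 1, e + offset + L, "F2", "right"))
  clen <- unname(chromLengths[df$chr])
  cs <- pmax(df$start, 1)
  ce <- pmin(df$end, clen)
  clipped <- cs != df$start | ce != df$end
  keep <- cs <= ce
  df <- df[keep, , drop = FALSE]
  cs <- cs[keep]
  ce <- ce[keep]
  clipped <- clipped[keep]
  gr <- GenomicRanges::GRanges(
    seqnames = df$chr,
    ranges = IRanges::IRanges(start = cs, end = ce),
    seqinfo = GenomeInfoDb::Seqinfo(seqnames = names(chromLengths),
                                    seqlengths = chromLengths))
  S4Vectors::mcols(gr)$hir <- df$hir
  S4Vectors::mcols(gr)$flank <- df$flank
  S4Vectors::mcols(gr)$side <- df$side
  S4Vectors::mcols(gr)$clipped <- clipped
  S4Vectors::mcols(gr)$overlapsHIR <-
    GenomicRanges::countOverlaps(gr, hirs) > 0
  S4Vectors::metadata(gr)$binSize <- S4Vectors::metadata(hirs)$binSize
  S4Vectors::metadata(gr)$offset <- offset
  gr
}

#' Write a region set as BED6
#'
#' The score column is the region's mean stationary value scaled by `1e6`
#' (BED scores are integers in practice; stationary probabilities are of
#' order `1/nBins`).
#'
#' @param regions a `GRanges` from [callHIRs()] or [makeFlanks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRegionsBed <- function(regions, path) {
  gr <- regions
  ms <- S4Vectors::mcols(gr)$meanStat
  S4Vectors::mcols(gr)$score <-
    if (is.null(ms)) 0 else round(ms * 1e6, 3)
  if (is.null(S4Vectors::mcols(gr)$name))
    S4Vectors::mcols(gr)$name <-
      paste0(S4Vectors::mcols(gr)$hir, "_", S4Vectors::mcols(gr)$flank,
             "_", S4Vectors::mcols(gr)$side)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
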