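#' Construct a SignalTrack
#'
#' @param values per-bin numeric signal, `NA` where missing.
#' @param name dataset name.
#' @param chrom chromosome name.
#' @param binSize bin width in bp.
#' @param normalized whether `values` are already on the 0-100 percentile
#'   scale.
#' @return a [SignalTrack-class].
#' @export
SignalTrack <- function(values, name = "track", chrom = "chr1",
                        binSize = 5000, normalized = FALSE) {
  new("SignalTrack", name = as.character(name), chrom = as.character(chrom),
      binSize = as.numeric(binSize), values = as.numeric(values),
      normalized = isTRUE(normalized))
}

#' Read a binned signal track from a bedGraph file
#'
#' Records are averaged onto the requested fixed bins, weighting by the
#' number of bases each record contributes to a bin; bins with no coverage
#' are missing.
#'
#' @param path bedGraph file path.
#' @param chrom chromosome to extract.
#' @param binSize target bin width in bp.
#' @param nBins number of bins.
#' @param name dataset name; defaults to the file name.
#' @return a [SignalTrack-class].
#' @export
readBedGraphTrack <- function(path, chrom, binSize, nBins,
                              name = basename(path)) {
  if (!file.exists(path))
    stop("bedGraph file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) == chrom]
  bins <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = (seq_len(nBins) - 1) * binSize + 1,
                              width = binSize))
  hits <- GenomicRanges::findOverlaps(bins, gr)
  vals <- rep(NA_real_, nBins)
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(bins[S4Vectors::queryHits(hits)],
                                    gr[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    sc <- S4Vectors::mcols(gr)$score[S4Vectors::subjectHits(hits)]
    num <- tapply(w * sc, S4Vectors::queryHits(hits), sum)
    den <- tapply(w, S4Vectors::queryHits(hits), sum)
    vals[as.integer(names(num))] <- as.numeric(num) / as.numeric(den)
  }
  SignalTrack(vals, name = name, chrom = chrom, binSize = binSize)
}

#' Write a signal track as bedGraph
#'
#' @param track a [SignalTrack-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeBedGraphTrack <- function(track, path) {
  .exportBedGraph(binValues(track), chrom(track), binSize(track), path)
}

#' Downsample a signal track to a coarser bin size
#'
#' Each coarse bin is the mean of its constituent fine bins, ignoring
#' missing values; a coarse bin is missing iff all its constituents are.
#'
#' @param track a [SignalTrack-class].
#' @param targetBin target bin width, an integer multiple of the track's
#'   bin size.
#' @return a [SignalTrack-class] at the coarser resolution.
#' @export
downsampleTrack <- function(track, targetBin) {
  f <- targetBin / binSize(track)
  if (f != round(f) || f < 1)
    stop("target bin size must be an integer multiple of the track bin size")
  f <- as.integer(f)
  v <- binValues(track)
  out <- .blockMeans(v, f)
  SignalTrack(out, name = track@name, chrom = chrom(track),
              binSize = targetBin, normalized = track@normalized)
}

.blockMeans <- function(v, f) {
  if (f == 1L) return(v)
  n <- length(v)
  ng <- ceiling(n / f)
  length(v) <- ng * f  # pads with NA
  m <- matrix(v, nrow = f)
  out <- colMeans(m, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  out
}

#' Percentile-normalize a signal track
#'
#' Brings heterogeneous signal tracks onto a common 0-100 enrichment
#' scale.  All values below the genomic average (the mean of non-missing
#' values) are first set to that average, so sub-background signal is
#' indistinguishable from background.  Each remaining value is then
#' replaced by its percentile among the above-average values (max-rank
#' convention for ties, scaled so the genomic maximum maps exactly to
#' 100).  After normalization, 0 means enrichment at or below the genomic
#' average and 100 the maximum enrichment observed.
#'
#' @param track a [SignalTrack-class] with at least one non-missing value.
#' @return the normalized [SignalTrack-class] (`normalized = TRUE`).
#' @examples
#' binValues(normalizeTrack(SignalTrack(0:9)))
#' # 0 0 0 0 0 20 40 60 80 100
#' @export
normalizeTrack <- function(track) {
  v <- binValues(track)
  if (all(is.na(v)))
    stop("cannot normalize a track with no data")
  mu <- mean(v, na.rm = TRUE)
  out <- v
  above <- !is.na(v) & v > mu
  out[!is.na(v) & v <= mu] <- 0
  if (any(above)) {
    r <- rank(v[above], ties.method = "max")
    out[above] <- 100 * r / sum(above)
  }
  SignalTrack(out, name = track@name, chrom = chrom(track),
              binSize = binSize(track), normalized = TRUE)
}

.regionBins <- function(regions, binSize, nBins) {
  # all bins overlapping any region by >= 1 bp, 1-based
  s <- GenomicRanges::start(regions)
  e <- GenomicRanges::end(regions)
  idx <- unlist(lapply(seq_along(s), function(k) {
    lo <- (s[k] - 1) %/% binSize + 1
    hi <- (e[k] - 1) %/% binSize + 1
    seq.int(max(1, lo), min(nBins, hi))
  }))
  sort(unique(idx))
}

#' Apply the dataset exclusion rules
#'
#' Tracks with more than 50% missing data genome-wide, or with mean
#' normalized enrichment over HIR bins below 2 (the second percentile of
#' the 0-100 scale, i.e. essentially background at HIRs), are excluded
#' from downstream enrichment analysis.
#'
#' @param tracks list of normalized [SignalTrack-class] objects.
#' @param hirs `GRanges` of HIRs from [callHIRs()].
#' @param missingMax maximum tolerated missing fraction, default 0.5.
#' @param minHIREnrichment minimum mean normalized enrichment at HIRs,
#'   default 2.
#' @return `list(kept = <tracks>, dropped = <data.frame name/reason>)`.
#' @export
excludeDatasets <- function(tracks, hirs, missingMax = 0.5,
                            minHIREnrichment = 2) {
  stopifnot(all(vapply(tracks, function(t) t@normalized, logical(1))))
  kept <- list()
  drops <- character(0)
  dropname <- character(0)
  for (tr in tracks) {
    v <- binValues(tr)
    hirBins <- .regionBins(hirs, binSize(tr), length(v))
    missFrac <- mean(is.na(v))
    meanHIR <- if (length(hirBins)) mean(v[hirBins], na.rm = TRUE) else NaN
    if (missFrac > missingMax) {
      drops <- c(drops, sprintf("missing>%d%%", round(100 * missingMax)))
      dropname <- c(dropname, tr@name)
    } else if (!is.finite(meanHIR) || meanHIR < minHIREnrichment) {
      drops <- c(drops, "low enrichment")
      dropname <- c(dropname, tr@name)
    } else {
      kept <- c(kept, tr)
    }
  }
  list(kept = kept,
       dropped = data.frame(name = dropname, reason = drops,
                            stringsAsFactors = FALSE))
}

.regionMeans <- function(track, regions) {
  v <- binValues(track)
  bs <- binSize(track)
  n <- length(v)
  vapply(seq_along(regions), function(k) {
    idx <- .regionBins(regions[k], bs, n)
    x <- v[idx]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
}

#' Enrichment of a track in HIRs versus their flanking regions
#'
#' Computes the mean normalized enrichment of the track over every HIR and
#' every flank region, then compares the per-region HIR means with the F1
#' and F2 flank means by two-sample t tests.  Both the Welch and the
#' pooled-variance (classical Student) statistics are reported.
#'
#' @param track a normalized [SignalTrack-class].
#' @param hirs HIR `GRanges`.
#' @param flanks flank `GRanges` from [makeFlanks()].
#' @return a list with `means` (data.frame of per-region means, with the
#'   region set in `set`) and `tests` (data.frame with columns
#'   `comparison`, `method`, `t`, `p`, `meanDiff`).  Test entries are `NA`
#'   when fewer than two regions are available on either side.
#' @export
regionEnrichment <- function(track, hirs, flanks) {
  stopifnot(track@normalized)
  sets <- list(
    HIR = hirs,
    F1 = flanks[S4Vectors::mcols(flanks)$flank == "F1"],
    F2 = flanks[S4Vectors::mcols(flanks)$flank == "F2"])
  means <- lapply(sets, function(rg) .regionMeans(track, rg))
  mdf <- data.frame(
    set = rep(names(sets), lengths(means)),
    mean = unlist(means, use.names = FALSE), stringsAsFactors = FALSE)
  tst <- do.call(rbind, lapply(c("F1", "F2"), function(fl) {
    a <- means$HIR[!is.na(means$HIR)]
    b <- means[[fl]][!is.na(means[[fl]])]
    do.call(rbind, lapply(c(welch = FALSE, pooled = TRUE), function(pool) {
      if (length(a) < 2 || length(b) < 2 ||
          (stats::var(a) == 0 && stats::var(b) == 0))
        return(data.frame(comparison = paste0("HIR_vs_", fl),
                          method = if (pool) "pooled" else "welch",
                          t = NA_real_, p = NA_real_,
                          meanDiff = mean(a) - mean(b)))
      tt <- stats::t.test(a, b, var.equal = pool)
      data.frame(comparison = paste0("HIR_vs_", fl),
                 method = if (pool) "pooled" else "welch",
                 t = unname(tt$statistic), p = tt$p.value,
                 meanDiff = mean(a) - mean(b))
    }))
  }))
  tst$method <- ifelse(tst$method == "pooled", "pooled", "welch")
  rownames(tst) <- NULL
  list(means = mdf, tests = tst)
}

#' Spearman correlation between a track and the interactivity profile
#'
#' Both inputs are averaged into non-overlapping windows of `window` bp
#' (ignoring missing bins) and the Spearman rank correlation is computed
#' over windows where both are non-missing, with average ranks for ties.
#' Several chromosomes may be supplied as parallel lists of tracks and
#' profiles; windows are pooled across them.
#'
#' @param track a [SignalTrack-class], or list of them (one per
#'   chromosome).
#' @param p a [StationaryProfile-class], or matching list.
#' @param window window size in bp, default 1e5.
#' @param chroms optional chromosome subset applied when lists are given.
#' @return `list(rho, p.value, n)`; errors if fewer than 3 paired windows.
#' @export
spearmanVsProfile <- function(track, p, window = 1e5, chroms = NULL) {
  if (is(track, "SignalTrack")) track <- list(track)
  if (is(p, "StationaryProfile")) p <- list(p)
  stopifnot(length(track) == length(p))
  if (!is.null(chroms)) {
    keep <- vapply(track, chrom, character(1)) %in% chroms
    track <- track[keep]
    p <- p[keep]
  }
  xs <- ys <- numeric(0)
  for (k in seq_along(track)) {
    stopifnot(chrom(track[[k]]) == chrom(p[[k]]))
    fx <- window / binSize(track[[k]])
    fy <- window / binSize(p[[k]])
    if (fx != round(fx) || fy != round(fy))
      stop("window must be an integer multiple of both bin sizes")
    xs <- c(xs, .blockMeans(binValues(track[[k]]), as.integer(fx)))
    ys <- c(ys, .blockMeans(binValues(p[[k]]), as.integer(fy)))
  }
  ok <- !is.na(xs) & !is.na(ys)
  if (sum(ok) < 3)
    stop("fewer than 3 paired windows: correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(xs[ok], ys[ok], method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = sum(ok))
}
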