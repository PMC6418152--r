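#' Construct a ContactMap
#'
#' @param values square numeric matrix of contact frequencies. Must be
#'   symmetric, finite and non-negative.
#' @param chrom chromosome name.
#' @param binSize bin width in base pairs.
#' @param mask integer vector of 1-based bin indices to exclude.
#' @return a [ContactMap-class].
#' @examples
#' m <- ContactMap(matrix(c(0, 2, 2, 0), 2), chrom = "chrT", binSize = 5000)
#' nBins(m)
#' @export
ContactMap <- function(values, chrom = "chr1", binSize = 5000,
                       mask = integer(0)) {
  storage.mode(values) <- "double"
  new("ContactMap", chrom = as.character(chrom), binSize = as.numeric(binSize),
      values = unname(values), mask = sort(unique(as.integer(mask))))
}

#' Read a contact map from disk
#'
#' Reads a per-chromosome intra-chromosomal contact matrix in either sparse
#' COO format (three tab-separated columns `i j value` with 0-based bin
#' indices) or dense whitespace-delimited matrix format.
#'
#' COO input is symmetrized by mirroring: an entry may be given for either
#' `(i, j)` or `(j, i)`; if both are present their values must agree.
#' Bins never observed are retained as all-zero rows.  Dense input must be
#' symmetric already.
#'
#' @param path path to the matrix file.
#' @param format `"coo"` or `"dense"`.
#' @param chrom,binSize chromosome name and bin width (bp) of the map.
#' @param nBins bin count; for COO input, defaults to the largest index
#'   seen plus one.  Required for an empty COO file.
#' @param mask optional integer vector of 1-based masked bin indices.
#' @return a [ContactMap-class].
#' @seealso [writeContactMap()], [maskZeroRows()]
#' @export
readContactMap <- function(path, format = c("coo", "dense"), chrom = "chr1",
                           binSize = 5000, nBins = NULL, mask = integer(0)) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("contact map file not found: ", path)
  if (format == "dense") {
    v <- as.matrix(utils::read.table(path, header = FALSE))
    if (nrow(v) != ncol(v))
      stop("dense contact matrix must be square")
    if (anyNA(v) || any(!is.finite(v)))
      stop("contact values must be finite and non-missing")
    if (!isTRUE(all.equal(unname(v), unname(t(v)), check.attributes = FALSE)))
      stop("dense contact matrix is asymmetric")
    if (!is.null(nBins) && nrow(v) != nBins)
      stop("dense matrix has ", nrow(v), " bins, expected ", nBins)
    return(ContactMap(v, chrom = chrom, binSize = binSize, mask = mask))
  }
  co <- tryCatch(
    utils::read.table(path, header = FALSE,
                      colClasses = c("integer", "integer", "numeric")),
    error = function(e) {
      if (file.size(path) == 0) NULL else stop(e)
    })
  if (is.null(co) || nrow(co) == 0) {
    if (is.null(nBins))
      stop("empty COO file: 'nBins' must be given")
    return(ContactMap(matrix(0, nBins, nBins), chrom = chrom,
                      binSize = binSize, mask = mask))
  }
  names(co) <- c("i", "j", "value")
  if (anyNA(co$i) || anyNA(co$j))
    stop("COO bin indices must not be missing")
  if (any(!is.finite(co$value)))
    stop("COO contact values must be finite")
  if (any(co$value < 0))
    stop("COO contact values must be non-negative")
  if (any(co$i < 0) || any(co$j < 0))
    stop("COO bin indices must be non-negative")
  if (is.null(nBins))
    nBins <- max(co$i, co$j) + 1L
  if (any(co$i >= nBins) || any(co$j >= nBins))
    stop("COO bin index out of range: indices must be < nBins (", nBins, ")")
  v <- matrix(0, nBins, nBins)
  key <- paste(pmin(co$i, co$j), pmax(co$i, co$j))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    agree <- tapply(co$value, key, function(x) length(unique(x)) == 1L)
    if (!all(agree))
      stop("conflicting COO entries: (i,j) and (j,i) differ for ",
           sum(!agree), " pair(s)")
  }
  v[cbind(co$i + 1L, co$j + 1L)] <- co$value
  v[cbind(co$j + 1L, co$i + 1L)] <- co$value
  ContactMap(v, chrom = chrom, binSize = binSize, mask = mask)
}

#' Write a contact map or normalized map to disk
#'
#' COO output lists the upper triangle (including the diagonal) of all
#' non-zero, non-missing entries with 0-based bin indices; dense output is
#' the full whitespace-delimited matrix.  Values are written with 17
#' significant digits so that a write/read round trip is exact for exactly
#' representable values.
#'
#' @param x a [ContactMap-class] or [NormalizedMap-class].
#' @param path output file path.
#' @param format `"coo"` or `"dense"`.
#' @return `path`, invisibly.
#' @export
writeContactMap <- function(x, path, format = c("coo", "dense")) {
  format <- match.arg(format)
  v <- as.matrix(x)
  if (format == "dense") {
    lines <- apply(v, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = "\t"))
    writeLines(lines, path)
  } else {
    idx <- which(upper.tri(v, diag = TRUE) & !is.na(v) & v != 0,
                 arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    lines <- sprintf("%d\t%d\t%.17g", idx[, 1] - 1L, idx[, 2] - 1L,
                     v[idx])
    writeLines(lines, path)
  }
  invisible(path)
}

#' Add all-zero rows to the mask of a contact map
#'
#' Bins with no observed contacts at all are typically unmappable; leaving
#' them unmasked would bias the per-distance medians toward zero.
#'
#' @param map a [ContactMap-class].
#' @return the map with all-zero bins appended to its mask.
#' @export
maskZeroRows <- function(map) {
  z <- which(rowSums(as.matrix(map)) == 0)
  ContactMap(as.matrix(map), chrom = chrom(map), binSize = binSize(map),
             mask = union(maskedBins(map), z))
}

#' Distance-decay expectation of a contact map
#'
#' Hi-C contact frequency decays with genomic distance, so the expected
#' contact frequency at bin distance `d` is taken as the median over all
#' unmasked entries `values[i, i + d]`.  Masked bins are excluded from the
#' medians; a distance at which every pair touches a masked bin gets `NA`.
#' The even-count median is the midpoint of the two central order
#' statistics.
#'
#' @param map a [ContactMap-class].
#' @return an [ExpectedProfile-class] with one median per bin distance
#'   `0 .. nBins(map) - 1`.
#' @examples
#' v <- rbind(c(10, 5, 2, 1), c(5, 12, 6, 2), c(2, 6, 11, 4), c(1, 2, 4, 9))
#' binValues(expectedProfile(ContactMap(v)))  # 10.5 5 2 1
#' @export
expectedProfile <- function(map) {
  v <- as.matrix(map)
  n <- nrow(v)
  ok <- !(seq_len(n) %in% maskedBins(map))
  med <- vapply(0:(n - 1L), function(d) {
    i <- seq_len(n - d)
    use <- ok[i] & ok[i + d]
    if (!any(use)) return(NA_real_)
    stats::median(v[cbind(i[use], i[use] + d)])
  }, numeric(1))
  new("ExpectedProfile", binSize = binSize(map), med = med)
}

#' Distance-normalize a contact map
#'
#' Produces the `observed - expected` (`kind = "oe_subtract"`) or
#' `observed / expected` (`kind = "oe_divide"`) map, where the expectation
#' is the per-distance median of [expectedProfile()].  Subtraction yields a
#' map that may be negative; division yields a non-negative map with `NA`
#' wherever the expected value is zero.  Rows/columns of masked bins are
#' set to `NA`.
#'
#' @param map a [ContactMap-class].
#' @param expected an [ExpectedProfile-class] computed from a map of the
#'   same geometry; defaults to `expectedProfile(map)`.
#' @param kind `"oe_subtract"` (default) or `"oe_divide"`.
#' @return a [NormalizedMap-class].
#' @export
normalizeMap <- function(map, expected = expectedProfile(map),
                         kind = c("oe_subtract", "oe_divide")) {
  kind <- match.arg(kind)
  v <- as.matrix(map)
  n <- nrow(v)
  med <- binValues(expected)
  if (length(med) != n)
    stop("expected profile covers ", length(med), " distances but the map has ",
         n, " bins")
  if (binSize(expected) != binSize(map))
    stop("bin size mismatch between map and expected profile")
  dmat <- abs(outer(seq_len(n), seq_len(n), "-")) + 1L
  e <- matrix(med[dmat], n, n)
  if (kind == "oe_subtract") {
    out <- v - e
  } else {
    out <- v / e
    out[!is.na(e) & e == 0] <- NA_real_
  }
  msk <- maskedBins(map)
  out[msk, ] <- NA_real_
  out[, msk] <- NA_real_
  new("NormalizedMap", chrom = chrom(map), binSize = binSize(map),
      values = out, mask = msk, kind = kind)
}
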