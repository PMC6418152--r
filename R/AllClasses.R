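
#' ContactMap: a symmetric intra-chromosomal Hi-C contact matrix
#'
#' A `ContactMap` holds the contact frequencies between all pairs of
#' fixed-size genomic bins of one chromosome, together with a set of
#' masked (excluded) bins.  Bin `i` (1-based in R) covers the half-open
#' genomic interval `[(i-1)*binSize, i*binSize)` in 0-based coordinates.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width in base pairs.
#' @slot values symmetric, non-negative, finite `nBins x nBins` matrix.
#' @slot mask integer vector of 1-based bin indices excluded from analysis
#'   (unmappable or otherwise unusable bins).
#'
#' @seealso [readContactMap()], [expectedProfile()], [normalizeMap()]
#' @export
setClass("ContactMap",
  representation(
    chrom = "character",
    binSize = "numeric",
    values = "matrix",
    mask = "integer"
  )
)

.validBinnedGeometry <- function(object) {
  msg <- character(0)
  if (length(object@chrom) != 1L || is.na(object@chrom))
    msg <- c(msg, "'chrom' must be a single chromosome name")
  if (length(object@binSize) != 1L || is.na(object@binSize) ||
      object@binSize <= 0)
    msg <- c(msg, "'binSize' must be a single positive number")
  v <- object@values
  if (!is.numeric(v) || nrow(v) != ncol(v))
    msg <- c(msg, "'values' must be a square numeric matrix")
  n <- nrow(v)
  if (length(object@mask) &&
      (anyNA(object@mask) || any(object@mask < 1L) || any(object@mask > n)))
    msg <- c(msg, "'mask' indices must lie in 1..nBins")
  msg
}

setValidity("ContactMap", function(object) {
  msg <- .validBinnedGeometry(object)
  v <- object@values
  if (anyNA(v) || any(!is.finite(v)))
    msg <- c(msg, "contact values must be finite and non-missing")
  else {
    if (any(v < 0))
      msg <- c(msg, "contact values must be non-negative")
    if (!isTRUE(all.equal(v, t(v), check.attributes = FALSE)))
      msg <- c(msg, "contact matrix must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' ExpectedProfile: distance-decay expectation of a contact map
#'
#' Stores, for every bin distance `d = 0 .. nBins-1`, the median contact
#' frequency observed at that distance over unmasked bin pairs.  Entries are
#' `NA` for distances at which every pair involves a masked bin.
#'
#' @slot binSize bin width in base pairs.
#' @slot med numeric vector of per-distance median contact frequencies,
#'   `med[d + 1]` giving the value at bin distance `d`.
#' @export
setClass("ExpectedProfile",
  representation(binSize = "numeric", med = "numeric")
)

setValidity("ExpectedProfile", function(object) {
  if (any(object@med < 0, na.rm = TRUE))
    "expected contact frequencies must be non-negative"
  else TRUE
})

#' NormalizedMap: observed-expected or observed/expected contact map
#'
#' The distance-decay corrected form of a [ContactMap-class]: either the
#' per-distance median is subtracted from every entry (`"oe_subtract"`,
#' values may be negative) or every entry is divided by it (`"oe_divide"`,
#' values are non-negative, `NA` where the expected value is zero).  Rows
#' and columns of masked bins are `NA`.
#'
#' @slot chrom,binSize,values,mask as in [ContactMap-class]; `values` may
#'   contain negative entries (`oe_subtract`) or `NA` (masked bins, or zero
#'   expected under `oe_divide`).
#' @slot kind `"oe_subtract"` or `"oe_divide"`.
#' @export
setClass("NormalizedMap",
  representation(
    chrom = "character",
    binSize = "numeric",
    values = "matrix",
    mask = "integer",
    kind = "character"
  )
)

setValidity("NormalizedMap", function(object) {
  msg <- .validBinnedGeometry(object)
  if (!object@kind %in% c("oe_subtract", "oe_divide"))
    msg <- c(msg, "'kind' must be \"oe_subtract\" or \"oe_divide\"")
  v <- object@values
  if (!isTRUE(all.equal(v, t(v), check.attributes = FALSE)) ||
      !identical(is.na(v), is.na(t(v))))
    msg <- c(msg, "normalized matrix must be symmetric (including NA pattern)")
  if (identical(object@kind, "oe_divide") && any(v < 0, na.rm = TRUE))
    msg <- c(msg, "observed/expected values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' TransitionMatrix: row-stochastic random-walk matrix on the contact network
#'
#' Built from a clamped `oe_subtract` (or `oe_divide`) map by dividing every
#' row by its sum.  Bins whose row sums to zero after clamping negative
#' entries to zero are added to the mask; the matrix `W` is defined over the
#' surviving ("kept") bins only.
#'
#' @slot chrom,binSize chromosome and bin width.
#' @slot nBins total number of bins of the originating map.
#' @slot keep integer indices (1-based, into the full bin range) of the bins
#'   carried by `W`, in increasing order.
#' @slot W row-stochastic matrix over the kept bins; rows sum to 1 within
#'   1e-9.
#' @slot rowWeights row sums of the clamped symmetric weight matrix over the
#'   kept bins; for symmetric weights the stationary distribution is
#'   proportional to these.
#' @slot components integer connected-component label per kept bin, computed
#'   on the clamped weight graph.
#' @export
setClass("TransitionMatrix",
  representation(
    chrom = "character",
    binSize = "numeric",
    nBins = "integer",
    keep = "integer",
    W = "matrix",
    rowWeights = "numeric",
    components = "integer"
  )
)

setValidity("TransitionMatrix", function(object) {
  msg <- character(0)
  k <- length(object@keep)
  if (nrow(object@W) != k || ncol(object@W) != k)
    msg <- c(msg, "'W' must be square over the kept bins")
  if (k) {
    if (any(object@W < 0))
      msg <- c(msg, "transition probabilities must be non-negative")
    if (any(abs(rowSums(object@W) - 1) > 1e-9))
      msg <- c(msg, "every row of W must sum to 1 within 1e-9")
  }
  if (length(object@rowWeights) != k || length(object@components) != k)
    msg <- c(msg, "'rowWeights' and 'components' must match the kept bins")
  if (length(msg)) msg else TRUE
})

#' StationaryProfile: per-bin interactivity track
#'
#' The stationary probability distribution of the random walk encoded by a
#' [TransitionMatrix-class]: a per-bin probability interpreted as the
#' interactivity (relative number of excess contacts) of that bin.  Masked
#' bins carry `NA`; non-missing values are non-negative and sum to 1.
#'
#' @slot chrom,binSize chromosome and bin width.
#' @slot p per-bin probability vector with `NA` at masked bins.
#' @slot method how it was computed: `"eig"`, `"rowsum"` or `"power"`.
#' @export
setClass("StationaryProfile",
  representation(
    chrom = "character",
    binSize = "numeric",
    p = "numeric",
    method = "character"
  )
)

setValidity("StationaryProfile", function(object) {
  msg <- character(0)
  p <- object@p
  if (any(p < 0, na.rm = TRUE))
    msg <- c(msg, "stationary probabilities must be non-negative")
  if (sum(!is.na(p)) && abs(sum(p, na.rm = TRUE) - 1) > 1e-9)
    msg <- c(msg, "non-missing probabilities must sum to 1 within 1e-9")
  if (!object@method %in% c("eig", "rowsum", "power"))
    msg <- c(msg, "'method' must be one of \"eig\", \"rowsum\", \"power\"")
  if (length(msg)) msg else TRUE
})

#' SignalTrack: a binned real-valued genomic signal
#'
#' Per-bin signal values (ChIP-seq, DNase-seq, MNase-seq and the like) on
#' the same binning convention as [ContactMap-class], with missing-data
#' support.  After [normalizeTrack()] the values are percentiles on the
#' 0-100 scale (0 = at or below the genomic average, 100 = genomic
#' maximum).
#'
#' @slot name dataset name.
#' @slot chrom chromosome name.
#' @slot binSize bin width in base pairs.
#' @slot values per-bin signal, `NA` where missing.
#' @slot normalized `TRUE` once percentile-normalized.
#' @export
setClass("SignalTrack",
  representation(
    name = "character",
    chrom = "character",
    binSize = "numeric",
    values = "numeric",
    normalized = "logical"
  )
)

setValidity("SignalTrack", function(object) {
  msg <- character(0)
  v <- object@values
  if (any(is.infinite(v)))
    msg <- c(msg, "signal values must be finite where present")
  if (isTRUE(object@normalized) &&
      (any(v < 0, na.rm = TRUE) || any(v > 100, na.rm = TRUE)))
    msg <- c(msg, "normalized values must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})
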