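#' Bin-geometry accessors
#'
#' `chrom()`, `binSize()`, `nBins()` and `maskedBins()` give the chromosome
#' name, bin width (bp), bin count and 1-based masked bin indices of the
#' binned objects in this package.
#'
#' @param x a [ContactMap-class], [NormalizedMap-class],
#'   [TransitionMatrix-class], [StationaryProfile-class] or
#'   [SignalTrack-class].
#' @param ... ignored.
#' @return `chrom()` a character scalar; `binSize()` and `nBins()` numeric
#'   scalars; `maskedBins()` an integer vector.
#' @name bin-accessors
NULL

#' @rdname bin-accessors
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))

#' @rdname bin-accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname bin-accessors
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname bin-accessors
#' @export
setGeneric("maskedBins", function(x) standardGeneric("maskedBins"))

#' @rdname bin-accessors
#' @export
setMethod("chrom", "ContactMap", function(x) x@chrom)
#' @rdname bin-accessors
#' @export
setMethod("chrom", "NormalizedMap", function(x) x@chrom)
#' @rdname bin-accessors
#' @export
setMethod("chrom", "SignalTrack", function(x) x@chrom)
#' @rdname bin-accessors
#' @export
setMethod("chrom", "TransitionMatrix", function(x) x@chrom)
#' @rdname bin-accessors
#' @export
setMethod("chrom", "StationaryProfile", function(x) x@chrom)

#' @rdname bin-accessors
#' @export
setMethod("binSize", "ContactMap", function(x) x@binSize)
#' @rdname bin-accessors
#' @export
setMethod("binSize", "NormalizedMap", function(x) x@binSize)
#' @rdname bin-accessors
#' @export
setMethod("binSize", "TransitionMatrix", function(x) x@binSize)
#' @rdname bin-accessors
#' @export
setMethod("binSize", "StationaryProfile", function(x) x@binSize)
#' @rdname bin-accessors
#' @export
setMethod("binSize", "SignalTrack", function(x) x@binSize)
#' @rdname bin-accessors
#' @export
setMethod("binSize", "ExpectedProfile", function(x) x@binSize)

#' @rdname bin-accessors
#' @export
setMethod("nBins", "ContactMap", function(x) nrow(x@values))
#' @rdname bin-accessors
#' @export
setMethod("nBins", "NormalizedMap", function(x) nrow(x@values))
#' @rdname bin-accessors
#' @export
setMethod("nBins", "TransitionMatrix", function(x) x@nBins)
#' @rdname bin-accessors
#' @export
setMethod("nBins", "StationaryProfile", function(x) length(x@p))
#' @rdname bin-accessors
#' @export
setMethod("nBins", "SignalTrack", function(x) length(x@values))

#' @rdname bin-accessors
#' @export
setMethod("maskedBins", "ContactMap", function(x) x@mask)
#' @rdname bin-accessors
#' @export
setMethod("maskedBins", "NormalizedMap", function(x) x@mask)
#' @rdname bin-accessors
#' @export
setMethod("maskedBins", "TransitionMatrix",
          function(x) setdiff(seq_len(x@nBins), x@keep))
#' @rdname bin-accessors
#' @export
setMethod("maskedBins", "StationaryProfile", function(x) which(is.na(x@p)))

#' @rdname bin-accessors
#' @export
setMethod("as.matrix", "ContactMap", function(x, ...) x@values)

#' @rdname bin-accessors
#' @export
setMethod("as.matrix", "NormalizedMap", function(x, ...) x@values)

#' Per-bin values of profiles and tracks
#'
#' @param x a [StationaryProfile-class], [SignalTrack-class] or
#'   [ExpectedProfile-class].
#' @return numeric vector of per-bin (or, for [ExpectedProfile-class],
#'   per-distance) values, `NA` at masked/missing positions.
#' @export
setGeneric("binValues", function(x) standardGeneric("binValues"))

#' @rdname binValues
#' @export
setMethod("binValues", "StationaryProfile", function(x) x@p)

#' @rdname binValues
#' @export
setMethod("binValues", "SignalTrack", function(x) x@values)

#' @rdname binValues
#' @export
setMethod("binValues", "ExpectedProfile", function(x) x@med)

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap on", object@chrom, "-", nrow(object@values), "bins of",
      object@binSize, "bp;", length(object@mask), "masked\n")
})

setMethod("show", "NormalizedMap", function(object) {
  cat("NormalizedMap (", object@kind, ") on ", object@chrom, " - ",
      nrow(object@values), " bins of ", object@binSize, " bp; ",
      length(object@mask), " masked\n", sep = "")
})

setMethod("show", "ExpectedProfile", function(object) {
  cat("ExpectedProfile over", length(object@med), "distances at",
      object@binSize, "bp resolution\n")
})

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix on", object@chrom, "-", length(object@keep), "of",
      object@nBins, "bins kept;",
      length(unique(object@components)), "connected component(s)\n")
})

setMethod("show", "StationaryProfile", function(object) {
  p <- object@p
  cat("StationaryProfile (", object@method, ") on ", object@chrom, " - ",
      length(p), " bins of ", object@binSize, " bp; ",
      sum(is.na(p)), " masked\n", sep = "")
})

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack '", object@name, "' on ", object@chrom, " - ",
      length(object@values), " bins of ", object@binSize, " bp; ",
      sum(is.na(object@values)), " missing",
      if (object@normalized) "; percentile-normalized" else "", "\n",
      sep = "")
})
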