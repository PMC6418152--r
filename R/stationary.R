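#' Build the random-walk transition matrix from a normalized contact map
#'
#' The normalized map is interpreted as a weighted contact network: bins
#' are nodes, and the (clamped) normalized contact frequency between two
#' bins is the weight of the link joining them.  Negative entries — bins in
#' contact less often than expected at their distance — carry no excess
#' affinity and are clamped to zero; `NA` entries contribute zero weight.
#' Every row is then divided by its sum, giving the probability that a
#' random walker at bin `i` jumps to bin `j`.
#'
#' Bins whose row sums to zero after clamping (including all previously
#' masked bins) are added to the mask and dropped from the matrix.
#' Connected components of the clamped weight graph are recorded so that
#' the stationary distribution can be handled per component.
#'
#' @param nm a [NormalizedMap-class]; the `oe_subtract` form is the
#'   intended input, `oe_divide` is accepted.
#' @param dropDiagonal zero out self-contacts (the main diagonal) before
#'   clamping.  Default `FALSE`: self-contacts are retained.
#' @return a [TransitionMatrix-class].
#' @examples
#' v <- rbind(c(10, 5, 2, 1), c(5, 12, 6, 2), c(2, 6, 11, 4), c(1, 2, 4, 9))
#' tm <- buildTransitionMatrix(normalizeMap(ContactMap(v)))
#' tm@W  # 2x2 block over the two surviving bins
#' @export
buildTransitionMatrix <- function(nm, dropDiagonal = FALSE) {
  stopifnot(is(nm, "NormalizedMap"))
  A <- as.matrix(nm)
  A[is.na(A)] <- 0
  A[A < 0] <- 0
  if (dropDiagonal)
    diag(A) <- 0
  msk <- maskedBins(nm)
  if (length(msk)) {
    A[msk, ] <- 0
    A[, msk] <- 0
  }
  rs <- rowSums(A)
  keep <- which(rs > 0)
  if (!length(keep))
    stop("empty network: no bin has positive clamped weight")
  # A is symmetric, so dropping zero-sum rows cannot zero any kept row:
  # the matching columns are already all-zero.
  Ak <- A[keep, keep, drop = FALSE]
  W <- Ak / rs[keep]
  g <- igraph::graph_from_adjacency_matrix(Ak > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- as.integer(igraph::components(g)$membership)
  new("TransitionMatrix", chrom = chrom(nm), binSize = binSize(nm),
      nBins = nrow(A), keep = as.integer(keep), W = unname(W),
      rowWeights = unname(rs[keep]), components = comp)
}

#' Stationary distribution of the contact-network random walk
#'
#' Computes the interactivity profile: the probability vector fixed by
#' `p = p W`, i.e. the left eigenvector of the transition matrix associated
#' with eigenvalue one, normalized to sum to one.  A bin's stationary
#' probability is proportional to its share of excess contacts and is used
#' as a per-bin interactivity score.
#'
#' Three methods are provided and agree on connected symmetric inputs:
#' * `"eig"` (default): eigendecomposition of `t(W)` per connected
#'   component; the eigenvector for the eigenvalue closest to one is taken
#'   elementwise in absolute value and normalized.  An error is raised if
#'   that eigenvalue differs from one by more than `1e-6`.
#' * `"rowsum"`: the closed form for random walks on symmetric weights,
#'   `p[i]` proportional to the clamped weight row sum of bin `i`.
#' * `"power"`: power iteration `p <- p W` from a uniform start until the
#'   maximum absolute change falls below `tol`.
#'
#' When the clamped weight graph has several connected components the
#' stationary distribution is not unique; each component's distribution is
#' weighted by the component's share of total clamped weight, so that the
#' result still reflects relative numbers of contacts.
#'
#' @param tm a [TransitionMatrix-class].
#' @param method `"eig"`, `"rowsum"` or `"power"`.
#' @param tol convergence tolerance for `"power"`.
#' @param maxIter iteration cap for `"power"`; exceeding it is an error.
#' @return a [StationaryProfile-class] with `NA` at masked bins.
#' @examples
#' nm <- new("NormalizedMap", chrom = "chrT", binSize = 5000,
#'           values = rbind(c(0, 2, 1), c(2, 0, 1), c(1, 1, 0)),
#'           mask = integer(0), kind = "oe_subtract")
#' binValues(stationaryDistribution(buildTransitionMatrix(nm)))
#' # 0.375 0.375 0.250
#' @export
stationaryDistribution <- function(tm, method = c("eig", "rowsum", "power"),
                                   tol = 1e-12, maxIter = 1e5) {
  method <- match.arg(method)
  stopifnot(is(tm, "TransitionMatrix"))
  k <- length(tm@keep)
  p <- rep(NA_real_, tm@nBins)
  total <- sum(tm@rowWeights)
  pk <- numeric(k)
  for (cc in unique(tm@components)) {
    idx <- which(tm@components == cc)
    share <- sum(tm@rowWeights[idx]) / total
    pc <- switch(method,
      rowsum = tm@rowWeights[idx] / sum(tm@rowWeights[idx]),
      eig = .stationaryEig(tm@W[idx, idx, drop = FALSE]),
      power = .stationaryPower(tm@W[idx, idx, drop = FALSE], tol, maxIter))
    pk[idx] <- pc * share
  }
  p[tm@keep] <- pk
  new("StationaryProfile", chrom = chrom(tm), binSize = binSize(tm),
      p = p, method = method)
}

.stationaryEig <- function(W) {
  if (nrow(W) == 1L)
    return(1)
  e <- eigen(t(W))
  i <- which.min(abs(e$values - 1))
  lam <- e$values[i]
  if (abs(lam - 1) > 1e-6)
    stop("leading eigenvalue ", format(lam), " differs from 1 by more than 1e-6")
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

.stationaryPower <- function(W, tol, maxIter) {
  n <- nrow(W)
  p <- rep(1 / n, n)
  for (it in seq_len(maxIter)) {
    p2 <- as.vector(p %*% W)
    if (max(abs(p2 - p)) < tol)
      return(p2 / sum(p2))
    p <- p2
  }
  stop("power iteration did not converge within ", maxIter, " iterations")
}

#' Write a stationary profile as bedGraph
#'
#' One record per unmasked bin; masked bins are omitted.
#'
#' @param p a [StationaryProfile-class] (or [SignalTrack-class]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
profileToBedGraph <- function(p, path) {
  .exportBedGraph(binValues(p), chrom(p), binSize(p), path)
}

.exportBedGraph <- function(values, chrom, binSize, path) {
  keep <- which(!is.na(values))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(chrom, length(keep)),
    ranges = IRanges::IRanges(start = (keep - 1) * binSize + 1,
                              width = binSize),
    score = values[keep])
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
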