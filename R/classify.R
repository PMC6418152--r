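#' Assemble the HIR x track enrichment matrix
#'
#' Entry `(h, t)` is the mean normalized enrichment of track `t` over the
#' bins of HIR `h`.  Entries missing because the track has no data over
#' the HIR are imputed with the column mean; the number of imputed entries
#' is recorded in the `"imputed"` attribute.
#'
#' @param tracks list of normalized [SignalTrack-class] objects (after
#'   [excludeDatasets()]).
#' @param hirs HIR `GRanges`; must be non-empty.
#' @return a numeric matrix with HIR names as row names and track names as
#'   column names.
#' @export
assembleMatrix <- function(tracks, hirs) {
  if (!length(hirs))
    stop("cannot assemble a feature matrix for an empty HIR set")
  if (!length(tracks))
    stop("no tracks supplied")
  X <- vapply(tracks, function(tr) .regionMeans(tr, hirs),
              numeric(length(hirs)))
  X <- matrix(X, nrow = length(hirs))
  rownames(X) <- S4Vectors::mcols(hirs)$name
  colnames(X) <- vapply(tracks, function(tr) tr@name, character(1))
  nImputed <- 0L
  for (j in seq_len(ncol(X))) {
    na <- is.na(X[, j])
    if (all(na))
      stop("track '", colnames(X)[j], "' has no data over any HIR")
    if (any(na)) {
      X[na, j] <- mean(X[!na, j])
      nImputed <- nImputed + sum(na)
    }
  }
  attr(X, "imputed") <- nImputed
  X
}

#' Principal component scores of the enrichment matrix
#'
#' Columns are centred and scaled to unit variance (zero-variance columns
#' are dropped with a warning), then the rows are projected onto the top
#' right singular directions.  This equals PCA on the column correlation
#' matrix.  Component signs follow a deterministic convention: the
#' largest-magnitude loading of each component is made positive (ties
#' broken by lowest column index).
#'
#' @param X matrix from [assembleMatrix()].
#' @param nComponents number of components to keep; must not exceed the
#'   rank of the scaled matrix.
#' @return a list with `scores` (n x nComponents), `loadings`,
#'   `explainedVar` (fractions for *all* components; sums to 1) and
#'   `dropped` (names of zero-variance columns).
#' @export
pcaScores <- function(X, nComponents = 6) {
  stopifnot(nrow(X) >= 2, ncol(X) >= 2)
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  Xs <- scale(X)
  sv <- svd(Xs)
  tol <- max(dim(Xs)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  if (nComponents > r)
    stop("nComponents (", nComponents, ") exceeds the matrix rank (", r, ")")
  V <- sv$v[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(nComponents)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- Xs %*% V
  colnames(scores) <- colnames(V) <- paste0("PC", seq_len(nComponents))
  rownames(V) <- colnames(X)
  list(scores = scores, loadings = V,
       explainedVar = sv$d^2 / sum(sv$d^2), dropped = dropped)
}

#' Broken-stick component count
#'
#' Data-driven alternative for choosing the number of components: keeps
#' components whose explained-variance fraction exceeds the broken-stick
#' expectation.
#'
#' @param explainedVar explained-variance fractions from [pcaScores()].
#' @return the number of components to keep (at least 1).
#' @export
brokenStick <- function(explainedVar) {
  k <- length(explainedVar)
  bs <- rev(cumsum(1 / rev(seq_len(k)))) / k
  above <- explainedVar > bs
  if (!above[1]) return(1L)
  # leading run of components above the broken-stick expectation
  sum(cumprod(above))
}

#' Ward clustering of PCA scores into HIR classes
#'
#' Agglomerative hierarchical clustering with Ward's criterion on
#' Euclidean distances between the component scores, cut at `k` clusters.
#' Labels are renumbered `1..k` by decreasing cluster size (ties broken by
#' the lowest member row index), so that class 1 is always the largest.
#'
#' @param scores score matrix from [pcaScores()].
#' @param k number of classes, default 6.
#' @return integer vector of class labels named by row names.
#' @export
wardClusters <- function(scores, k = 6) {
  if (k < 1)
    stop("k must be at least 1")
  if (k > nrow(scores))
    stop("k exceeds the number of rows")
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  raw <- stats::cutree(hc, k = k)
  size <- tabulate(raw, nbins = k)
  first <- vapply(seq_len(k), function(c) match(c, raw), integer(1))
  ord <- order(-size, first)
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  out <- relabel[raw]
  names(out) <- rownames(scores)
  out
}

#' Classify HIRs from an enrichment matrix
#'
#' Convenience wrapper: [pcaScores()] on the assembled matrix followed by
#' [wardClusters()] on the component scores.
#'
#' @param X matrix from [assembleMatrix()].
#' @param nComponents number of components, default 6.
#' @param k number of classes, default 6.
#' @return list with `classes` (named integer vector), `pca` (the
#'   [pcaScores()] result) and `k`.
#' @export
classifyHIRs <- function(X, nComponents = 6, k = 6) {
  nc <- min(nComponents, ncol(X), nrow(X) - 1L)
  pca <- pcaScores(X, nComponents = nc)
  list(classes = wardClusters(pca$scores, k = min(k, nrow(X))),
       pca = pca, k = min(k, nrow(X)))
}
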