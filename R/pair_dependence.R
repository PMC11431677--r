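#' Build the locus-pair index
#'
#' Enumerates the D = L'(L'-1)/2 unique unordered pairs of loci in
#' lexicographic order by (i, j), i < j. Every downstream pair-level object
#' carries this map; any consistent order yields the same eigenspectra
#' (similarity invariance).
#'
#' @param l Integer locus count, >= 2.
#' @return A [PairIndexMap-class].
#' @examples
#' nPairs(makePairIndex(10)) # 45
#' @export
makePairIndex <- function(l) {
  l <- as.integer(l)
  if (is.na(l) || l < 2L) stop("'l' must be an integer >= 2")
  i <- rep.int(seq_len(l - 1L), times = (l - 1L):1L)
  j <- sequence((l - 1L):1L) + i
  new("PairIndexMap", nLoci = l, pairs = cbind(i = i, j = j))
}

#' Number of pairs sharing a locus with a given pair
#'
#' Any pair (i, j) shares exactly one locus with 2(L' - 2) other pairs;
#' the r-squared values of sharing pairs are positively correlated, which
#' is the focal source of pseudoreplication in linkage-disequilibrium
#' analyses. Only L'/2 disjoint pairs are mutually independent.
#'
#' @param l Integer locus count.
#' @param pair Integer vector (i, j), 1 <= i < j <= l.
#' @return Integer 2(l - 2).
#' @examples
#' countSharingPairs(10, c(2, 6)) # 16
#' @seealso [sharingPairs()] for the explicit enumeration.
#' @export
countSharingPairs <- function(l, pair) {
  checkPair(l, pair)
  2L * (as.integer(l) - 2L)
}

checkPair <- function(l, pair) {
  if (length(pair) != 2L || pair[1] < 1L || pair[2] <= pair[1] || pair[2] > l)
    stop("invalid pair: need 1 <= i < j <= l")
  invisible(TRUE)
}

#' Enumerate the pairs sharing a locus with a given pair
#'
#' @param index A [PairIndexMap-class].
#' @param pair Integer (i, j), i < j.
#' @return Integer matrix of the sharing pairs (one row each); its row
#'   count equals [countSharingPairs()].
#' @export
sharingPairs <- function(index, pair) {
  checkPair(index@nLoci, pair)
  p <- index@pairs
  hit <- (p[, 1] %in% pair | p[, 2] %in% pair) &
    !(p[, 1] == pair[1] & p[, 2] == pair[2])
  p[hit, , drop = FALSE]
}

#' Flatten the r-squared array into a pair-by-replicate matrix
#'
#' Row k holds the r-squared trajectory of pair k (in [makePairIndex()]
#' order) across replicates. With \code{squareLayout = TRUE} the rows
#' instead follow the full L' x L' layout (every ordered pair plus the
#' diagonal, L'^2 rows); the diagonal and duplicate rows are then removed
#' downstream as zero-variance/duplicated structure. That layout exists
#' only for comparison with analyses that used the square matrix.
#'
#' @param arr An [R2ReplicateArray-class] with symmetric slices (checked
#'   to 1e-12).
#' @param squareLayout Use the L'^2 square layout (default FALSE).
#' @return A [PairObservationMatrix-class].
#' @export
vectorizePairs <- function(arr, squareLayout = FALSE) {
  v <- arr@values
  l <- dim(v)[1]
  n <- dim(v)[3]
  for (k in seq_len(n)) {
    s <- v[, , k]
    if (max(abs(s - t(s))) > 1e-12)
      stop("replicate ", k, ": r-squared slice is asymmetric beyond 1e-12")
  }
  idx <- makePairIndex(l)
  if (squareLayout) {
    m <- matrix(v, nrow = l * l, ncol = n)
    full <- cbind(i = rep(seq_len(l), times = l), j = rep(seq_len(l), each = l))
    obj <- new("PairIndexMap", nLoci = l, pairs = idx@pairs)
    out <- new("PairObservationMatrix", values = m, index = obj,
               replicateIds = arr@replicateIds)
    attr(out@values, "layout") <- "square"
    rownames(out@values) <- paste(full[, 1], full[, 2], sep = ":")
    return(out)
  }
  lin <- (idx@pairs[, 2] - 1L) * l + idx@pairs[, 1]
  m <- matrix(v, nrow = l * l, ncol = n)[lin, , drop = FALSE]
  rownames(m) <- paste(idx@pairs[, 1], idx@pairs[, 2], sep = ":")
  colnames(m) <- arr@replicateIds
  new("PairObservationMatrix", values = m, index = idx,
      replicateIds = arr@replicateIds)
}

#' Restore the upper triangle from a pair-observation matrix
#'
#' Inverse of [vectorizePairs()] (unique-pair layout) for one replicate.
#'
#' @param obs A [PairObservationMatrix-class].
#' @param replicate Integer replicate (column) index.
#' @return Symmetric L' x L' matrix with unit diagonal.
#' @export
unvectorizePairs <- function(obs, replicate = 1L) {
  idx <- obs@index
  l <- idx@nLoci
  m <- diag(nrow = l)
  m[cbind(idx@pairs[, 1], idx@pairs[, 2])] <- obs@values[, replicate]
  m[cbind(idx@pairs[, 2], idx@pairs[, 1])] <- obs@values[, replicate]
  m
}

#' Across-replicate covariance of pair r-squared
#'
#' Estimates the D x D covariance Sigma (and implicitly the correlation R)
#' of r-squared across locus pairs from the n_rep replicate columns -- the
#' "correlations of correlations" that quantify pseudoreplication. Pair
#' rows with zero variance across replicates would make correlation entries
#' undefined and poison the eigendecomposition, so they are dropped with a
#' recorded count. Sigma itself is not materialized (rank <= n_rep - 1;
#' see [PairCovariance-class]): use [covMatrix()]/[corrMatrix()] for small
#' D or [topEigenvalues()] for the spectrum at any D.
#'
#' @param obs A [PairObservationMatrix-class] with >= 2 replicates.
#' @param divisor \code{"unbiased"} (n_rep - 1, default) or \code{"ml"}
#'   (n_rep).
#' @param sdTol Absolute standard-deviation floor below which a pair row
#'   counts as constant (default 1e-8). r-squared lives in [0, 1], so rows
#'   varying only at floating-point noise level (e.g. pairs of perfectly
#'   collinear loci whose r-squared is identically 1 in every replicate)
#'   fall far below this while any genuine resampling variation sits far
#'   above it; standardizing such rows would inject spurious unit-variance
#'   noise directions into R.
#' @return A [PairCovariance-class].
#' @export
pairCovariance <- function(obs, divisor = c("unbiased", "ml"), sdTol = 1e-8) {
  divisor <- match.arg(divisor)
  x <- obs@values
  n <- ncol(x)
  if (n < 2L) stop("need at least 2 replicates to estimate a covariance")
  ctr <- x - rowMeans(x)
  ss <- rowSums(ctr * ctr)
  keep <- ss > n * sdTol^2
  dropped <- sum(!keep)
  if (!any(keep)) stop("degenerate covariance: all pair rows have zero variance across replicates")
  den <- if (divisor == "unbiased") n - 1L else n
  new("PairCovariance",
      centered = ctr[keep, , drop = FALSE],
      rowSd = sqrt(ss[keep] / den),
      keptPairs = which(keep), droppedPairs = as.integer(dropped),
      nObs = as.integer(n), divisor = as.numeric(den),
      index = obs@index)
}

#' Dense covariance / correlation matrices
#'
#' Materialize Sigma or R from a [PairCovariance-class]. Intended for
#' small problems (D up to a few thousand); storage is O(D^2), which is
#' the method's own scalability bottleneck, so larger requests error.
#'
#' @param cov A [PairCovariance-class].
#' @param maxDim Refuse to allocate beyond this dimension (default 3000).
#' @return A symmetric matrix over the retained pair rows.
#' @export
covMatrix <- function(cov, maxDim = 3000L) {
  d <- nrow(cov@centered)
  if (d > maxDim)
    stop("D = ", d, " retained pairs: dense Sigma would need O(D^2) storage; ",
         "use topEigenvalues() or raise 'maxDim'")
  tcrossprod(cov@centered) / cov@divisor
}

#' @rdname covMatrix
#' @export
corrMatrix <- function(cov, maxDim = 3000L) {
  d <- nrow(cov@centered)
  if (d > maxDim)
    stop("D = ", d, " retained pairs: dense R would need O(D^2) storage; ",
         "use topEigenvalues() or raise 'maxDim'")
  y <- cov@centered / cov@rowSd
  tcrossprod(y) / cov@divisor
}
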