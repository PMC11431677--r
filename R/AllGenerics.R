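#' Accessors
#'
#' Small accessor generics for the package's S4 containers.
#'
#' @param x An object.
#' @return \code{samples}: list of dosage matrices; \code{locusIds}:
#'   character; \code{nLoci}, \code{nPairs}, \code{nReplicates}: integer;
#'   \code{r2Values}: the 3-d array; \code{pairValues}: the D x n_rep
#'   matrix; \code{pairIndex}: a [PairIndexMap-class]; \code{eigenValues}:
#'   numeric; \code{nPositive}: integer.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("locusIds", function(x) standardGeneric("locusIds"))
#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @rdname accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))
#' @rdname accessors
#' @export
setGeneric("r2Values", function(x) standardGeneric("r2Values"))
#' @rdname accessors
#' @export
setGeneric("pairValues", function(x) standardGeneric("pairValues"))
#' @rdname accessors
#' @export
setGeneric("pairIndex", function(x) standardGeneric("pairIndex"))
#' @rdname accessors
#' @export
setGeneric("eigenValues", function(x) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setGeneric("nPositive", function(x) standardGeneric("nPositive"))

#' @rdname accessors
setMethod("samples", "ReplicateSet", function(x) x@samples)
#' @rdname accessors
setMethod("locusIds", "ReplicateSet", function(x) x@locusIds)
#' @rdname accessors
setMethod("locusIds", "R2ReplicateArray", function(x) x@locusIds)
#' @rdname accessors
setMethod("nLoci", "ReplicateSet", function(x) length(x@locusIds))
#' @rdname accessors
setMethod("nLoci", "R2ReplicateArray", function(x) length(x@locusIds))
#' @rdname accessors
setMethod("nLoci", "PairIndexMap", function(x) x@nLoci)
#' @rdname accessors
setMethod("nPairs", "PairIndexMap", function(x) nrow(x@pairs))
#' @rdname accessors
setMethod("nPairs", "PairObservationMatrix", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nPairs", "PairCovariance", function(x) nrow(x@centered))
#' @rdname accessors
setMethod("nReplicates", "ReplicateSet", function(x) length(x@samples))
#' @rdname accessors
setMethod("nReplicates", "R2ReplicateArray", function(x) dim(x@values)[3])
#' @rdname accessors
setMethod("nReplicates", "PairObservationMatrix", function(x) ncol(x@values))
#' @rdname accessors
setMethod("nReplicates", "PairCovariance", function(x) x@nObs)
#' @rdname accessors
setMethod("r2Values", "R2ReplicateArray", function(x) x@values)
#' @rdname accessors
setMethod("pairValues", "PairObservationMatrix", function(x) x@values)
#' @rdname accessors
setMethod("pairIndex", "PairObservationMatrix", function(x) x@index)
#' @rdname accessors
setMethod("pairIndex", "PairCovariance", function(x) x@index)
#' @rdname accessors
setMethod("eigenValues", "EigenSpectrum", function(x) x@values)
#' @rdname accessors
setMethod("nPositive", "EigenSpectrum", function(x) x@np)

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: Ne =", if (is.infinite(object@ne)) "infinite" else object@ne,
      "| S =", object@s, "| L =", object@l,
      "| generations =", object@generations,
      "| replicates =", object@nRep, "\n")
  cat("  filterScope =", object@filterScope, "| p =", object@p,
      "| seed =", object@seed, "\n")
  invisible(object)
})

setMethod("show", "ReplicateSet", function(object) {
  cat("ReplicateSet:", length(object@samples), "replicates of",
      nrow(object@samples[[1]]), "individuals x",
      length(object@locusIds), "loci",
      if (is.null(object@pool)) "(infinite-Ne mode)" else
        sprintf("(pool of %d)", nrow(object@pool)), "\n")
  invisible(object)
})

setMethod("show", "R2ReplicateArray", function(object) {
  d <- dim(object@values)
  cat(sprintf("R2ReplicateArray: %d x %d loci x %d replicates\n",
              d[1], d[2], d[3]))
  invisible(object)
})

setMethod("show", "PairIndexMap", function(object) {
  cat(sprintf("PairIndexMap: L' = %d loci, D = %d unique pairs\n",
              object@nLoci, nrow(object@pairs)))
  invisible(object)
})

setMethod("show", "PairObservationMatrix", function(object) {
  cat(sprintf("PairObservationMatrix: %d pairs x %d replicates\n",
              nrow(object@values), ncol(object@values)))
  invisible(object)
})

setMethod("show", "PairCovariance", function(object) {
  cat(sprintf(
    "PairCovariance: %d pair rows (of %d; %d zero-variance dropped), %d replicates\n",
    nrow(object@centered), nPairs(object@index), object@droppedPairs,
    object@nObs))
  cat("  rank <=", min(nrow(object@centered), object@nObs - 1L),
      "| divisor =", object@divisor, "\n")
  invisible(object)
})

setMethod("show", "EigenSpectrum", function(object) {
  cat(sprintf(
    "EigenSpectrum of %s: dim %d, %d eigenvalues retained, np = %d\n",
    if (object@useCorr) "R (correlation)" else "Sigma (covariance)",
    object@dim, length(object@values), object@np))
  invisible(object)
})

setMethod("show", "EntropySummary", function(object) {
  cat("EntropySummary:\n")
  cat(sprintf("  D = %d pairs (L' = %d loci, %d zero-variance rows dropped)\n",
              object@d, object@lRetained, object@droppedPairs))
  cat(sprintf("  np = %d | TC (default) = %.6g | TC (canonical) = %.6g\n",
              object@np, object@tcTruncated, object@tcCanonical))
  cat(sprintf("  H(Sigma) = %.6g | H(R) = %.6g | pseudo-logdet(Sigma) = %.6g\n",
              object@hSigma, object@hCorr, object@logdet))
  if (object@flagged)
    cat("  [flagged: a variant had non-positive (1 - np/D_eff)]\n")
  invisible(object)
})

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf("RegressionFit (%s): %s\n", object@response, object@formula))
  print(object@coefficients, row.names = FALSE, digits = 4)
  cat(sprintf("  R-squared = %.6f | AIC = %.3f | n = %d (%d dropped)\n",
              object@rSquared, object@aic, object@n, object@nDropped))
  invisible(object)
})

#' @describeIn RegressionFit-class Coefficients etc. as a data frame.
#' @param x A RegressionFit.
#' @param ... Ignored.
#' @export
as.data.frame.RegressionFit <- function(x, ...) x@coefficients

#' @describeIn EntropySummary-class One-row data frame of all statistics.
#' @param x An EntropySummary.
#' @param ... Ignored.
#' @export
as.data.frame.EntropySummary <- function(x, ...) {
  v <- x@tcVariants
  data.frame(
    d = x@d, lRetained = x@lRetained, droppedPairs = x@droppedPairs,
    np = x@np, npSigma = x@npSigma,
    tc = x@tcTruncated, tcCanonical = x@tcCanonical,
    tcSumEigenLocus = v[["sum_eigen.locus_count"]],
    tcLogdetMatrix = v[["pseudo_logdet.matrix_dim"]],
    tcLogdetLocus = v[["pseudo_logdet.locus_count"]],
    hSigma = x@hSigma, hCorr = x@hCorr, logdet = x@logdet,
    flagged = x@flagged
  )
}
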