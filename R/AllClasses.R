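#' @import methods
NULL

#' Simulation configuration
#'
#' Parameters of one simulated dataset: a monoecious, randomly mating
#' (selfing allowed) Wright--Fisher population of unlinked biallelic loci,
#' plus the replicate-resampling protocol used to estimate the covariance
#' of r-squared across locus pairs.
#'
#' @slot ne Numeric; effective (= census) parent count per generation.
#'   \code{Inf} selects the infinite-population reference mode, in which
#'   genotypes are drawn directly in Hardy--Weinberg proportions at the
#'   parametric allele frequency \code{p}.
#' @slot s Integer; offspring sample size per replicate.
#' @slot l Integer; nominal locus count.
#' @slot generations Integer; burn-in length (generations of random mating
#'   before sampling). Six generations establish equilibrium
#'   linkage disequilibrium for unlinked loci.
#' @slot nRep Integer; number of replicate samples resampled from the final
#'   generation.
#' @slot filterScope Character; \code{"any_replicate"} removes every locus
#'   monomorphic in at least one replicate sample (so all replicates share
#'   one locus set), \code{"pool_only"} removes only loci monomorphic in
#'   the final-generation pool.
#' @slot p Numeric; parametric reference-allele frequency used by the
#'   infinite-Ne mode. The all-heterozygote initialization of the finite
#'   model implies 0.5.
#' @slot seed Integer or NA; RNG seed recorded with the configuration and
#'   used by the pipeline helpers when set.
#'
#' @seealso [simConfig()]
#' @export
setClass("SimConfig",
  representation(
    ne = "numeric", s = "integer", l = "integer",
    generations = "integer", nRep = "integer",
    filterScope = "character", p = "numeric", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (length(object@ne) != 1 || is.na(object@ne) ||
      (!is.infinite(object@ne) && (object@ne < 2 || object@ne != round(object@ne))))
    msgs <- c(msgs, "'ne' must be an integer >= 2 or Inf")
  if (object@s < 2L) msgs <- c(msgs, "'s' (offspring sample size) must be >= 2")
  if (object@l < 2L) msgs <- c(msgs, "'l' (locus count) must be >= 2")
  if (object@generations < 0L) msgs <- c(msgs, "'generations' must be >= 0")
  if (object@nRep < 2L) msgs <- c(msgs, "'nRep' must be >= 2")
  if (!object@filterScope %in% c("any_replicate", "pool_only"))
    msgs <- c(msgs, "'filterScope' must be \"any_replicate\" or \"pool_only\"")
  if (object@p <= 0 || object@p >= 1) msgs <- c(msgs, "'p' must lie in (0, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Replicate genotype samples sharing one locus set
#'
#' An ordered collection of genotype dosage matrices (individuals x loci,
#' entries 0/1/2 copies of the reference allele), all resampled with
#' replacement from the same final-generation pool (finite Ne) or drawn
#' fresh under Hardy--Weinberg proportions (infinite Ne), over a common
#' ordered locus set.
#'
#' @slot samples List of integer dosage matrices, each \code{s} rows.
#' @slot locusIds Character; locus labels shared by all samples (columns).
#' @slot pool The final-generation parent pool the samples were drawn from
#'   (restricted to the retained loci), or NULL in infinite-Ne mode.
#' @slot config The [SimConfig-class] that produced the set.
#'
#' @export
setClass("ReplicateSet",
  representation(samples = "list", locusIds = "character",
                 pool = "ANY", config = "SimConfig")
)

setValidity("ReplicateSet", function(object) {
  msgs <- character()
  if (!length(object@samples)) msgs <- c(msgs, "empty replicate set")
  ok <- vapply(object@samples, function(m) {
    is.matrix(m) && identical(colnames(m), object@locusIds) &&
      all(m %in% 0:2)
  }, logical(1))
  if (!all(ok)) msgs <- c(msgs, "all samples must be 0/1/2 matrices over 'locusIds'")
  nr <- vapply(object@samples, nrow, integer(1))
  if (length(unique(nr)) > 1)
    msgs <- c(msgs, "all replicate samples must have the same number of rows")
  if (length(msgs)) msgs else TRUE
})

#' Replicate-stacked array of pairwise r-squared
#'
#' The (L', L', n_rep) array of genotypic r-squared: one symmetric slice
#' per replicate sample, diagonal 1 by convention.
#'
#' @slot values Numeric 3-d array, dims (loci, loci, replicates).
#' @slot locusIds Character labels of the first two dimensions.
#' @slot replicateIds Character labels of the third dimension.
#'
#' @export
setClass("R2ReplicateArray",
  representation(values = "array", locusIds = "character",
                 replicateIds = "character")
)

setValidity("R2ReplicateArray", function(object) {
  d <- dim(object@values)
  msgs <- character()
  if (length(d) != 3 || d[1] != d[2])
    msgs <- c(msgs, "'values' must be a (L, L, n_rep) array")
  if (d[1] != length(object@locusIds) || d[3] != length(object@replicateIds))
    msgs <- c(msgs, "dimension labels do not match array dims")
  v <- object@values
  if (anyNA(v) || min(v) < -1e-12 || max(v) > 1 + 1e-12)
    msgs <- c(msgs, "r-squared values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Locus-pair index map
#'
#' Bijection between pair rank k in 1..D and the ordered pair (i, j),
#' i < j, in lexicographic order; D = L'(L'-1)/2.
#'
#' @slot nLoci Integer L'.
#' @slot pairs Integer D x 2 matrix of (i, j), i < j, lexicographic.
#'
#' @export
setClass("PairIndexMap",
  representation(nLoci = "integer", pairs = "matrix")
)

setValidity("PairIndexMap", function(object) {
  l <- object@nLoci
  p <- object@pairs
  msgs <- character()
  if (l < 2L) msgs <- c(msgs, "'nLoci' must be >= 2")
  if (nrow(p) != l * (l - 1L) / 2L) msgs <- c(msgs, "pair count must be L(L-1)/2")
  if (any(p[, 1] >= p[, 2])) msgs <- c(msgs, "pairs must satisfy i < j")
  if (length(msgs)) msgs else TRUE
})

#' Pair-by-replicate observation matrix
#'
#' r-squared of every unique locus pair (rows, in [PairIndexMap-class]
#' order) across replicates (columns).
#'
#' @slot values Numeric D x n_rep matrix, entries in [0, 1].
#' @slot index The [PairIndexMap-class] labelling the rows.
#' @slot replicateIds Character column labels.
#'
#' @export
setClass("PairObservationMatrix",
  representation(values = "matrix", index = "PairIndexMap",
                 replicateIds = "character")
)

#' Across-replicate covariance of locus-pair r-squared
#'
#' The sample covariance Sigma (and correlation R) of r-squared across the
#' D = L'(L'-1)/2 locus pairs -- the "correlations of correlations". Because
#' D commonly exceeds the replicate count, Sigma has rank at most
#' n_rep - 1 and is never materialized here: the object stores the
#' column-centered D x n_rep observation matrix, from which dense Sigma/R
#' (for small D, via [covMatrix()]/[corrMatrix()]) or the truncated
#' eigenspectrum (any D, via [topEigenvalues()]) are derived. Pair rows
#' with zero variance across replicates are dropped on construction.
#'
#' @slot centered Numeric (kept D) x n_rep row-centered observation matrix.
#' @slot rowSd Numeric; per-row standard deviations (same divisor as the
#'   covariance).
#' @slot keptPairs Integer indices (into the original pair order) of rows
#'   with nonzero variance.
#' @slot droppedPairs Integer; number of zero-variance rows removed.
#' @slot nObs Integer; number of replicates.
#' @slot divisor Numeric; n_rep - 1 (unbiased) or n_rep (ML).
#' @slot index The originating [PairIndexMap-class].
#'
#' @export
setClass("PairCovariance",
  representation(centered = "matrix", rowSd = "numeric",
                 keptPairs = "integer", droppedPairs = "integer",
                 nObs = "integer", divisor = "numeric",
                 index = "PairIndexMap")
)

setValidity("PairCovariance", function(object) {
  msgs <- character()
  if (nrow(object@centered) != length(object@rowSd))
    msgs <- c(msgs, "'rowSd' length must match retained rows")
  if (ncol(object@centered) != object@nObs)
    msgs <- c(msgs, "'nObs' must equal the number of observation columns")
  if (object@nObs < 2L) msgs <- c(msgs, "need at least 2 replicates")
  if (length(msgs)) msgs else TRUE
})

#' Truncated eigenspectrum
#'
#' The k largest eigenvalues of the pair covariance Sigma or correlation R,
#' with the count np of eigenvalues exceeding a relative positivity
#' threshold. For D > n_rep the spectrum is obtained from the
#' n_rep x n_rep Gram matrix of centered observations, whose nonzero
#' eigenvalues equal those of the D x D matrix.
#'
#' @slot values Numeric, descending eigenvalues (length min(kMax, available)).
#' @slot np Integer; eigenvalues above \code{threshold * max(eigenvalue)}.
#' @slot kMax Integer; requested spectrum length.
#' @slot threshold Numeric; relative positivity tolerance.
#' @slot dim Integer; dimension of the underlying matrix (retained pairs).
#' @slot useCorr Logical; TRUE if the spectrum is of R, FALSE if of Sigma.
#'
#' @export
setClass("EigenSpectrum",
  representation(values = "numeric", np = "integer", kMax = "integer",
                 threshold = "numeric", dim = "integer", useCorr = "logical")
)

setValidity("EigenSpectrum", function(object) {
  msgs <- character()
  if (is.unsorted(rev(object@values), strictly = FALSE))
    msgs <- c(msgs, "eigenvalues must be in descending order")
  if (object@np > length(object@values))
    msgs <- c(msgs, "'np' cannot exceed the number of retained eigenvalues")
  if (length(msgs)) msgs else TRUE
})

#' Entropy summary of one dataset
#'
#' Eigenspectrum-derived statistics of the pair covariance: canonical
#' Gaussian total correlation, the truncated-spectrum estimator in all four
#' labeled variants, multivariate Gaussian entropies of Sigma and R, and
#' the pseudo-log-determinant.
#'
#' @slot tcCanonical Numeric, nats; -1/2 sum(ln lambda_i(R)) over retained
#'   eigenvalues (Gaussian total correlation; exact at full rank).
#' @slot tcTruncated Numeric; default truncated estimator
#'   sum(lambda_i(R)) * (1 - np/D).
#' @slot tcVariants Named numeric(4); all base x dimension variants.
#' @slot hSigma Numeric, nats; Gaussian entropy from Sigma's spectrum on
#'   its np-dimensional support (scale-dependent).
#' @slot hCorr Numeric, nats; same from R (scale-invariant).
#' @slot logdet Numeric; pseudo-log-determinant of Sigma.
#' @slot np Integer; positive-eigenvalue count of R's spectrum.
#' @slot npSigma Integer; positive-eigenvalue count of Sigma's spectrum.
#' @slot d Integer; matrix dimension (retained pairs).
#' @slot lRetained Integer; retained locus count.
#' @slot droppedPairs Integer; zero-variance pair rows removed upstream.
#' @slot flagged Logical; TRUE if any variant had a non-positive
#'   (1 - np/D_eff) factor.
#'
#' @export
setClass("EntropySummary",
  representation(tcCanonical = "numeric", tcTruncated = "numeric",
                 tcVariants = "numeric", hSigma = "numeric",
                 hCorr = "numeric", logdet = "numeric", np = "integer",
                 npSigma = "integer", d = "integer", lRetained = "integer",
                 droppedPairs = "integer", flagged = "logical")
)

#' Ordinary-least-squares fit of an entropy response
#'
#' Coefficients and fit statistics of a linear model of a log-transformed
#' entropy statistic on log(L), log(Ne), log(S).
#'
#' @slot coefficients Data frame: term, estimate, std.error, t.value, p.value.
#' @slot rSquared Numeric in [0, 1].
#' @slot aic Numeric.
#' @slot formula Character descriptor of the fitted model.
#' @slot response Character; "tc" or "h".
#' @slot n Integer; records used.
#' @slot nDropped Integer; records excluded for non-positive response.
#'
#' @export
setClass("RegressionFit",
  representation(coefficients = "data.frame", rSquared = "numeric",
                 aic = "numeric", formula = "character",
                 response = "character", n = "integer", nDropped = "integer")
)

setValidity("RegressionFit", function(object) {
  if (object@rSquared < -1e-12 || object@rSquared > 1 + 1e-12)
    "R-squared must lie in [0, 1]" else TRUE
})
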