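#' Simulate one dataset and compute its entropy summary
#'
#' End-to-end pipeline for a single configuration: burn-in (or the
#' infinite-Ne Hardy--Weinberg generator), replicate resampling with the
#' monomorphic filter, per-replicate r-squared matrices, pair
#' vectorization, across-replicate covariance, and the eigenspectrum
#' entropy statistics.
#'
#' @param config A [SimConfig-class].
#' @param seed Optional integer seed (defaults to \code{config@seed} when
#'   set); applied via \code{set.seed()} before any random draw so repeated
#'   calls are bit-identical.
#' @param kMax,threshold Passed to [topEigenvalues()].
#' @param keepReplicates Also return the [ReplicateSet-class] (default
#'   FALSE; the genotype samples can be large).
#' @return A list with elements \code{summary} ([EntropySummary-class]),
#'   \code{lRetained}, \code{config}, \code{seed}, and (optionally)
#'   \code{replicates}.
#' @examples
#' res <- datasetEntropy(simConfig(ne = 40, s = 50, l = 25), seed = 1)
#' res$summary
#' @export
datasetEntropy <- function(config, seed = NULL, kMax = 500L,
                           threshold = 1e-10, keepReplicates = FALSE) {
  if (is.null(seed) && !is.na(config@seed)) seed <- config@seed
  if (!is.null(seed)) set.seed(as.integer(seed))
  reps <- sampleReplicates(config)
  arr <- buildR2Array(reps)
  obs <- vectorizePairs(arr)
  cov <- pairCovariance(obs)
  es <- entropySummary(cov, lRetained = nLoci(reps), kMax = kMax,
                       threshold = threshold)
  out <- list(summary = es, lRetained = nLoci(reps), config = config,
              seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
  if (keepReplicates) out$replicates <- reps
  out
}
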