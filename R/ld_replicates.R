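#' Genotypic r-squared between two loci
#'
#' The squared Pearson correlation between the dosage vectors of two loci
#' in one sample -- the standard genotypic linkage-disequilibrium measure
#' for unphased biallelic data. No haplotype phasing is involved.
#'
#' @param a,b Numeric/integer dosage vectors of equal length >= 2, neither
#'   constant.
#' @return A scalar in [0, 1].
#' @examples
#' genotypeR2(c(0, 1, 2, 1), c(2, 1, 0, 1)) # perfect negative LD -> 1
#' @export
genotypeR2 <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("dosage vectors must have equal length >= 2")
  if (max(a) == min(a) || max(b) == min(b))
    stop("monomorphic in sample: constant dosage vector (should have been filtered upstream)")
  stats::cor(a, b)^2
}

#' Pairwise r-squared matrix of one sample
#'
#' Entry (i, j) is [genotypeR2()] of dosage columns i and j, computed in
#' one vectorized correlation of the whole dosage matrix; the diagonal is
#' set to 1 by convention.
#'
#' @param sample Dosage matrix (individuals x loci), all columns
#'   polymorphic.
#' @return Symmetric L' x L' matrix with unit diagonal.
#' @export
r2Matrix <- function(sample) {
  rng <- apply(sample, 2L, function(col) max(col) - min(col))
  if (any(rng == 0))
    stop("monomorphic in sample: locus column(s) ",
         paste(which(rng == 0), collapse = ", "),
         " are constant (should have been filtered upstream)")
  r <- stats::cor(sample)
  r2 <- r * r
  diag(r2) <- 1
  r2
}

#' Stack per-replicate r-squared matrices into an array
#'
#' @param reps A [ReplicateSet-class] whose replicates share one locus set.
#' @return An [R2ReplicateArray-class] with dims (L', L', n_rep).
#' @export
buildR2Array <- function(reps) {
  l <- nLoci(reps)
  n <- nReplicates(reps)
  vals <- vapply(reps@samples, r2Matrix, matrix(0, l, l))
  dim(vals) <- c(l, l, n)
  repIds <- paste0("rep", seq_len(n))
  dimnames(vals) <- list(reps@locusIds, reps@locusIds, repIds)
  new("R2ReplicateArray", values = vals, locusIds = reps@locusIds,
      replicateIds = repIds)
}
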