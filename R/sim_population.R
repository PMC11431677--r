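#' Create a simulation configuration
#'
#' @param ne Effective (= census) parent count per generation; an integer
#'   \code{>= 2}, or \code{Inf} for the infinite-population reference mode.
#' @param s Offspring sample size per replicate (default 50).
#' @param l Nominal locus count (default 25).
#' @param generations Burn-in generations (default 6).
#' @param nRep Replicate samples resampled from the final generation
#'   (default 50).
#' @param filterScope Monomorphic-filter scope; see [SimConfig-class].
#' @param p Parametric reference-allele frequency for the infinite-Ne mode
#'   (default 0.5, the frequency implied by the all-heterozygote start).
#' @param seed Optional integer seed recorded with the configuration.
#' @return A [SimConfig-class].
#' @examples
#' simConfig(ne = 10, s = 50, l = 25)
#' simConfig(ne = Inf, s = 100, l = 200)
#' @export
simConfig <- function(ne, s = 50L, l = 25L, generations = 6L, nRep = 50L,
                      filterScope = c("any_replicate", "pool_only"),
                      p = 0.5, seed = NA_integer_) {
  filterScope <- match.arg(filterScope)
  new("SimConfig", ne = as.numeric(ne), s = as.integer(s), l = as.integer(l),
      generations = as.integer(generations), nRep = as.integer(nRep),
      filterScope = filterScope, p = p, seed = as.integer(seed))
}

#' Is a configuration in infinite-Ne mode?
#'
#' @param config A [SimConfig-class].
#' @return Logical.
#' @export
isInfiniteNe <- function(config) is.infinite(config@ne)

locusNames <- function(l) paste0("L", seq_len(l))

#' Initialize the founder population
#'
#' Every founder is heterozygous at every biallelic locus, so every locus
#' starts at reference-allele frequency exactly 0.5 with maximal
#' heterozygosity and no linkage disequilibrium.
#'
#' @param config A finite-Ne [SimConfig-class].
#' @return An Ne x L integer dosage matrix of 1s, columns named by locus.
#' @export
initPopulation <- function(config) {
  if (isInfiniteNe(config))
    stop("infinite-Ne configuration: use hweSample() instead of initPopulation()")
  matrix(1L, nrow = config@ne, ncol = config@l,
         dimnames = list(NULL, locusNames(config@l)))
}

# Each parent transmits one of its two alleles per locus: a heterozygote
# (dosage 1) transmits the reference allele with probability 1/2,
# homozygotes deterministically. Loci are unlinked, so transmissions are
# independent across loci.
transmitGametes <- function(parentDosages) {
  g <- matrix(stats::rbinom(length(parentDosages), 1L, parentDosages / 2),
              nrow = nrow(parentDosages),
              dimnames = dimnames(parentDosages))
  storage.mode(g) <- "integer"
  g
}

#' Advance the population one generation
#'
#' Produces \code{nrow(parents)} offspring. For each offspring, two parents
#' are drawn uniformly at random with replacement from the current pool
#' (monoecious random mating; selfing occurs with probability 1/Ne), and
#' each parent transmits one allele per locus by Mendelian segregation,
#' independently across unlinked loci.
#'
#' @param parents Integer dosage matrix (individuals x loci).
#' @return Offspring dosage matrix of the same shape.
#' @export
advanceGeneration <- function(parents) {
  if (!is.matrix(parents) || nrow(parents) < 1L)
    stop("'parents' must be a non-empty dosage matrix")
  ne <- nrow(parents)
  p1 <- sample.int(ne, ne, replace = TRUE)
  p2 <- sample.int(ne, ne, replace = TRUE)
  off <- transmitGametes(parents[p1, , drop = FALSE]) +
    transmitGametes(parents[p2, , drop = FALSE])
  storage.mode(off) <- "integer"
  off
}

#' Run the burn-in and return the final-generation pool
#'
#' Initializes the all-heterozygote founder population and advances it
#' \code{generations} times. The burn-in lets random mating and drift
#' establish the equilibrium level of linkage disequilibrium for unlinked
#' loci before offspring are sampled.
#'
#' @param config A finite-Ne [SimConfig-class].
#' @return The Ne x L dosage matrix of the final generation.
#' @export
runBurnIn <- function(config) {
  pool <- initPopulation(config)
  for (g in seq_len(config@generations)) pool <- advanceGeneration(pool)
  pool
}

#' Draw a Hardy--Weinberg sample (infinite-Ne reference)
#'
#' Skips the pedigree entirely: each genotype dosage is drawn independently
#' as Binomial(2, p) at the parametric allele frequency, so single-locus
#' genotypes are in Hardy--Weinberg proportions and any linkage
#' disequilibrium among the unlinked loci is pure finite-sample noise.
#'
#' @param config An infinite-Ne [SimConfig-class].
#' @return An S x L integer dosage matrix.
#' @export
hweSample <- function(config) {
  if (!isInfiniteNe(config))
    stop("finite-Ne configuration: use runBurnIn() instead of hweSample()")
  m <- matrix(stats::rbinom(config@s * config@l, 2L, config@p),
              nrow = config@s, ncol = config@l,
              dimnames = list(NULL, locusNames(config@l)))
  storage.mode(m) <- "integer"
  m
}

#' Resample replicate offspring samples
#'
#' Finite Ne: draws \code{nRep} samples of S individuals each, with
#' replacement, from the final-generation pool (rows may repeat and S may
#' exceed Ne). Resampling one shared pool is what preserves the
#' inter-locus-pair dependence that the downstream covariance measures.
#' Infinite Ne: each replicate is a fresh Hardy--Weinberg draw.
#' The monomorphic filter is applied afterwards (see
#' [filterMonomorphic()]) so all replicates share one locus set.
#'
#' @param config A [SimConfig-class].
#' @param pool Final-generation dosage matrix (required for finite Ne;
#'   computed via [runBurnIn()] if omitted).
#' @param filter Apply [filterMonomorphic()] before returning (default TRUE).
#' @return A [ReplicateSet-class].
#' @export
sampleReplicates <- function(config, pool = NULL, filter = TRUE) {
  if (isInfiniteNe(config)) {
    smp <- lapply(seq_len(config@nRep), function(k) hweSample(config))
    pool <- NULL
  } else {
    if (is.null(pool)) pool <- runBurnIn(config)
    if (!is.matrix(pool) || nrow(pool) < 1L) stop("empty parent pool")
    smp <- lapply(seq_len(config@nRep), function(k) {
      pool[sample.int(nrow(pool), config@s, replace = TRUE), , drop = FALSE]
    })
  }
  reps <- new("ReplicateSet", samples = smp,
              locusIds = colnames(smp[[1]]), pool = pool, config = config)
  if (filter) filterMonomorphic(reps) else reps
}

#' Remove monomorphic loci
#'
#' With scope \code{"any_replicate"} (the default), a locus is removed when
#' its dosage column is constant in any replicate sample, so the retained
#' locus set -- and hence the pair index -- is identical across replicates,
#' which a well-defined D x D pair covariance requires. With
#' \code{"pool_only"}, only loci monomorphic in the final-generation pool
#' are removed (infinite-Ne sets have no pool and always use the
#' any-replicate rule).
#'
#' @param reps A [ReplicateSet-class].
#' @param scope Filter scope; defaults to the configuration's.
#' @return The filtered [ReplicateSet-class]; retained locus count is
#'   \code{nLoci()} of the result.
#' @export
filterMonomorphic <- function(reps, scope = reps@config@filterScope) {
  constantCols <- function(m) {
    apply(m, 2L, function(col) max(col) == min(col))
  }
  if (scope == "pool_only" && !is.null(reps@pool)) {
    drop <- constantCols(reps@pool)
  } else {
    drop <- Reduce(`|`, lapply(reps@samples, constantCols))
  }
  if (!any(drop)) return(reps)
  keep <- !drop
  if (sum(keep) < 2L)
    stop("fewer than 2 polymorphic loci retained; dataset degenerate, resimulate")
  new("ReplicateSet",
      samples = lapply(reps@samples, function(m) m[, keep, drop = FALSE]),
      locusIds = reps@locusIds[keep],
      pool = if (is.null(reps@pool)) NULL else
        reps@pool[, keep, drop = FALSE],
      config = reps@config)
}
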