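#' Top eigenvalues of the pair covariance or correlation
#'
#' Computes the \code{kMax} largest eigenvalues of Sigma (or of the
#' correlation matrix R when \code{useCorr = TRUE}). When the number of
#' retained pairs D exceeds the replicate count, the D x D matrix is never
#' formed: its nonzero eigenvalues equal those of the n_rep x n_rep Gram
#' (inner-product) matrix of the centered (and, for R, row-standardized)
#' observations, which is eigendecomposed densely. For D <= n_rep the
#' D x D matrix is decomposed directly. Both routes agree to within
#' numerical tolerance.
#'
#' \code{np} counts eigenvalues exceeding \code{threshold * lambda_max}: a
#' relative cutoff, because the r-squared covariances are O(1e-3) and an
#' absolute cutoff would discard genuine signal.
#'
#' @param cov A [PairCovariance-class].
#' @param kMax Number of eigenvalues to retain (default 500; the rank bound
#'   min(D, n_rep - 1) usually binds first).
#' @param useCorr Spectrum of R (TRUE, default) or Sigma (FALSE).
#' @param threshold Relative positivity tolerance (default 1e-10).
#' @return An [EigenSpectrum-class].
#' @export
topEigenvalues <- function(cov, kMax = 500L, useCorr = TRUE,
                           threshold = 1e-10) {
  kMax <- as.integer(kMax)
  if (is.na(kMax) || kMax < 1L) stop("'kMax' must be >= 1")
  y <- if (useCorr) cov@centered / cov@rowSd else cov@centered
  d <- nrow(y)
  n <- cov@nObs
  ev <- if (d > n) {
    eigen(crossprod(y) / cov@divisor, symmetric = TRUE, only.values = TRUE)$values
  } else {
    eigen(tcrossprod(y) / cov@divisor, symmetric = TRUE, only.values = TRUE)$values
  }
  lmax <- ev[1]
  np <- if (lmax <= 0) 0L else sum(ev > threshold * lmax)
  k <- min(kMax, length(ev))
  np <- min(as.integer(np), k)
  new("EigenSpectrum", values = ev[seq_len(k)], np = np, kMax = kMax,
      threshold = threshold, dim = as.integer(d), useCorr = useCorr)
}

#' Pseudo-log-determinant
#'
#' Sum of the logarithms of the np positive eigenvalues -- the
#' log-determinant of the matrix restricted to its nondegenerate subspace
#' (equal to the ordinary log-determinant at full rank).
#'
#' @param spec An [EigenSpectrum-class] with np >= 1.
#' @return Scalar, nats.
#' @export
pseudoLogdet <- function(spec) {
  if (spec@np < 1L) stop("no positive eigenvalues: pseudo-log-determinant undefined")
  sum(log(spec@values[seq_len(spec@np)]))
}

#' Canonical Gaussian total correlation
#'
#' Total correlation (multiinformation) is the sum of marginal entropies
#' minus the joint entropy; it is zero iff the variables are independent
#' and measures the information shared within the set -- here, the
#' pseudoreplication among locus-pair r-squared values. For a multivariate
#' Gaussian it reduces to -1/2 ln|R| with R the correlation matrix, so the
#' estimate is -1/2 the sum of log eigenvalues of R; with a truncated
#' spectrum the sum runs over the np retained eigenvalues and the
#' truncation is reported via the \code{"truncated"} attribute.
#'
#' @param spec An [EigenSpectrum-class] of the correlation matrix R.
#' @return Scalar, nats, with attribute \code{truncated} (logical).
#' @export
totalCorrelationCanonical <- function(spec) {
  if (!spec@useCorr)
    warning("canonical total correlation is defined on the correlation matrix; ",
            "got a Sigma spectrum")
  val <- -0.5 * pseudoLogdet(spec)
  attr(val, "truncated") <- spec@np < spec@dim
  val
}

#' Truncated-spectrum total-correlation estimator (all labeled variants)
#'
#' The truncated estimator multiplies a base statistic of the retained
#' eigenvalues by (1 - np / D_eff). Both readings of each ambiguous piece
#' are computed and labeled: base is either the sum of retained eigenvalues
#' (\code{"sum_eigen"}) or the pseudo-log-determinant
#' (\code{"pseudo_logdet"}); D_eff is either the matrix dimension
#' (\code{"matrix_dim"}, default -- with 50 replicates np can exceed the
#' locus count, which would make the factor negative) or the nominal locus
#' count (\code{"locus_count"}). A non-positive factor is flagged via the
#' \code{"flagged"} attribute, never silently dropped.
#'
#' @param spec An [EigenSpectrum-class] (of R under the default pipeline).
#' @param base Base statistic; see Details.
#' @param dEff Effective-dimension reading; see Details.
#' @param nLoci Retained locus count (required for
#'   \code{dEff = "locus_count"}).
#' @return Scalar with attribute \code{flagged} (logical).
#' @examples
#' # arithmetic of the formula: sum(lambda) = 45, np = 10, D = 45 -> 35
#' sp <- new("EigenSpectrum", values = rep(4.5, 10), np = 10L, kMax = 500L,
#'           threshold = 1e-10, dim = 45L, useCorr = TRUE)
#' totalCorrelationTruncated(sp) # 45 * (1 - 10/45) = 35
#' @export
totalCorrelationTruncated <- function(spec,
                                  base = c("sum_eigen", "pseudo_logdet"),
                                  dEff = c("matrix_dim", "locus_count"),
                                  nLoci = NULL) {
  base <- match.arg(base)
  dEff <- match.arg(dEff)
  if (spec@np < 1L) stop("no positive eigenvalues")
  b <- if (base == "sum_eigen") sum(spec@values[seq_len(spec@np)]) else
    pseudoLogdet(spec)
  de <- if (dEff == "matrix_dim") spec@dim else {
    if (is.null(nLoci)) stop("'nLoci' required for dEff = \"locus_count\"")
    as.integer(nLoci)
  }
  fac <- 1 - spec@np / de
  val <- b * fac
  attr(val, "flagged") <- fac <= 0
  if (fac <= 0)
    warning("(1 - np/D_eff) = ", format(fac), " is non-positive (np = ",
            spec@np, ", D_eff = ", de, "): estimator flagged")
  val
}

#' Multivariate Gaussian differential entropy from a spectrum
#'
#' H = (d/2)(1 + ln 2 pi) + 1/2 sum_{i<=np} ln lambda_i, the entropy of a
#' Gaussian restricted to the nondegenerate subspace spanned by the
#' positive-eigenvalue directions; \code{d} defaults to np, so a
#' rank-deficient covariance is treated as a full-rank distribution on its
#' support. Computed from Sigma it is scale-dependent; from R it is
#' scale-invariant.
#'
#' @param spec An [EigenSpectrum-class] with np >= 1.
#' @param d Dimension used in the constant term (default \code{spec@np}).
#' @return Scalar, nats.
#' @examples
#' # identity covariance in 3 dimensions: (3/2)(1 + ln 2*pi)
#' sp <- new("EigenSpectrum", values = c(1, 1, 1), np = 3L, kMax = 500L,
#'           threshold = 1e-10, dim = 3L, useCorr = FALSE)
#' gaussianEntropy(sp)
#' @export
gaussianEntropy <- function(spec, d = spec@np) {
  (d / 2) * (1 + log(2 * pi)) + 0.5 * pseudoLogdet(spec)
}

#' Ratio of finite-Ne to infinite-Ne total correlation
#'
#' Scales a finite-Ne dataset's total correlation by that of a matched
#' infinite-Ne configuration (same L, S, replicate count), isolating the
#' drift-driven component of inter-pair dependence.
#'
#' @param tcFinite,tcInfinite Scalars; \code{tcInfinite} must be nonzero.
#' @return \code{tcFinite / tcInfinite}.
#' @export
tcRatio <- function(tcFinite, tcInfinite) {
  if (!is.finite(tcInfinite) || tcInfinite == 0)
    stop("infinite-Ne total correlation must be finite and nonzero")
  as.numeric(tcFinite) / as.numeric(tcInfinite)
}

#' Full entropy summary of a pair covariance
#'
#' Computes the truncated spectra of both Sigma and R and derives every
#' entropy statistic: canonical total correlation (from R), the default
#' truncated estimator and its three labeled alternates, Gaussian entropies
#' H(Sigma) and H(R) on their supports, and the pseudo-log-determinant of
#' Sigma.
#'
#' @param cov A [PairCovariance-class].
#' @param lRetained Retained locus count (for the locus-count variants and
#'   bookkeeping).
#' @param kMax,threshold Passed to [topEigenvalues()].
#' @return An [EntropySummary-class].
#' @export
entropySummary <- function(cov, lRetained = nLoci(cov@index), kMax = 500L,
                           threshold = 1e-10) {
  specR <- topEigenvalues(cov, kMax = kMax, useCorr = TRUE, threshold = threshold)
  specS <- topEigenvalues(cov, kMax = kMax, useCorr = FALSE, threshold = threshold)
  variants <- c(
    sum_eigen.matrix_dim = 0, sum_eigen.locus_count = 0,
    pseudo_logdet.matrix_dim = 0, pseudo_logdet.locus_count = 0
  )
  flagged <- FALSE
  for (b in c("sum_eigen", "pseudo_logdet")) {
    for (de in c("matrix_dim", "locus_count")) {
      v <- withCallingHandlers(
        totalCorrelationTruncated(specR, base = b, dEff = de, nLoci = lRetained),
        warning = function(w) invokeRestart("muffleWarning")
      )
      variants[paste(b, de, sep = ".")] <- as.numeric(v)
      flagged <- flagged || isTRUE(attr(v, "flagged"))
    }
  }
  new("EntropySummary",
      tcCanonical = as.numeric(totalCorrelationCanonical(specR)),
      tcTruncated = variants[["sum_eigen.matrix_dim"]],
      tcVariants = variants,
      hSigma = gaussianEntropy(specS),
      hCorr = gaussianEntropy(specR),
      logdet = pseudoLogdet(specS),
      np = specR@np, npSigma = specS@np,
      d = specR@dim, lRetained = as.integer(lRetained),
      droppedPairs = cov@droppedPairs,
      flagged = flagged)
}
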