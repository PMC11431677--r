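specFromValues <- function(vals, np = length(vals), dim = length(vals),
                           useCorr = TRUE) {
  new("EigenSpectrum", values = as.numeric(vals), np = as.integer(np),
      kMax = 500L, threshold = 1e-10, dim = as.integer(dim),
      useCorr = useCorr)
}

test_that("Gram-matrix route equals the dense eigendecomposition", {
  set.seed(20)
  # wide case D > n: spectrum must come from the n x n Gram matrix
  x <- randomObsMatrix(28, 8)
  cov <- pairCovariance(asPairObs(x))
  sp <- topEigenvalues(cov, kMax = 28, useCorr = FALSE)
  dense <- eigen(stats::cov(t(x)), symmetric = TRUE, only.values = TRUE)$values
  k <- nPositive(sp)
  expect_lte(k, 7L) # rank bound n - 1
  expect_equal(eigenValues(sp)[1:k], dense[1:k], tolerance = 1e-8)
  # tall case D < n: dense route
  x2 <- randomObsMatrix(5, 40)
  sp2 <- topEigenvalues(pairCovariance(asPairObs(x2)), kMax = 5, useCorr = FALSE)
  dense2 <- eigen(stats::cov(t(x2)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(eigenValues(sp2), dense2, tolerance = 1e-8)
  expect_equal(nPositive(sp2), 5L)
  # correlation-matrix spectrum against dense cov2cor oracle
  sp3 <- topEigenvalues(pairCovariance(asPairObs(x2)), kMax = 5, useCorr = TRUE)
  dense3 <- eigen(stats::cov2cor(stats::cov(t(x2))), symmetric = TRUE,
                  only.values = TRUE)$values
  expect_equal(eigenValues(sp3), dense3, tolerance = 1e-8)
  expect_error(topEigenvalues(cov, kMax = 0), "kMax")
})

test_that("truncation is consistent for full-rank matrices within kMax", {
  set.seed(21)
  x <- randomObsMatrix(6, 60)
  cov <- pairCovariance(asPairObs(x))
  spFull <- topEigenvalues(cov, kMax = 6)
  spBig <- topEigenvalues(cov, kMax = 500)
  expect_equal(eigenValues(spFull), eigenValues(spBig)[1:6], tolerance = 1e-9)
  expect_equal(nPositive(spFull), 6L)
})

test_that("pseudo-log-determinant follows its closed forms and determinant oracle", {
  expect_equal(pseudoLogdet(specFromValues(c(1, 1, 1))), 0)
  expect_equal(pseudoLogdet(specFromValues(c(exp(2), exp(1)))), 3)
  set.seed(22)
  x <- randomObsMatrix(6, 40)
  sp <- topEigenvalues(pairCovariance(asPairObs(x)), useCorr = FALSE)
  expect_equal(pseudoLogdet(sp),
               as.numeric(determinant(stats::cov(t(x)), logarithm = TRUE)$modulus),
               tolerance = 1e-8)
  expect_error(pseudoLogdet(specFromValues(1, np = 0)), "undefined")
})

test_that("canonical total correlation: identity, bivariate closed form, monotonicity", {
  expect_equal(as.numeric(totalCorrelationCanonical(specFromValues(rep(1, 5)))), 0)
  # bivariate rho = 0.6: eigenvalues of R are 1 +/- rho
  rho <- 0.6
  tc <- totalCorrelationCanonical(specFromValues(c(1 + rho, 1 - rho)))
  expect_equal(as.numeric(tc), -0.5 * log(1 - rho^2), tolerance = 1e-12)
  expect_equal(as.numeric(tc), 0.22314355, tolerance = 1e-7)
  # and it equals the marginal-minus-joint entropy oracle
  expect_equal(as.numeric(tc),
               oracleTotalCorrelation(matrix(c(1, rho, rho, 1), 2)),
               tolerance = 1e-9)
  tcs <- vapply(c(0.1, 0.5, 0.9, 0.99), function(r) {
    as.numeric(totalCorrelationCanonical(specFromValues(c(1 + r, 1 - r))))
  }, numeric(1))
  expect_true(all(diff(tcs) > 0))
})

test_that("eigenvalue and definitional routes to total correlation agree (full rank)", {
  set.seed(23)
  for (d in c(3, 5, 8)) {
    x <- randomObsMatrix(d, 80, scale = stats::runif(1, 0.5, 2))
    cov <- pairCovariance(asPairObs(x))
    sp <- topEigenvalues(cov, kMax = d, useCorr = TRUE)
    tcEigen <- as.numeric(totalCorrelationCanonical(sp))
    tcDef <- oracleTotalCorrelation(stats::cov(t(x)))
    expect_equal(tcEigen, tcDef, tolerance = 1e-9)
    expect_gte(tcEigen, 0)
  }
})

test_that("canonical TC is scale-invariant while H(Sigma) shifts by sum(log c)", {
  set.seed(24)
  x <- randomObsMatrix(5, 50)
  cvs <- c(3, 1, 0.2, 1, 10)
  covA <- pairCovariance(asPairObs(x))
  covB <- pairCovariance(asPairObs(x * cvs))
  tcA <- as.numeric(totalCorrelationCanonical(topEigenvalues(covA)))
  tcB <- as.numeric(totalCorrelationCanonical(topEigenvalues(covB)))
  expect_equal(tcA, tcB, tolerance = 1e-9)
  hA <- gaussianEntropy(topEigenvalues(covA, useCorr = FALSE))
  hB <- gaussianEntropy(topEigenvalues(covB, useCorr = FALSE))
  expect_equal(hB - hA, sum(log(cvs)), tolerance = 1e-9)
})

test_that("truncated estimator computes all labeled variants and flags bad factors", {
  sp <- specFromValues(rep(4.5, 10), np = 10, dim = 45)
  expect_equal(as.numeric(totalCorrelationTruncated(sp)), 35) # 45 (1 - 10/45)
  expect_equal(as.numeric(totalCorrelationTruncated(sp, base = "pseudo_logdet")),
               10 * log(4.5) * (1 - 10 / 45))
  v <- suppressWarnings(
    totalCorrelationTruncated(sp, dEff = "locus_count", nLoci = 5))
  expect_true(attr(v, "flagged"))
  expect_warning(totalCorrelationTruncated(sp, dEff = "locus_count", nLoci = 5),
                 "non-positive")
  expect_error(totalCorrelationTruncated(sp, dEff = "locus_count"), "nLoci")
  # full-rank identity R with pseudo-logdet base: 0 x 0 factor = 0
  spI <- specFromValues(rep(1, 6))
  # full rank makes the factor 0 (and flags it); the value is still 0
  expect_equal(as.numeric(suppressWarnings(
    totalCorrelationTruncated(spI, base = "pseudo_logdet"))), 0)
})

test_that("Gaussian entropy matches its closed forms", {
  expect_equal(gaussianEntropy(specFromValues(c(1, 1, 1), useCorr = FALSE)),
               (3 / 2) * (1 + log(2 * pi)), tolerance = 1e-12)
  expect_equal(gaussianEntropy(specFromValues(c(1, 1, 1), useCorr = FALSE)),
               4.2568156, tolerance = 1e-6)
  v <- 0.37
  expect_equal(gaussianEntropy(specFromValues(v, useCorr = FALSE)),
               0.5 * log(2 * pi * exp(1) * v), tolerance = 1e-12)
})

test_that("TC ratio is a guarded quotient", {
  expect_equal(tcRatio(3.2, 3.2), 1.0)
  expect_equal(tcRatio(1.9, 2.0), 0.95)
  expect_error(tcRatio(1, 0), "nonzero")
})

test_that("the pipeline entropy summary has coherent fields and a negative H(Sigma)", {
  set.seed(25)
  res <- datasetEntropy(simConfig(ne = 20, s = 50, l = 15, nRep = 50), seed = 99)
  es <- res$summary
  expect_s4_class(es, "EntropySummary")
  expect_lte(es@np, 49L)
  expect_equal(es@d + es@droppedPairs,
               es@lRetained * (es@lRetained - 1L) / 2L)
  # the r-squared covariances are tiny, so the support-dimension Gaussian
  # entropy of Sigma is negative in this regime
  expect_lt(es@hSigma, 0)
  expect_gt(es@hCorr, 0)
  # default variant is sum-eigen x matrix-dim
  expect_equal(es@tcTruncated, es@tcVariants[["sum_eigen.matrix_dim"]])
  df <- as.data.frame(es)
  expect_equal(df$tc, es@tcTruncated)
  expect_equal(df$np, es@np)
})
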