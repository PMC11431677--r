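# Independent, definitional oracles used across the suite. These
# deliberately avoid the package's own code paths (explicit loops and
# closed forms instead of vectorized pipelines).

# Pearson correlation squared, written out from the definition.
oraclePearsonR2 <- function(a, b) {
  da <- a - mean(a)
  db <- b - mean(b)
  (sum(da * db))^2 / (sum(da * da) * sum(db * db))
}

# Per-pair looped r-squared matrix.
oracleR2Matrix <- function(x) {
  l <- ncol(x)
  out <- diag(nrow = l)
  for (i in seq_len(l - 1)) {
    for (j in (i + 1):l) {
      out[i, j] <- out[j, i] <- oraclePearsonR2(x[, i], x[, j])
    }
  }
  out
}

# Definitional unbiased covariance of rows of x (D x n) across columns.
oracleRowCovariance <- function(x) {
  d <- nrow(x)
  n <- ncol(x)
  out <- matrix(0, d, d)
  for (i in seq_len(d)) {
    for (j in seq_len(d)) {
      out[i, j] <- sum((x[i, ] - mean(x[i, ])) * (x[j, ] - mean(x[j, ]))) / (n - 1)
    }
  }
  out
}

# Brute-force enumeration of pairs sharing a locus with (i, j).
oracleSharingCount <- function(l, i, j) {
  cnt <- 0L
  for (a in seq_len(l - 1)) {
    for (b in (a + 1):l) {
      if (a == i && b == j) next
      if (a %in% c(i, j) || b %in% c(i, j)) cnt <- cnt + 1L
    }
  }
  cnt
}

# Gaussian total correlation from the definition: sum of marginal
# entropies minus joint entropy, both via the multivariate-normal
# closed forms on the dense covariance matrix.
oracleTotalCorrelation <- function(sigma) {
  d <- nrow(sigma)
  hJoint <- (d / 2) * (1 + log(2 * pi)) +
    0.5 * determinant(sigma, logarithm = TRUE)$modulus
  hMarg <- sum(0.5 * log(2 * pi * exp(1) * diag(sigma)))
  as.numeric(hMarg - hJoint)
}

# Random full-rank correlation matrix of dimension d (via ample samples).
randomObsMatrix <- function(d, n, scale = 1) {
  matrix(stats::rnorm(d * n, sd = scale), nrow = d, ncol = n)
}

# Wrap a raw D x n observation matrix into the package's pair pipeline
# classes. The attached index is the smallest one with at least D pairs;
# downstream covariance/spectrum code only consumes the values.
asPairObs <- function(x) {
  l <- 2L
  while (l * (l - 1L) / 2L < nrow(x)) l <- l + 1L
  new("PairObservationMatrix", values = x, index = makePairIndex(l),
      replicateIds = paste0("rep", seq_len(ncol(x))))
}

# Exact Wright-Fisher fixation probability: 2N allele copies, binomial
# resampling, starting frequency p0, t generations.
oracleFixationProb <- function(ne, t, p0 = 0.5) {
  n2 <- 2L * ne
  v <- rep(0, n2 + 1)
  v[round(p0 * n2) + 1] <- 1
  P <- outer(0:n2, 0:n2, function(j, i) stats::dbinom(j, n2, i / n2))
  for (g in seq_len(t)) v <- as.vector(P %*% v)
  v[1] + v[n2 + 1]
}
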