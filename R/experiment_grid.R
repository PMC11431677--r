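#' Default sensitivity-grid levels
#'
#' The factorial design spans two orders of magnitude of effective
#' population size, an eightfold range of locus counts and a twofold range
#' of offspring sample sizes, with a 6-generation burn-in and 50 replicate
#' samples per dataset; an infinite-Ne reference is run for every (S, L)
#' cell.
#'
#' @return List with numeric vectors \code{ne}, \code{s}, \code{l}.
#' @export
gridLevels <- function() {
  list(ne = c(10, 20, 40, 80, 160, 640, 1280),
       s = c(50, 100),
       l = c(25, 50, 100, 200))
}

#' Run the sensitivity grid
#'
#' Simulates \code{datasetsPerCell} independent datasets (fresh pedigree
#' each) for every finite (Ne, S, L) cell and for the infinite-Ne reference
#' at every (S, L), computing the full entropy summary per dataset. Each
#' finite record gets a \code{tcRatio}: its default total correlation over
#' the mean of the matching infinite-Ne cell. Per-dataset seeds are drawn
#' once from the root seed in a fixed cell order, so a rerun with the same
#' root seed is bit-identical. A failing dataset is recorded with its error
#' message and the run continues.
#'
#' @param levels Grid levels as from [gridLevels()].
#' @param datasetsPerCell Independent datasets per cell (default 10).
#' @param generations,nRep Simulation protocol (defaults 6 and 50).
#' @param rootSeed Integer root seed (default 1).
#' @param kMax,threshold Passed to [topEigenvalues()].
#' @param verbose Print one line per cell.
#' @return Data frame, one row per dataset: design columns (\code{ne} =
#'   Inf for the reference cells), \code{datasetId}, \code{seed}, every
#'   [EntropySummary-class] statistic, \code{tcRatio} (finite rows only)
#'   and \code{error}.
#' @export
runGrid <- function(levels = gridLevels(), datasetsPerCell = 10L,
                    generations = 6L, nRep = 50L, rootSeed = 1L,
                    kMax = 500L, threshold = 1e-10, verbose = FALSE) {
  stopifnot(length(levels$ne) > 0, length(levels$s) > 0, length(levels$l) > 0,
            !anyNA(levels$ne), !anyNA(levels$s), !anyNA(levels$l))
  cells <- rbind(
    expand.grid(ne = Inf, s = levels$s, l = levels$l),
    expand.grid(ne = levels$ne, s = levels$s, l = levels$l)
  )
  nDatasets <- nrow(cells) * datasetsPerCell
  set.seed(as.integer(rootSeed))
  seeds <- sample.int(2147483646L, nDatasets)
  rows <- vector("list", nDatasets)
  k <- 0L
  for (c_i in seq_len(nrow(cells))) {
    ne <- cells$ne[c_i]; s <- cells$s[c_i]; l <- cells$l[c_i]
    if (verbose)
      message(sprintf("cell %d/%d: Ne=%s S=%d L=%d", c_i, nrow(cells),
                      if (is.infinite(ne)) "inf" else ne, s, l))
    for (d_i in seq_len(datasetsPerCell)) {
      k <- k + 1L
      cfg <- simConfig(ne = ne, s = s, l = l, generations = generations,
                       nRep = nRep)
      res <- tryCatch(
        datasetEntropy(cfg, seed = seeds[k], kMax = kMax,
                       threshold = threshold),
        error = function(e) e
      )
      base <- data.frame(ne = ne, s = s, lNominal = l, datasetId = d_i,
                         seed = seeds[k])
      rows[[k]] <- if (inherits(res, "error")) {
        cbind(base,
              as.data.frame(emptySummaryRow()),
              error = conditionMessage(res))
      } else {
        cbind(base, as.data.frame(res$summary), error = NA_character_)
      }
    }
  }
  records <- do.call(rbind, rows)
  records$tcRatio <- NA_real_
  inf <- is.infinite(records$ne) & is.na(records$error)
  for (s in levels$s) {
    for (l in levels$l) {
      ref <- records$tc[inf & records$s == s & records$lNominal == l]
      if (!length(ref)) next
      refMean <- mean(ref)
      # a full-rank R (D <= n_rep - 1) zeroes the truncated estimator;
      # the ratio is undefined there and stays NA
      if (!is.finite(refMean) || refMean == 0) next
      sel <- !is.infinite(records$ne) & records$s == s &
        records$lNominal == l & is.na(records$error)
      records$tcRatio[sel] <- records$tc[sel] / refMean
    }
  }
  records
}

emptySummaryRow <- function() {
  data.frame(d = NA_integer_, lRetained = NA_integer_,
             droppedPairs = NA_integer_, np = NA_integer_,
             npSigma = NA_integer_, tc = NA_real_, tcCanonical = NA_real_,
             tcSumEigenLocus = NA_real_, tcLogdetMatrix = NA_real_,
             tcLogdetLocus = NA_real_, hSigma = NA_real_, hCorr = NA_real_,
             logdet = NA_real_, flagged = NA)
}

finiteRecords <- function(records) {
  records[!is.infinite(records$ne) & is.na(records$error), , drop = FALSE]
}

#' Ordinary-least-squares model of an entropy statistic
#'
#' Fits log(response) on log(L), log(Ne), log(S) (natural logs) over the
#' finite-Ne records, optionally with all pairwise interactions. For the
#' total-correlation response the default truncated estimator (\code{tc}
#' column) is used; for the Gaussian-entropy response, H(Sigma) is negative
#' in the regime of interest, so the response is log(-H) and records with
#' non-negative H are excluded with a message and counted in
#' \code{nDropped}. Infinite-Ne records never enter (log Ne undefined);
#' they feed only the ratio analysis.
#'
#' @param records Grid data frame from [runGrid()].
#' @param response \code{"tc"} or \code{"h"}.
#' @param withInteractions Include pairwise interactions (default FALSE).
#' @return A [RegressionFit-class].
#' @export
fitEntropyRegressions <- function(records, response = c("tc", "h"),
                                  withInteractions = FALSE) {
  response <- match.arg(response)
  fin <- finiteRecords(records)
  y <- if (response == "tc") fin$tc else -fin$hSigma
  ok <- is.finite(y) & y > 0
  nDropped <- sum(!ok)
  if (nDropped > 0)
    message(nDropped, " record(s) with non-positive ",
            if (response == "tc") "TC" else "-H", " excluded from the fit")
  dat <- data.frame(logResp = log(y[ok]), logL = log(fin$lNominal[ok]),
                    logNe = log(fin$ne[ok]), logS = log(fin$s[ok]))
  if (nrow(dat) < 5L) stop("too few usable records to fit the model")
  form <- if (withInteractions)
    logResp ~ (logL + logNe + logS)^2 else logResp ~ logL + logNe + logS
  fit <- stats::lm(form, data = dat)
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "std.error", "t.value", "p.value")
  co <- cbind(term = rownames(co), co)
  rownames(co) <- NULL
  new("RegressionFit", coefficients = co, rSquared = sm$r.squared,
      aic = stats::AIC(fit), formula = deparse(form), response = response,
      n = nrow(dat), nDropped = as.integer(nDropped))
}

#' Rank fitted models by AIC
#'
#' @param fits List of [RegressionFit-class] objects for the same response
#'   on the same records.
#' @return Data frame ordered by AIC (ties broken by fewer parameters),
#'   with columns formula, k, aic, dAIC.
#' @export
compareModels <- function(fits) {
  stopifnot(length(fits) >= 2)
  resp <- vapply(fits, function(f) f@response, character(1))
  ns <- vapply(fits, function(f) f@n, integer(1))
  if (length(unique(resp)) != 1 || length(unique(ns)) != 1)
    stop("models must share one response fitted to the same records")
  tab <- data.frame(
    formula = vapply(fits, function(f) f@formula, character(1)),
    k = vapply(fits, function(f) nrow(f@coefficients), integer(1)),
    aic = vapply(fits, function(f) f@aic, numeric(1))
  )
  tab <- tab[order(tab$aic, tab$k), , drop = FALSE]
  tab$dAIC <- tab$aic - tab$aic[1]
  rownames(tab) <- NULL
  tab
}

#' Correlation table of entropy statistics and design factors
#'
#' Pearson correlations among the default total correlation, H(Sigma), and
#' the design factors L, Ne, S over the finite-Ne grid records. Over the
#' balanced factorial design the factor-factor correlations are exactly
#' zero. With \code{useLog = TRUE} the entropy columns enter as log(TC)
#' and log(-H) (pairwise-complete) and the factors as logs.
#'
#' @param records Grid data frame from [runGrid()].
#' @param useLog Correlate on the log scale (default FALSE, raw values).
#' @return Symmetric 5 x 5 correlation matrix (TC, H, L, Ne, S).
#' @export
correlationTable <- function(records, useLog = FALSE) {
  fin <- finiteRecords(records)
  m <- cbind(TC = fin$tc, H = fin$hSigma, L = fin$lNominal, Ne = fin$ne,
             S = fin$s)
  if (useLog) {
    m[, "TC"] <- log(m[, "TC"])
    h <- -fin$hSigma
    m[, "H"] <- ifelse(is.finite(h) & h > 0, log(h), NA_real_)
    m[, c("L", "Ne", "S")] <- log(m[, c("L", "Ne", "S")])
  }
  stats::cor(m, use = if (useLog) "pairwise.complete.obs" else "everything")
}

#' Scaling of finite-Ne total correlation against the infinite-Ne reference
#'
#' Cell means and Monte Carlo standard errors of the TC/TC-infinity ratio,
#' by (L, S, Ne).
#'
#' @param records Grid data frame from [runGrid()] (must contain
#'   \code{tcRatio}).
#' @return Data frame with columns lNominal, s, ne, n, meanRatio, seRatio.
#' @export
scalingSummary <- function(records) {
  fin <- finiteRecords(records)
  fin <- fin[is.finite(fin$tcRatio), , drop = FALSE]
  if (!nrow(fin))
    stop("no finite-Ne records with a TC ratio: was the infinite-Ne reference run?")
  agg <- do.call(rbind, lapply(
    split(fin, list(fin$lNominal, fin$s, fin$ne), drop = TRUE),
    function(g) data.frame(
      lNominal = g$lNominal[1], s = g$s[1], ne = g$ne[1], n = nrow(g),
      meanRatio = mean(g$tcRatio),
      seRatio = stats::sd(g$tcRatio) / sqrt(nrow(g))
    )
  ))
  agg <- agg[order(agg$lNominal, agg$s, agg$ne), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
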