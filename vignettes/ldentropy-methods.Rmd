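---
title: "Quantifying pseudoreplication among locus pairs with entropy statistics"
author: "ldentropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pseudoreplication among locus pairs with entropy statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldentropy)
```

## The model

`ldentropy` studies one specific source of pseudoreplication in linkage
disequilibrium (LD) analyses: *overlapping pairs of loci*. With `L` loci
there are `D = L(L-1)/2` pairwise genotypic `r²` values, but any pair
`(i, j)` shares a locus with `2(L-2)` other pairs, and sharing pairs have
positively correlated `r²`. Only `L/2` disjoint pairs are mutually
independent, so the effective degrees of freedom behind "mean `r²`" are far
below `D`. Physical linkage adds a second, separate source of dependence;
this package deliberately simulates *unlinked* loci so that whatever
dependence remains is attributable to the overlapping-pairs effect alone.

The simulator is the canonical monoecious Wright–Fisher scheme:

* `Ne` diploid parents per generation, constant census size, no mutation,
  selection or migration;
* founders heterozygous at every biallelic locus, so every locus starts at
  allele frequency exactly 0.5 with maximal heterozygosity and no LD;
* each offspring draws two parents uniformly with replacement (selfing
  probability `1/Ne`), and each parent transmits one allele per locus by
  Mendelian segregation, independently across loci (unlinked);
* a burn-in of 6 generations, enough for unlinked loci to reach their
  equilibrium level of LD under drift.

Estimating the covariance of `r²` *across* locus pairs needs repeated
observations of all `D` pairs under the same realized pedigree. A fresh
pedigree per observation would erode exactly the inter-pair dependence we
want to measure, so the package resamples: `n_rep = 50` replicate samples
of `S` individuals are drawn with replacement from the single
final-generation pool of `Ne` individuals (rows may repeat; `S` may exceed
`Ne`). We take the "pool of potential offspring" to be those `Ne`
final-generation individuals themselves — the narrowest reading; a larger
brood would dilute, but not remove, the shared-pedigree dependence.

The infinite-population reference skips the pedigree entirely: every
genotype is an independent Binomial(2, 0.5) draw, i.e. Hardy–Weinberg
proportions at the parametric frequency implied by the all-heterozygote
initialization (configurable via `p`). Any LD in such a sample is pure
finite-sample noise, making it the natural denominator for the `TC/TC∞`
ratio that isolates the drift-driven component of inter-pair dependence.

### Monomorphic filtering

Drift fixes loci; fixed loci have undefined `r²`. The filter runs after all
replicates are drawn, and by default (`filterScope = "any_replicate"`)
removes every locus that is monomorphic in *any* replicate, so all
replicates share one locus set — a requirement for a well-defined `D × D`
pair covariance. The alternative `"pool_only"` scope (only pool-fixed loci
removed) is exposed for comparison but can leave sample-level constant
columns that the `r²` step will reject by contract.

## From genotypes to the pair covariance

Per replicate, `r²` is the squared Pearson correlation between dosage
vectors — the genotypic LD measure for unphased data; no haplotype phasing
anywhere. Stacking gives an `(L', L', 50)` array; the upper triangle of
each slice, in lexicographic pair order, forms the `D × 50` observation
matrix. Row covariance `Σ` (divisor `n−1` by default; ML divisor
switchable) and correlation `R` are the "correlations of correlations".

Two numerical guards matter here:

* **Zero-variance pair rows.** A pair whose `r²` is constant across
  replicates has an undefined correlation row. At small `Ne` this happens
  systematically: with only `Ne` distinct genotypes in the pool, some locus
  pairs are perfectly collinear and their `r²` is identically 1 in every
  replicate, varying only at floating-point noise (~1e-16). Standardizing
  such a row would inflate that noise into a spurious unit-variance
  eigendirection. Rows with standard deviation below `1e-8` (absolute; `r²`
  is O(1)) are therefore dropped, with the count reported everywhere
  downstream.
* **Never materialize `Σ`.** `rank(Σ) ≤ n_rep − 1 = 49`, so all nonzero
  eigenvalues of the `D × D` matrix equal those of the `50 × 50` Gram
  matrix of (standardized) centered observations. For `D > n_rep` the
  spectrum is computed exclusively by that route; dense `Σ`/`R` are
  available (`covMatrix()`, `corrMatrix()`) only for small `D`, since
  `O(D²)` storage is precisely the method's scalability bottleneck
  (`D = 19900` already at `L = 200`). The two routes agree to 1e-8
  relative tolerance, which the test suite asserts.

## Entropy statistics and their variants

For a multivariate Gaussian the total correlation
`TC = Σᵢ H(xᵢ) − H(x)` reduces to `−½ ln |R|`; the canonical estimator is
therefore `−½ Σᵢ ln λᵢ(R)` over the `np` retained eigenvalues, flagged as
truncated whenever `np < D`. The test suite verifies the identity between
this eigenvalue route and the definitional marginal-minus-joint computation
on full-rank instances, its scale invariance, and its monotonicity in the
bivariate correlation.

The *truncated estimator* multiplies a base statistic of the retained
spectrum by `(1 − np/D_eff)`. Both of its ingredients admit two readings,
and rather than privileging one silently the package computes all four
labeled variants:

* base: sum of retained eigenvalues (default) or pseudo-log-determinant
  `Σ ln λᵢ`;
* `D_eff`: the matrix dimension `D` (default) or the locus count `L'`.

The defaults are chosen for well-definedness: with 50 replicates,
`np ≤ 49` can exceed `L'`, making the locus-count factor negative — such
cases are computed anyway and *flagged*, never hidden. With the default
reading and `D > 49` the estimator equals `trace(R)·(1 − np/D) = D − np`
(all nonzero eigenvalues of a correlation matrix sum to its dimension), so
it is dominated by the pair-count combinatorics — which is also why it
scales essentially as `L²` across the grid. When `D ≤ n_rep − 1`, `R` is
full rank and the estimator is exactly zero; the `TC/TC∞` ratio is
undefined there and reported as `NA`.

Gaussian entropy is computed on the nondegenerate support:
`H = (np/2)(1 + ln 2π) + ½ Σᵢ ln λᵢ`, from `Σ` (scale-dependent; negative
whenever the `r²` covariances are small enough, which is the regime of
interest) and from `R` (scale-invariant). Treating the rank-deficient
covariance as a full-rank distribution on its `np`-dimensional support is
the only reading under which an identity matrix of dimension 3 gives the
textbook `(3/2)(1 + ln 2π)` while the pipeline's tiny covariances give
finite, sign-stable values.

The eigenvalue positivity threshold is *relative* (`1e-10 × λmax`):
`r²` covariances are O(1e-3) and an absolute cutoff would discard genuine
signal. `kMax = 500` eigenvalues are retained by default — moot at the
default replicate count (rank ≤ 49) but meaningful for user-supplied data
with more replicates.

## The sensitivity grid and models

`runGrid()` runs the full factorial design — `Ne ∈ {10, 20, 40, 80, 160,
640, 1280}` (56 finite cells with `S ∈ {50, 100}`, `L ∈ {25, 50, 100,
200}`) plus the infinite-`Ne` reference for every `(S, L)` — with 10
independent datasets (fresh pedigrees) per cell. Ten per cell balances
Monte Carlo error of cell means against runtime (the full grid is 640
datasets and runs in about two minutes on one CPU; test tolerances are set
for this count). Per-dataset seeds are drawn once from the root seed in a
fixed cell order, so a rerun is byte-identical — asserted in the tests.

Regressions are ordinary least squares of `log(TC)` (and `log(−H)`, with
non-negative-`H` records excluded and counted) on `log(L)`, `log(Ne)`,
`log(S)`, natural logs throughout; the base affects only coefficient scale,
not `R²` or AIC ranking. Infinite-`Ne` records never enter regressions or
the correlation table (`log Ne` undefined); they feed only the ratio
analysis. The correlation table is computed on raw values by default, with
a log-scale switch — both are available because either convention is
defensible and they answer slightly different questions. Interaction models
are compared by AIC with ties broken toward fewer parameters; a
fixed-effects linear model is the only model class implemented, since
that is what the reported quantities require.

```{r grid, eval = FALSE}
records <- runGrid(rootSeed = 1)
fitEntropyRegressions(records, response = "tc")
correlationTable(records)
scalingSummary(records)
```

## What the generator does and does not emulate

The generator reproduces drift, Mendelian segregation, selfing, the
equilibrium LD of unlinked loci, and the sampling noise of finite offspring
samples. It does **not** emulate physical linkage (no chromosomes, no
recombination map — dependence from syntenic loci is out of scope by
design), mutation, migration, selection, two-sex mating, overlapping
generations, or allele-frequency spectra other than the 0.5-start. Passing
tests therefore demonstrate correct behavior for the overlapping-pairs
mechanism in an idealized population; they say nothing about linked
markers or real allele-frequency distributions, where both the magnitude
of `r²` and the dependence structure differ.

## Numerical choices and degenerate inputs

* Dosage matrices are integer 0/1/2; transmission uses the exact
  binomial representation (a parent of dosage `d` transmits the reference
  allele with probability `d/2`), which the tests check against Mendelian
  expectations and the exact fixation probabilities of the corresponding
  Markov chain.
* Fewer than two polymorphic loci after filtering aborts with a
  "degenerate dataset" error rather than producing a 0/1-pair covariance.
* All-constant observation matrices (e.g. duplicated replicates) are a
  degenerate-covariance error.
* Asymmetric `r²` slices beyond 1e-12 are rejected; vectorized and looped
  `r²` agree to 1e-12 by contract.
* Pair order is lexicographic and recorded; any consistent order yields the
  same spectrum (similarity invariance — also a test).
* Grid cells that fail are recorded with their error message and the run
  continues; the CLI writes its manifest on failure too.

## Problem sizes used in the test suite

Unit tests run on small instances (tens of loci, ≤ 50 replicates); the
statistics-level checks run the full default grid once (640 datasets,
shared across test blocks via a cached helper). Monte Carlo assertions use
3-standard-error bands at the stated sizes.

## Known limitations

* `O(D²)` dense export is refused above a few thousand pairs; the centered
  observation matrix is the scalable representation.
* The truncated estimator's default variant is trace-dominated
  (`≈ D − np`), so its `Ne` and `S` sensitivity is weak by construction;
  the canonical TC is the information-theoretically interpretable
  quantity, but is negative under heavy truncation.
* The Gaussian assumption behind both `TC` and `H` is an approximation:
  `r²` values are bounded and skewed, and no non-Gaussian entropy
  estimator is provided.
* VCF export is minimal (single pseudo-contig, GT only) and exists for
  interoperability, not to imply physical positions.
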