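Package: ldentropy
Title: Entropy-Based Quantification of Pseudoreplication in Linkage
    Disequilibrium Analyses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward-time simulation of a monoecious, randomly mating
    population of unlinked biallelic loci, replicate-resampled arrays of
    pairwise genotypic r-squared, and the covariance and correlation
    structure across all locus pairs (the "correlations of correlations").
    Truncated-eigenspectrum entropy statistics -- total correlation and
    multivariate Gaussian entropy -- quantify the pseudoreplication that
    overlapping pairs of loci introduce into linkage-disequilibrium
    analyses. Includes a sensitivity grid over effective population size,
    locus count and sample size, ordinary-least-squares models of the
    entropy statistics, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'sim_population.R'
    'ld_replicates.R'
    'pair_dependence.R'
    'entropy_metrics.R'
    'pipeline.R'
    'experiment_grid.R'
    'io.R'
    'cli.R'
    'ldentropy-package.R'
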