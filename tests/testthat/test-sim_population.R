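test_that("configuration validation enforces the simulation invariants", {
  expect_s4_class(simConfig(ne = 10), "SimConfig")
  expect_true(isInfiniteNe(simConfig(ne = Inf)))
  expect_error(simConfig(ne = 1), "ne")
  expect_error(simConfig(ne = 10, s = 1), "offspring")
  expect_error(simConfig(ne = 10, l = 1), "locus")
  expect_error(simConfig(ne = 10, generations = -1), "generations")
  expect_error(simConfig(ne = 10, nRep = 1), "nRep")
})

test_that("founders are all heterozygous with allele frequency exactly 0.5", {
  pop <- initPopulation(simConfig(ne = 4, l = 3))
  expect_identical(dim(pop), c(4L, 3L))
  expect_true(all(pop == 1L))
  pop2 <- initPopulation(simConfig(ne = 10, l = 25))
  expect_identical(dim(pop2), c(10L, 25L))
  expect_equal(unname(colMeans(pop2) / 2), rep(0.5, 25))
  expect_error(initPopulation(simConfig(ne = Inf)), "hweSample")
})

test_that("offspring of all-heterozygote parents follow Mendelian 1/4:1/2:1/4", {
  set.seed(11)
  parents <- initPopulation(simConfig(ne = 3000, l = 4))
  off <- advanceGeneration(parents)
  expect_true(all(off %in% 0:2))
  # each dosage is Binomial(2, 1/2); compare each class count to the exact
  # binomial expectation within 3 standard errors
  n <- length(off)
  pExp <- c(0.25, 0.5, 0.25)
  for (d in 0:2) {
    obs <- mean(off == d)
    se <- sqrt(pExp[d + 1] * (1 - pExp[d + 1]) / n)
    expect_lt(abs(obs - pExp[d + 1]), 3 * se)
  }
})

test_that("fixation is absorbing across generations", {
  set.seed(5)
  parents <- matrix(c(2L, 2L, 2L, 2L, 0L, 0L, 0L, 0L, 1L, 0L, 2L, 1L),
                    nrow = 4, dimnames = list(NULL, c("L1", "L2", "L3")))
  pop <- parents
  for (g in 1:5) {
    pop <- advanceGeneration(pop)
    expect_true(all(pop[, "L1"] == 2L))
    expect_true(all(pop[, "L2"] == 0L))
  }
})

test_that("generation advance and burn-in are seed-deterministic", {
  cfg <- simConfig(ne = 12, l = 8, generations = 6)
  set.seed(42); a <- runBurnIn(cfg)
  set.seed(42); b <- runBurnIn(cfg)
  expect_identical(a, b)
  set.seed(43); c <- runBurnIn(cfg)
  expect_false(identical(a, c))
  expect_identical(runBurnIn(simConfig(ne = 7, l = 5, generations = 0)),
                   initPopulation(simConfig(ne = 7, l = 5)))
})

test_that("expected heterozygosity decays as 0.5 (1 - 1/(2Ne))^t", {
  set.seed(7)
  ne <- 16; t <- 4; nPed <- 120; l <- 20
  hMeans <- replicate(nPed, {
    pool <- runBurnIn(simConfig(ne = ne, l = l, generations = t))
    p <- colMeans(pool) / 2
    mean(2 * p * (1 - p))
  })
  expected <- 0.5 * (1 - 1 / (2 * ne))^t
  se <- stats::sd(hMeans) / sqrt(nPed)
  expect_lt(abs(mean(hMeans) - expected), 3 * se)
})

test_that("large-Ne allele frequencies stay near 0.5 with binomial drift variance", {
  set.seed(8)
  cfg <- simConfig(ne = 1280, l = 200, generations = 6)
  pool <- runBurnIn(cfg)
  p <- colMeans(pool) / 2
  expect_lt(abs(mean(p) - 0.5), 0.02)
  # drift variance approx t/(8 Ne) for small t/Ne
  vExp <- 6 / (8 * 1280)
  expect_lt(var(p), 3 * vExp)
  expect_gt(var(p), vExp / 3)
})

test_that("infinite-Ne draws are Hardy-Weinberg at the parametric frequency", {
  expect_error(hweSample(simConfig(ne = 10)), "runBurnIn")
  set.seed(21)
  g <- hweSample(simConfig(ne = Inf, s = 4000, l = 3))
  n <- length(g)
  for (d in 0:2) {
    pExp <- stats::dbinom(d, 2, 0.5)
    se <- sqrt(pExp * (1 - pExp) / n)
    expect_lt(abs(mean(g == d) - pExp), 3 * se)
  }
  set.seed(33); a <- hweSample(simConfig(ne = Inf, s = 20, l = 5))
  set.seed(33); b <- hweSample(simConfig(ne = Inf, s = 20, l = 5))
  expect_identical(a, b)
})

test_that("replicates resample the pool with replacement over a shared locus set", {
  set.seed(9)
  cfg <- simConfig(ne = 10, s = 50, l = 25, nRep = 50)
  pool <- runBurnIn(cfg)
  reps <- sampleReplicates(cfg, pool = pool)
  expect_s4_class(reps, "ReplicateSet")
  expect_length(samples(reps), 50)
  expect_true(all(vapply(samples(reps), nrow, integer(1)) == 50L))
  # every replicate row is one of the <= 10 distinct pool rows
  poolKeys <- apply(reps@pool, 1, paste, collapse = "")
  for (k in c(1, 25, 50)) {
    keys <- apply(samples(reps)[[k]], 1, paste, collapse = "")
    expect_true(all(keys %in% poolKeys))
    expect_lte(length(unique(keys)), 10L)
  }
  set.seed(9); r1 <- sampleReplicates(cfg)
  set.seed(9); r2 <- sampleReplicates(cfg)
  expect_identical(r1@samples, r2@samples)
  set.seed(10); r3 <- sampleReplicates(cfg)
  expect_false(identical(r1@samples, r3@samples))
})

test_that("monomorphic filtering removes fixed loci and errors when degenerate", {
  cfg <- simConfig(ne = 4, s = 6, l = 4, nRep = 3)
  mk <- function(fixCol) {
    m <- matrix(sample(0:2, 24, replace = TRUE), nrow = 6,
                dimnames = list(NULL, paste0("L", 1:4)))
    m[, fixCol] <- 2L
    m[1, setdiff(1:4, fixCol)] <- 0L; m[2, setdiff(1:4, fixCol)] <- 2L
    m
  }
  set.seed(2)
  reps <- new("ReplicateSet", samples = list(mk(1), mk(1), mk(1)),
              locusIds = paste0("L", 1:4), pool = NULL, config = cfg)
  filt <- filterMonomorphic(reps)
  expect_identical(locusIds(filt), paste0("L", 2:4))
  expect_true(all(vapply(samples(filt), ncol, integer(1)) == 3L))

  # a locus constant in just one replicate is dropped from all of them
  smp <- list(mk(1), mk(1), mk(1))
  smp[[2]][, 3] <- 1L
  reps2 <- new("ReplicateSet", samples = smp, locusIds = paste0("L", 1:4),
               pool = NULL, config = cfg)
  expect_identical(locusIds(filterMonomorphic(reps2)), paste0("L", c(2, 4)))

  # all-polymorphic input is untouched
  poly <- filterMonomorphic(filt)
  expect_identical(poly@samples, filt@samples)

  # fewer than 2 retained loci is degenerate
  allFixed <- lapply(1:3, function(k) {
    m <- mk(1); m[, 2:3] <- 1L; m
  })
  reps3 <- new("ReplicateSet", samples = allFixed, locusIds = paste0("L", 1:4),
               pool = NULL, config = cfg)
  expect_error(filterMonomorphic(reps3), "degenerate")
})

test_that("observed fixation rate matches the exact Wright-Fisher chain", {
  set.seed(14)
  ne <- 10; t <- 6; nPed <- 60; l <- 40
  fixFrac <- replicate(nPed, {
    pool <- runBurnIn(simConfig(ne = ne, l = l, generations = t))
    mean(apply(pool, 2, function(col) max(col) == min(col) & col[1] %in% c(0L, 2L)))
  })
  pExact <- oracleFixationProb(ne, t)
  se <- stats::sd(fixFrac) / sqrt(nPed)
  expect_lt(abs(mean(fixFrac) - pExact), 3 * se)
})
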