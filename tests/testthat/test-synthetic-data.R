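test_that("occupancy probability respects its Gaussian-niche limits", {
  # at the niche optimum with d = 1 the probability equals h
  expect_equal(occupancyProbability(mu = c(0, 0), sigma = c(1, 1), h = 0.7,
                                    gradients = c(0, 0), d = 1), 0.7)
  # d = 0: identical probability at every site, whatever the environment
  set.seed(1)
  g <- matrix(rnorm(40), 20, 2)
  p0 <- occupancyProbability(c(0.3, -1), c(0.5, 0.5), 0.6, g, d = 0)
  expect_equal(diff(range(p0)), 0, tolerance = 1e-12)
  # a flat niche (huge sigma) gives p -> h everywhere
  pf <- occupancyProbability(c(0, 0), c(1e6, 1e6), 0.8, g, d = 1)
  expect_true(all(abs(pf - 0.8) < 1e-3))
  expect_error(occupancyProbability(0, -1, 0.5, 0, 1), "sigma")
})

test_that("the determinism mixture preserves expected prevalence", {
  set.seed(2)
  g <- matrix(rnorm(1000), 500, 2)
  for (d in c(0, 0.4, 1)) {
    p <- occupancyProbability(c(0.5, -0.2), c(0.4, 0.8), 0.5, g, d)
    expect_equal(mean(p),
                 mean(occupancyProbability(c(0.5, -0.2), c(0.4, 0.8), 0.5, g, 0)),
                 tolerance = 1e-12)
  }
})

test_that("generation is reproducible and stage-independent under the seed", {
  spec <- landscapeSpec(nSites = 80L, nSpecies = 30L, nGradients = 3L,
                        nObservedVars = 9L, seed = 42L)
  e1 <- generateEnvironment(spec)
  e2 <- generateEnvironment(spec)
  expect_identical(envMatrix(e1$env), envMatrix(e2$env))
  l1 <- suppressWarnings(sampleOccurrences(spec))
  expect_identical(envMatrix(l1$env), envMatrix(e1$env))
  l2 <- suppressWarnings(sampleOccurrences(spec))
  expect_identical(presenceMatrix(l1$occ), presenceMatrix(l2$occ))
  spec2 <- landscapeSpec(nSites = 80L, nSpecies = 30L, nGradients = 3L,
                         nObservedVars = 9L, seed = 43L)
  expect_false(identical(envMatrix(generateEnvironment(spec2)$env),
                         envMatrix(e1$env)))
})

test_that("near-certain flat niches fill the landscape", {
  spec <- landscapeSpec(nSites = 30L, nSpecies = 10L, nGradients = 2L,
                        nObservedVars = 4L, pEndemic = 0,
                        widespreadBreadthMeanlog = log(1e6),
                        widespreadBreadthSdlog = 0,
                        widespreadOccupancyShape1 = 1e9,
                        widespreadOccupancyShape2 = 1e-9,
                        determinism = 1, seed = 3L)
  land <- sampleOccurrences(spec)
  expect_true(all(presenceMatrix(land$occ) == 1))
})

test_that("realized prevalence tracks the expected occupancy probabilities", {
  spec <- landscapeSpec(nSites = 2000L, nSpecies = 120L, seed = 8L)
  land <- suppressWarnings(sampleOccurrences(spec))
  P <- land$probabilities[, speciesIDs(land$occ), drop = FALSE]
  expected <- colSums(P)
  se <- sqrt(colSums(P * (1 - P)))
  realized <- occupancy(land$occ)
  # redrawn near-empty species are conditioned on being nonzero; check the
  # species whose appearance was never in doubt
  solid <- expected >= 5
  inBand <- abs(realized[solid] - expected[solid]) <= 3 * se[solid]
  expect_gte(mean(inBand), 0.97)
})

test_that("the range-size distribution is right-skewed with a rare tail", {
  land <- suppressWarnings(simulateLandscape(landscapeSpec(seed = 5L)))
  ci <- occupancy(land$occ)
  expect_lt(median(ci), mean(ci))
  expect_gt(mean(ci <= 5), 0.05)          # genuine ultra-rare species
  expect_lt(median(ci) / nSites(land$occ), 0.1)  # most species are restricted
})

test_that("the planted gradients surface as Kaiser-significant components", {
  hits <- 0L
  for (seed in 1:10) {
    spec <- landscapeSpec(nSites = 1000L, nSpecies = 10L, nGradients = 6L,
                          seed = seed)
    env <- generateEnvironment(spec)$env
    if (nRetained(pcaFactors(env)) == 6L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("truth bundle is internally consistent", {
  land <- suppressWarnings(simulateLandscape(landscapeSpec(
    nSites = 150L, nSpecies = 60L, seed = 12L)))
  expect_identical(siteIDs(land$occ), siteIDs(land$env))
  expect_equal(scoreValues(land$trueRWR),
               scoreValues(computeRWR(land$occ)))
  expect_identical(dim(land$probabilities),
                   c(150L, 60L))
  expect_true(all(land$probabilities >= 0 & land$probabilities <= 1))
  # endemic species really are the narrow-range end of the spectrum
  n <- land$niches[land$niches$species_id %in% speciesIDs(land$occ), ]
  ci <- occupancy(land$occ)
  expect_lt(median(ci[n$endemic[match(names(ci), n$species_id)]]),
            median(ci[!n$endemic[match(names(ci), n$species_id)]]))
})
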