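# Fixtures are generated in code; nothing is read from disk.

# random binary incidence matrix with padded, sorted ids
randomOccurrence <- function(nSites, nSpecies, prob = 0.3, seed = 1) {
  set.seed(seed)
  m <- matrix(rbinom(nSites * nSpecies, 1, prob), nSites, nSpecies,
              dimnames = list(sprintf("s%03d", seq_len(nSites)),
                              sprintf("sp%03d", seq_len(nSpecies))))
  OccurrenceMatrix(m)
}

# a hand-built 3-site / 4-species matrix with nested species sets
nestedOccurrence <- function() {
  m <- rbind(s1 = c(1, 1, 1, 1),
             s2 = c(1, 1, 0, 0),
             s3 = c(1, 0, 0, 0))
  colnames(m) <- paste0("sp", 1:4)
  OccurrenceMatrix(m)
}

# strongly environment-determined landscape: fully niche-driven occupancy
# (d = 1), near-certain presence inside the niche (h ~ 1), broad smooth
# hotspots, and covariates that are nearly clean reads of the gradients
strongSpec <- function(seed, nSites = 1000L, nSpecies = 300L) {
  landscapeSpec(nSites = nSites, nSpecies = nSpecies,
                determinism = 1, mixingNoise = 0.02,
                endemicOccupancyShape1 = 50, endemicOccupancyShape2 = 1,
                widespreadOccupancyShape1 = 50, widespreadOccupancyShape2 = 1,
                endemicBreadthMeanlog = log(0.8), endemicBreadthSdlog = 0.2,
                centerJitter = 0.5, nCenters = 5L, pEndemic = 0.9,
                seed = seed)
}

# small landscape for fast end-to-end experiment tests
smallLandscape <- function(seed, nSites = 150L, nSpecies = 50L, d = 0.9) {
  suppressWarnings(simulateLandscape(landscapeSpec(
    nSites = nSites, nSpecies = nSpecies, nGradients = 3L,
    nObservedVars = 9L, nCenters = 3L, determinism = d, seed = seed)))
}
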