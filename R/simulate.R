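#' @include experiment.R
NULL

#' Specify a virtual landscape
#'
#' The generator emulates the data the workflow consumes: a numeric
#' site-covariate table whose correlation structure carries a known number
#' of latent environmental gradients, and a binary incidence matrix whose
#' species occupy sites through Gaussian (bell-shaped) niches on those
#' gradients.
#'
#' Rarity is spatially organised, as it is in real landscapes: most species
#' (`pEndemic`) are endemics clustered at one of `nCenters` endemism centers
#' — environmentally peripheral locations, each with a characteristic pair
#' of limiting gradients shared by its species.  Endemics have narrow niches
#' (lognormal breadth; the sdlog spread yields everything from single-site
#' ultra-rares to locally widespread species, i.e. a right-skewed range-size
#' distribution) and high maximal occupancy (presence is reliable inside the
#' range: range-size rarity, not low density).  The remaining species are
#' widespread background with broad niches and lower, variable density.
#'
#' The determinism parameter d ∈ \[0, 1\] tunes how strongly occupancy
#' follows the environment at constant expected prevalence
#' (see [occupancyProbability()]): d = 1 is fully niche-driven, d = 0 is
#' environment-free noise with the same range-size structure.
#'
#' Defaults describe a mid-sized atlas-style landscape — 1,000 sites, 300
#' species, 6 gradients observed through 18 noisy covariates, d = 0.9 —
#' whose occupancy distribution (median about 2\% of sites, roughly a fifth
#' of species in 5 or fewer sites, mean well above the median) resembles
#' published plant and bird atlases.
#'
#' @param nSites number of sites (default 1000).
#' @param nSpecies number of species (default 300).
#' @param nGradients latent environmental gradients (default 6).
#' @param nObservedVars observed covariates, each a noisy mixture of one or
#'   two gradients (default 3 per gradient).
#' @param pEndemic fraction of species attached to an endemism center
#'   (default 0.8).
#' @param nCenters endemism centers (default 6), anchored at environmentally
#'   peripheral sites.
#' @param centerJitter sd of endemic optima around their center (default
#'   0.25, in gradient-SD units).
#' @param endemicBreadthMeanlog,endemicBreadthSdlog lognormal niche-breadth
#'   parameters for endemics (defaults log(0.28), 0.6).
#' @param endemicOccupancyShape1,endemicOccupancyShape2 Beta parameters of
#'   endemic maximal occupancy h (defaults 8, 2: mean 0.8).
#' @param widespreadBreadthMeanlog,widespreadBreadthSdlog lognormal
#'   niche-breadth parameters for widespread species (defaults log(1.5), 0.3).
#' @param widespreadOccupancyShape1,widespreadOccupancyShape2 Beta
#'   parameters of widespread maximal occupancy (defaults 1.5, 3).
#' @param mixingNoise sd of covariate observation noise (default 0.25,
#'   against unit-variance gradients).
#' @param determinism d in \[0, 1\] (default 0.9).
#' @param seed integer seed.
#' @return a [LandscapeSpec-class].
#' @export
landscapeSpec <- function(nSites = 1000L, nSpecies = 300L, nGradients = 6L,
                          nObservedVars = 3L * nGradients,
                          pEndemic = 0.8, nCenters = 6L, centerJitter = 0.25,
                          endemicBreadthMeanlog = log(0.28),
                          endemicBreadthSdlog = 0.6,
                          endemicOccupancyShape1 = 8, endemicOccupancyShape2 = 2,
                          widespreadBreadthMeanlog = log(1.5),
                          widespreadBreadthSdlog = 0.3,
                          widespreadOccupancyShape1 = 1.5,
                          widespreadOccupancyShape2 = 3,
                          mixingNoise = 0.25, determinism = 0.9, seed = 1L) {
  new("LandscapeSpec",
      nSites = as.integer(nSites), nGradients = as.integer(nGradients),
      nObservedVars = as.integer(nObservedVars), nSpecies = as.integer(nSpecies),
      pEndemic = pEndemic, nCenters = as.integer(nCenters),
      centerJitter = centerJitter,
      endemicBreadthMeanlog = endemicBreadthMeanlog,
      endemicBreadthSdlog = endemicBreadthSdlog,
      endemicOccupancyShape1 = endemicOccupancyShape1,
      endemicOccupancyShape2 = endemicOccupancyShape2,
      widespreadBreadthMeanlog = widespreadBreadthMeanlog,
      widespreadBreadthSdlog = widespreadBreadthSdlog,
      widespreadOccupancyShape1 = widespreadOccupancyShape1,
      widespreadOccupancyShape2 = widespreadOccupancyShape2,
      mixingNoise = mixingNoise, determinism = determinism,
      seed = as.integer(seed))
}

setMethod("show", "LandscapeSpec", function(object) {
  cat(sprintf(paste0("LandscapeSpec: %d sites, %d species, %d gradients ",
                     "(%d observed vars), %d centers, d = %g, seed %d\n"),
              object@nSites, object@nSpecies, object@nGradients,
              object@nObservedVars, object@nCenters, object@determinism,
              object@seed))
})

# deterministic sub-seeds for the generator stages, all derived from the
# spec's seed so each stage is independently reproducible
specSeeds <- function(spec) seedSequence(spec@seed, 4L)

padIDs <- function(prefix, n)
  sprintf("%s%0*d", prefix, nchar(as.character(n)), seq_len(n))

#' Generate the environmental side of a virtual landscape
#'
#' Latent gradients are drawn standard-normal per site.  Each observed
#' covariate is a linear mixture of one primary gradient (assigned in
#' rotation, so every gradient is observed) and — when the pool is richer
#' than the gradients, with probability 1/2 — a second gradient at weight
#' 0.4, plus Gaussian observation noise.  With the defaults this yields a
#' correlated pool in which correlation-matrix PCA retains about
#' `nGradients` Kaiser-significant components.
#'
#' @param spec a [LandscapeSpec-class].
#' @return a list: `env` ([EnvironmentTable-class]) and `gradients` (site x
#'   gradient matrix of the latent truth, for recovery checks).
#' @export
generateEnvironment <- function(spec) {
  stopifnot(is(spec, "LandscapeSpec"))
  seeds <- specSeeds(spec)
  sites <- padIDs("site", spec@nSites)
  withSeed(seeds[1], {
    G <- matrix(stats::rnorm(spec@nSites * spec@nGradients),
                spec@nSites, spec@nGradients,
                dimnames = list(sites, paste0("grad", seq_len(spec@nGradients))))
    V <- matrix(0, spec@nSites, spec@nObservedVars,
                dimnames = list(sites, padIDs("var", spec@nObservedVars)))
    composite <- spec@nObservedVars > spec@nGradients
    for (j in seq_len(spec@nObservedVars)) {
      primary <- ((j - 1L) %% spec@nGradients) + 1L
      x <- G[, primary]
      if (composite && spec@nGradients > 1L && stats::runif(1) < 0.5) {
        secondary <- sample(setdiff(seq_len(spec@nGradients), primary), 1L)
        x <- x + 0.4 * G[, secondary]
      }
      V[, j] <- x + stats::rnorm(spec@nSites, sd = spec@mixingNoise)
    }
    list(env = EnvironmentTable(V, sort = FALSE), gradients = G)
  })
}

#' Draw the species niches of a virtual landscape
#'
#' Endemism centers are placed at sites in the outer 30\% of environmental
#' radius (rarity concentrates at environmental extremes); each center is
#' assigned a characteristic pair of limiting gradients.  Endemic species
#' take their center's gradient pair, an optimum jittered around the center,
#' a narrow lognormal breadth and a high Beta maximal occupancy; widespread
#' species get a random gradient pair, an optimum drawn like the sites, a
#' broad breadth and a lower occupancy.
#'
#' @param spec a [LandscapeSpec-class].
#' @param gradients the latent site x gradient matrix from
#'   [generateEnvironment()]; regenerated from the spec when omitted.
#' @return a data.frame with one row per species: `species_id`, `endemic`,
#'   `center`, `h`, and list columns `gradient`, `mu`, `sigma`.
#' @export
drawNiches <- function(spec, gradients = NULL) {
  stopifnot(is(spec, "LandscapeSpec"))
  if (is.null(gradients)) gradients <- generateEnvironment(spec)$gradients
  seeds <- specSeeds(spec)
  ng <- spec@nGradients
  withSeed(seeds[2], {
    radius <- sqrt(rowSums(gradients^2))
    peripheral <- which(radius >= stats::quantile(radius, 0.7))
    centers <- gradients[sample(peripheral, spec@nCenters, replace =
                                  spec@nCenters > length(peripheral)), ,
                         drop = FALSE]
    pairDim <- min(2L, ng)
    centerPair <- replicate(spec@nCenters, sample(ng, pairDim), simplify = FALSE)
    endemic <- stats::runif(spec@nSpecies) < spec@pEndemic
    niches <- data.frame(species_id = padIDs("sp", spec@nSpecies),
                         endemic = endemic, center = NA_integer_,
                         h = NA_real_)
    niches$gradient <- niches$mu <- niches$sigma <- vector("list", spec@nSpecies)
    for (i in seq_len(spec@nSpecies)) {
      if (endemic[i]) {
        k <- sample.int(spec@nCenters, 1L)
        niches$center[i] <- k
        niches$gradient[[i]] <- centerPair[[k]]
        niches$mu[[i]] <- centers[k, centerPair[[k]]] +
          stats::rnorm(pairDim, sd = spec@centerJitter)
        niches$sigma[[i]] <- stats::rlnorm(pairDim, spec@endemicBreadthMeanlog,
                                           spec@endemicBreadthSdlog)
        niches$h[i] <- stats::rbeta(1, spec@endemicOccupancyShape1,
                                    spec@endemicOccupancyShape2)
      } else {
        niches$gradient[[i]] <- sample(ng, pairDim)
        niches$mu[[i]] <- stats::rnorm(pairDim)
        niches$sigma[[i]] <- stats::rlnorm(pairDim, spec@widespreadBreadthMeanlog,
                                           spec@widespreadBreadthSdlog)
        niches$h[i] <- stats::rbeta(1, spec@widespreadOccupancyShape1,
                                    spec@widespreadOccupancyShape2)
      }
    }
    niches
  })
}

#' Occupancy probability of one species across sites
#'
#' The niche term is the product-Gaussian response
#' \eqn{G(x) = \exp(-\tfrac12 \sum_g ((x_g - \mu_g)/\sigma_g)^2)}.  The
#' determinism mixture \deqn{p = d\,h\,G(x) + (1 - d)\,h\,\bar G} replaces a
#' fraction (1 - d) of the niche signal with the species' landscape-mean
#' response \eqn{\bar G}, so expected prevalence is identical at every d:
#' at d = 0 occupancy is environment-free Bernoulli noise with the same
#' range-size distribution as at d = 1.  Rarity structure and environmental
#' signal are therefore independently tunable.
#'
#' @param mu,sigma numeric vectors: niche optimum and breadth per used
#'   gradient.
#' @param h maximal occupancy in (0, 1].
#' @param gradients site x gradient matrix restricted to the species' used
#'   gradients (a vector is treated as one site).
#' @param d determinism in \[0, 1\].
#' @return numeric vector of per-site occupancy probabilities.
#' @examples
#' occupancyProbability(mu = 0, sigma = 1, h = 0.6, gradients = 0, d = 1)
#' # at the optimum with d = 1 the probability equals h
#' @export
occupancyProbability <- function(mu, sigma, h, gradients, d) {
  stopifnot(d >= 0, d <= 1, h > 0, h <= 1, all(sigma > 0))
  g <- if (is.matrix(gradients)) gradients else matrix(gradients, nrow = 1)
  z <- sweep(g, 2, mu, "-")
  z <- sweep(z, 2, sigma, "/")
  niche <- exp(-0.5 * rowSums(z^2))
  d * h * niche + (1 - d) * h * mean(niche)
}

#' Sample a virtual incidence matrix with known ground truth
#'
#' Independent Bernoulli draws per site and species at the probabilities of
#' [occupancyProbability()].  Species that end up with zero presences are
#' redrawn up to 10 times and then dropped with a warning (their expected
#' prevalence was too low to ever appear at this landscape size).  The truth
#' bundle carries everything recovery tests need: the latent gradients, the
#' niche table, the per-site expected-occupancy matrix and the realized
#' full-landscape RWR.
#'
#' @param spec a [LandscapeSpec-class].
#' @return a list: `occ` ([OccurrenceMatrix-class]), `env`
#'   ([EnvironmentTable-class]), `gradients`, `niches`, `probabilities`
#'   (site x species expected occupancy), and `trueRWR`
#'   ([SiteScores-class] computed from the realized full matrix).
#' @export
sampleOccurrences <- function(spec) {
  stopifnot(is(spec, "LandscapeSpec"))
  seeds <- specSeeds(spec)
  envgen <- generateEnvironment(spec)
  niches <- drawNiches(spec, envgen$gradients)
  G <- envgen$gradients
  P <- vapply(seq_len(spec@nSpecies), function(i) {
    occupancyProbability(niches$mu[[i]], niches$sigma[[i]], niches$h[i],
                         G[, niches$gradient[[i]], drop = FALSE],
                         spec@determinism)
  }, numeric(spec@nSites))
  dimnames(P) <- list(rownames(G), niches$species_id)
  occ <- withSeed(seeds[3], {
    draws <- matrix(stats::runif(length(P)) < P, nrow(P), ncol(P),
                    dimnames = dimnames(P))
    for (i in which(colSums(draws) == 0)) {
      for (retry in seq_len(10L)) {
        draws[, i] <- stats::runif(nrow(P)) < P[, i]
        if (any(draws[, i])) break
      }
    }
    empty <- colSums(draws) == 0
    if (any(empty)) {
      warning(sum(empty), " species never occurred after 10 redraws and were dropped")
      draws <- draws[, !empty, drop = FALSE]
    }
    if (ncol(draws) == 0L) stop("all species empty: prevalence too low for this landscape")
    OccurrenceMatrix(draws + 0, sort = FALSE)
  })
  list(occ = occ, env = envgen$env, gradients = G, niches = niches,
       probabilities = P, trueRWR = computeRWR(occ))
}

#' Generate a complete virtual landscape
#'
#' Convenience wrapper around [sampleOccurrences()]; see there for the
#' returned truth bundle.
#'
#' @param spec a [LandscapeSpec-class].
#' @return see [sampleOccurrences()].
#' @export
simulateLandscape <- function(spec) sampleOccurrences(spec)
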