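#' @import methods
NULL

#' Binary site-by-species incidence matrix
#'
#' The central container: rows are sites (planning units), columns are
#' species, and an entry is 1 iff the species was recorded at the site.
#' Column sums are the per-species occupancy counts \eqn{c_i} that drive all
#' rarity weighting; row sums are site richness.  A full-landscape matrix has
#' every species present somewhere; a subset view (e.g. the inventoried q\%
#' sample of a split) may legitimately contain all-zero species columns.
#'
#' @slot presence numeric site x species matrix with 0/1 entries and unique
#'   dimnames.
#' @export
setClass("OccurrenceMatrix", representation(presence = "matrix"))

setValidity("OccurrenceMatrix", function(object) {
  p <- object@presence
  msg <- character()
  if (is.null(rownames(p)) || is.null(colnames(p)))
    msg <- c(msg, "presence matrix must have site and species dimnames")
  else {
    if (anyDuplicated(rownames(p))) msg <- c(msg, "duplicate site identifiers")
    if (anyDuplicated(colnames(p))) msg <- c(msg, "duplicate species identifiers")
  }
  if (length(p) && (!is.numeric(p) || anyNA(p) || !all(p %in% c(0, 1))))
    msg <- c(msg, "presence entries must all be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Site-by-variable environmental covariate table
#'
#' Numeric covariates (climate, productivity, topography summaries and the
#' like) for each site.  Missing values are rejected outright: the intended
#' predictors are complete landscape-wide layers, and silent imputation would
#' leak into every downstream model.
#'
#' @slot values numeric site x variable matrix, finite, with unique dimnames.
#' @export
setClass("EnvironmentTable", representation(values = "matrix"))

setValidity("EnvironmentTable", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "environment matrix must have site and variable dimnames")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate site identifiers")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate variable names")
  }
  if (length(v) && (!is.numeric(v) || any(!is.finite(v))))
    msg <- c(msg, "environment values must be finite numbers (no missing values)")
  if (length(msg)) msg else TRUE
})

#' Inventoried / holdout partition of the sites
#'
#' Records which sites form the q\% inventoried sample (species data
#' available to the planner) and which are held out.
#'
#' @slot inventoried character vector of inventoried site ids.
#' @slot holdout character vector of the remaining site ids.
#' @slot q sampled percentage in (0, 100].
#' @slot seed integer seed the split was drawn with.
#' @export
setClass("SiteSplit", representation(inventoried = "character",
                                     holdout = "character",
                                     q = "numeric", seed = "integer"))

setValidity("SiteSplit", function(object) {
  msg <- character()
  if (length(intersect(object@inventoried, object@holdout)))
    msg <- c(msg, "inventoried and holdout sets overlap")
  if (object@q <= 0 || object@q > 100) msg <- c(msg, "q must lie in (0, 100]")
  if (length(object@inventoried) < 2)
    msg <- c(msg, "inventoried set must contain at least 2 sites")
  if (length(msg)) msg else TRUE
})

#' Per-species rarity weights 1 / c_i
#'
#' The rarity value of a species is the inverse of the number of sites it
#' occupies, computed from one specific incidence matrix.  Species absent
#' from that matrix carry no weight and are omitted.
#'
#' @slot weights named numeric vector, values in (0, 1].
#' @slot source fingerprint of the matrix the weights were computed from.
#' @export
setClass("RarityWeights", representation(weights = "numeric", source = "character"))

setValidity("RarityWeights", function(object) {
  w <- object@weights
  msg <- character()
  if (length(w) && is.null(names(w))) msg <- c(msg, "weights must be named by species")
  if (length(w) && (any(!is.finite(w)) || any(w <= 0) || any(w > 1)))
    msg <- c(msg, "weights must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' One real-valued score per site
#'
#' Holds either rarity-weighted richness computed from incidence data
#' (label \code{"RWR"}) or model-predicted rarity-weighted richness
#' (label \code{"PRWR"}).  Scores are the ranking key for site accumulation.
#'
#' @slot scores named numeric vector, finite, one entry per site.
#' @slot label \code{"RWR"} or \code{"PRWR"}.
#' @export
setClass("SiteScores", representation(scores = "numeric", label = "character"))

setValidity("SiteScores", function(object) {
  msg <- character()
  if (length(object@scores) && is.null(names(object@scores)))
    msg <- c(msg, "scores must be named by site")
  if (any(!is.finite(object@scores))) msg <- c(msg, "scores must be finite")
  if (!object@label %in% c("RWR", "PRWR")) msg <- c(msg, "label must be RWR or PRWR")
  if (length(msg)) msg else TRUE
})

#' Correlation-matrix PCA of the environmental pool
#'
#' @slot eigenvalues descending eigenvalues of the correlation matrix; they
#'   sum to the number of variables.
#' @slot scores site x component matrix of component scores.
#' @slot loadings variable x component matrix.
#' @slot nRetained number of components kept under the Kaiser rule
#'   (eigenvalue > 1, minimum 1).
#' @export
setClass("PcaResult", representation(eigenvalues = "numeric", scores = "matrix",
                                     loadings = "matrix", nRetained = "integer"))

setValidity("PcaResult", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@eigenvalues), strictly = FALSE))
    msg <- c(msg, "eigenvalues must be in descending order")
  if (object@nRetained < 1L) msg <- c(msg, "nRetained must be >= 1")
  if (length(msg)) msg else TRUE
})

#' One representative predictor variable per retained component
#'
#' @slot selected ordered character vector of chosen variable names, no
#'   duplicates, one per retained component.
#' @slot component integer index of the component each variable represents.
#' @slot absCorrelation |Pearson r| between each variable and its component's
#'   scores.
#' @export
setClass("PredictorSet", representation(selected = "character",
                                        component = "integer",
                                        absCorrelation = "numeric"))

setValidity("PredictorSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@selected)) msg <- c(msg, "duplicate predictor variables")
  if (length(object@selected) != length(object@component) ||
      length(object@selected) != length(object@absCorrelation))
    msg <- c(msg, "slot lengths disagree")
  if (length(msg)) msg else TRUE
})

#' Fitted random-forest model of RWR
#'
#' Wraps the tree ensemble together with its training provenance and
#' out-of-bag (OOB) error.  Tree-ensemble predictions are averages of
#' training responses, so every prediction lies within the observed training
#' range.
#'
#' @slot forest the fitted \code{randomForest} ensemble.
#' @slot predictors predictor variable names used at fit time.
#' @slot trainingSites site ids the model was trained on.
#' @slot oobMSE out-of-bag mean squared error at the full ensemble size.
#' @slot oobR2 out-of-bag R-squared (NA for a constant response).
#' @slot responseRange min/max of the (transformed) training response.
#' @slot transform response transform: "identity", "log1p" or "rank".
#' @slot config list of fitting parameters (nTrees, mtry, minLeaf, seed).
#' @export
setClass("RwrForest", representation(forest = "ANY", predictors = "character",
                                     trainingSites = "character",
                                     oobMSE = "numeric", oobR2 = "numeric",
                                     responseRange = "numeric",
                                     transform = "character", config = "list"))

#' Species accumulation curve
#'
#' An ordering of sites together with the cumulative number of distinct
#' species represented by the first k sites, always counted against the full
#' landscape incidence matrix.  The analytic random baseline has no site
#' ordering (its \code{sites} slot is empty).
#'
#' @slot sites ordered site ids (empty for the analytic random expectation).
#' @slot S cumulative distinct-species counts S_k, k = 1..N; non-decreasing.
#' @slot kind one of "surrogate", "optimal", "random_expected".
#' @export
setClass("AccumulationCurve", representation(sites = "character", S = "numeric",
                                             kind = "character"))

setValidity("AccumulationCurve", function(object) {
  msg <- character()
  if (!object@kind %in% c("surrogate", "optimal", "random_expected"))
    msg <- c(msg, "kind must be surrogate, optimal or random_expected")
  if (length(object@S) > 1 && any(diff(object@S) < -1e-9))
    msg <- c(msg, "S_k must be non-decreasing")
  if (length(object@sites) && length(object@sites) != length(object@S))
    msg <- c(msg, "sites and S must have equal length when sites are recorded")
  if (length(msg)) msg else TRUE
})

#' Species Accumulation Index at a set of evaluation steps
#'
#' SAI = (S - R) / (O - R): 1 means the surrogate ordering represents species
#' as well as the optimal selection of equally many sites, 0 means no better
#' than random site selection, negative means worse than random.
#'
#' @slot saiK per-step SAI values, named by step k.
#' @slot meanSAI unweighted mean over the evaluated steps.
#' @slot steps the evaluated step sizes k.
#' @export
setClass("SaiValue", representation(saiK = "numeric", meanSAI = "numeric",
                                    steps = "integer"))

#' Replicated-experiment configuration
#'
#' @slot qValues inventoried percentages to sweep (default 5, 10, ..., 60).
#' @slot nReplicates random subsets per q (default 100).
#' @slot fractions top fractions of the landscape SAI is averaged over
#'   (default 0.05, 0.10, ..., 0.50).
#' @slot model list of random-forest parameters (see [modelConfig()]).
#' @slot masterSeed master seed all replicate seeds derive from.
#' @slot pcaOn "all" (default): PCA/predictor selection on the full
#'   environment table, outside the replicate loop; "inventoried": recomputed
#'   per replicate on the inventoried subset only.
#' @export
setClass("ExperimentConfig", representation(qValues = "numeric",
                                            nReplicates = "integer",
                                            fractions = "numeric",
                                            model = "list",
                                            masterSeed = "integer",
                                            pcaOn = "character"))

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (any(object@qValues <= 0 | object@qValues >= 100))
    msg <- c(msg, "qValues must lie strictly inside (0, 100)")
  if (object@nReplicates < 2L) msg <- c(msg, "nReplicates must be >= 2")
  if (any(object@fractions <= 0 | object@fractions > 1))
    msg <- c(msg, "fractions must lie in (0, 1]")
  if (!object@pcaOn %in% c("all", "inventoried"))
    msg <- c(msg, "pcaOn must be 'all' or 'inventoried'")
  if (length(msg)) msg else TRUE
})

#' Per-q summary of replicate SAI values
#'
#' @slot replicates nReplicates x length(qValues) matrix of per-replicate
#'   mean SAI values (columns named by q).
#' @slot summary data.frame with columns q, mean_sai, ci_low, ci_high,
#'   significant (95 percent percentile CI excludes zero).
#' @slot config the [ExperimentConfig-class] that produced it.
#' @export
setClass("SaiSummary", representation(replicates = "matrix",
                                      summary = "data.frame",
                                      config = "ExperimentConfig"))

#' Virtual-landscape specification
#'
#' Parameters of the synthetic generator: latent environmental gradients
#' drive species occupancy through Gaussian (bell-shaped) niches; observed
#' covariates are noisy linear mixtures of the gradients; the determinism
#' parameter d mixes niche-driven and environment-free occupancy at constant
#' expected prevalence.  Rarity is organised around endemism centers —
#' environmentally peripheral locations whose characteristic pair of
#' limiting gradients is shared by a cluster of narrow-range species — with
#' a minority of widespread background species.  See [landscapeSpec()] for
#' the parameter meanings and defaults.
#'
#' @slot nSites,nGradients,nObservedVars,nSpecies counts.
#' @slot pEndemic fraction of species that are center endemics.
#' @slot nCenters number of endemism centers.
#' @slot centerJitter sd of endemic niche optima around their center.
#' @slot endemicBreadthMeanlog,endemicBreadthSdlog lognormal parameters of
#'   endemic niche breadth (the sdlog spread creates the ultra-rare tail).
#' @slot endemicOccupancyShape1,endemicOccupancyShape2 Beta parameters of
#'   endemic maximal occupancy h (high: locally reliable presence).
#' @slot widespreadBreadthMeanlog,widespreadBreadthSdlog lognormal
#'   parameters of widespread-species niche breadth.
#' @slot widespreadOccupancyShape1,widespreadOccupancyShape2 Beta parameters
#'   of widespread maximal occupancy.
#' @slot mixingNoise sd of observation noise on covariates.
#' @slot determinism d in \[0, 1\]: weight of environment in occupancy.
#' @slot seed integer seed.
#' @export
setClass("LandscapeSpec", representation(
  nSites = "integer", nGradients = "integer",
  nObservedVars = "integer", nSpecies = "integer",
  pEndemic = "numeric", nCenters = "integer", centerJitter = "numeric",
  endemicBreadthMeanlog = "numeric", endemicBreadthSdlog = "numeric",
  endemicOccupancyShape1 = "numeric", endemicOccupancyShape2 = "numeric",
  widespreadBreadthMeanlog = "numeric", widespreadBreadthSdlog = "numeric",
  widespreadOccupancyShape1 = "numeric", widespreadOccupancyShape2 = "numeric",
  mixingNoise = "numeric", determinism = "numeric", seed = "integer"))

setValidity("LandscapeSpec", function(object) {
  msg <- character()
  counts <- c(object@nSites, object@nGradients, object@nObservedVars,
              object@nSpecies, object@nCenters)
  if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (object@nObservedVars < object@nGradients)
    msg <- c(msg, "nObservedVars must be >= nGradients")
  if (object@pEndemic < 0 || object@pEndemic > 1)
    msg <- c(msg, "pEndemic must lie in [0, 1]")
  if (object@determinism < 0 || object@determinism > 1)
    msg <- c(msg, "determinism must lie in [0, 1]")
  shapes <- c(object@endemicOccupancyShape1, object@endemicOccupancyShape2,
              object@widespreadOccupancyShape1, object@widespreadOccupancyShape2)
  if (any(shapes <= 0)) msg <- c(msg, "Beta occupancy shapes must be positive")
  if (length(msg)) msg else TRUE
})
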