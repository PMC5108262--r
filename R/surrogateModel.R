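#' @include envSelection.R
NULL

#' Random-forest fitting parameters
#'
#' Defaults follow standard regression-forest practice: 500 trees (ensemble
#' error stabilizes well before that), mtry = floor(p/3) candidate predictors
#' per split (minimum 1), and trees grown until leaves hold fewer than 5
#' training sites.
#'
#' @param nTrees number of trees (default 500).
#' @param mtry predictors tried at each split; `NULL` (default) means
#'   floor(p/3), minimum 1, resolved at fit time.
#' @param minLeaf minimum leaf size (default 5).
#' @param seed integer seed for the bootstrap / split randomness.
#' @param transform response transform applied before fitting: `"identity"`
#'   (default), `"log1p"` (back-transformed on prediction) or `"rank"`
#'   (rank-only responses; predictions remain on the rank scale, which is
#'   all a prioritization by rank requires).
#' @return a named list of validated parameters.
#' @export
modelConfig <- function(nTrees = 500L, mtry = NULL, minLeaf = 5L, seed = 1L,
                        transform = c("identity", "log1p", "rank")) {
  stopifnot(nTrees >= 1, minLeaf >= 1)
  transform <- match.arg(transform)
  list(nTrees = as.integer(nTrees),
       mtry = if (is.null(mtry)) NULL else as.integer(mtry),
       minLeaf = as.integer(minLeaf), seed = as.integer(seed),
       transform = transform)
}

applyTransform <- function(y, transform) {
  switch(transform,
         identity = y,
         log1p = log1p(y),
         rank = rank(y, ties.method = "average"))
}

#' Fit a random forest of RWR on selected environmental predictors
#'
#' Each tree is grown on a classical bootstrap resample of the training
#' sites (n draws with replacement, leaving about 37\% of sites out-of-bag
#' per tree); the out-of-bag mean squared error and R-squared estimate
#' generalization error without a separate validation set.
#'
#' @param env an [EnvironmentTable-class] covering at least the scored sites.
#' @param scores [SiteScores-class] for the training (inventoried) sites —
#'   typically subset-internal RWR from [computeRWR()].
#' @param predictors a [PredictorSet-class] (or character vector of variable
#'   names present in `env`).
#' @param config parameters from [modelConfig()].
#' @return a [RwrForest-class].
#' @export
fitRwrModel <- function(env, scores, predictors, config = modelConfig()) {
  stopifnot(is(env, "EnvironmentTable"), is(scores, "SiteScores"))
  vars <- if (is(predictors, "PredictorSet")) selectedVariables(predictors)
          else as.character(predictors)
  if (!length(vars)) stop("need at least one predictor")
  missingVar <- setdiff(vars, variableNames(env))
  if (length(missingVar))
    stop("predictor(s) absent from environment table: ",
         paste(missingVar, collapse = ", "))
  sites <- siteIDs(scores)
  if (length(sites) < 2) stop("need scores for at least 2 sites")
  missingSite <- setdiff(sites, siteIDs(env))
  if (length(missingSite))
    stop("scored site(s) without environment row: ",
         paste(utils::head(missingSite, 5), collapse = ", "))
  if (length(sites) < config$minLeaf)
    stop("fewer training sites than the minimum leaf size")
  x <- envMatrix(env)[sites, vars, drop = FALSE]
  y <- applyTransform(unname(scoreValues(scores)), config$transform)
  mtry <- if (is.null(config$mtry)) max(1L, floor(length(vars) / 3)) else config$mtry
  fit <- withSeed(config$seed,
                  randomForest::randomForest(x = as.data.frame(x), y = y,
                                             ntree = config$nTrees, mtry = mtry,
                                             nodesize = config$minLeaf))
  mse <- unname(fit$mse[config$nTrees])
  r2 <- if (stats::var(y) > 0) 1 - mse / (stats::var(y) * (length(y) - 1) / length(y)) else NA_real_
  new("RwrForest", forest = fit, predictors = vars, trainingSites = sites,
      oobMSE = mse, oobR2 = r2, responseRange = range(y),
      transform = config$transform,
      config = list(nTrees = config$nTrees, mtry = mtry,
                    minLeaf = config$minLeaf, seed = config$seed))
}

#' @rdname RwrForest-class
#' @param x a [RwrForest-class].
#' @export
setMethod("oobMSE", "RwrForest", function(x) x@oobMSE)

#' @rdname RwrForest-class
#' @export
setMethod("oobR2", "RwrForest", function(x) x@oobR2)

setMethod("show", "RwrForest", function(object) {
  cat(sprintf("RwrForest: %d trees, mtry %d, %d training sites, %d predictors\n",
              object@config$nTrees, object@config$mtry,
              length(object@trainingSites), length(object@predictors)))
  cat(sprintf("  OOB MSE %.4g, OOB R2 %.3f (response: %s)\n",
              object@oobMSE, object@oobR2, object@transform))
})

#' Predict rarity-weighted richness for every site
#'
#' Applies the fitted ensemble to all sites of an environment table —
#' inventoried and uninventoried alike — yielding PRWR, the prioritization
#' score for the whole landscape.  Ensemble predictions are means of
#' training responses, so they never extrapolate beyond the observed RWR
#' range.
#'
#' For the model's own training sites the out-of-bag prediction (mean over
#' the trees whose bootstrap excluded the site) is returned instead of the
#' in-bag ensemble mean.  In-bag predictions at training sites largely
#' memorize the training response, so a "predicted" ranking would secretly
#' reuse the inventoried species data; that inflates apparent surrogacy
#' even when the environment carries no information at all.  OOB prediction
#' keeps PRWR an honest environment-only score at every site.
#'
#' @param model a [RwrForest-class].
#' @param env an [EnvironmentTable-class] containing the model's predictor
#'   columns.
#' @return a [SiteScores-class] labelled `"PRWR"` covering every `env` site.
#' @export
predictPRWR <- function(model, env) {
  stopifnot(is(model, "RwrForest"), is(env, "EnvironmentTable"))
  missingVar <- setdiff(model@predictors, variableNames(env))
  if (length(missingVar))
    stop("environment table lacks model predictor(s): ",
         paste(missingVar, collapse = ", "))
  x <- as.data.frame(envMatrix(env)[, model@predictors, drop = FALSE])
  pred <- stats::predict(model@forest, newdata = x)
  names(pred) <- siteIDs(env)
  oob <- model@forest$predicted
  trained <- intersect(names(pred), names(oob))
  replace <- trained[is.finite(oob[trained])]   # never-OOB rows keep in-bag
  pred[replace] <- oob[replace]
  if (model@transform == "log1p") pred <- expm1(pred)
  new("SiteScores", scores = pred, label = "PRWR")
}

#' Out-of-bag error as a function of ensemble size
#'
#' Fits once at the largest requested tree count and reads the running OOB
#' MSE of the growing ensemble, verifying that error has stabilized well
#' below the default 500 trees.
#'
#' @inheritParams fitRwrModel
#' @param treeCounts increasing vector of ensemble sizes to report.
#' @return data.frame with columns `n_trees`, `oob_mse`.
#' @export
oobCurve <- function(env, scores, predictors, config = modelConfig(),
                     treeCounts = c(10, 50, 100, 200, 500)) {
  treeCounts <- sort(unique(as.integer(treeCounts)))
  stopifnot(all(treeCounts >= 1))
  cfg <- config
  cfg$nTrees <- max(treeCounts)
  fit <- fitRwrModel(env, scores, predictors, cfg)
  data.frame(n_trees = treeCounts, oob_mse = unname(fit@forest$mse[treeCounts]))
}
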