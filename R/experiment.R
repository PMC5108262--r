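#' @include representation.R surrogateModel.R
NULL

#' Build a replicated-experiment configuration
#'
#' @param qValues inventoried percentages to sweep (default 5, 10, ..., 60).
#' @param nReplicates random subsets per q (default 100).
#' @param fractions top landscape fractions SAI is averaged over
#'   (default 0.05 ... 0.50).
#' @param model random-forest parameters from [modelConfig()].
#' @param masterSeed master seed; every replicate seed derives from it via
#'   [seedSequence()].
#' @param pcaOn `"all"` (default) runs PCA/predictor selection once on the
#'   full environment table, outside the replicate loop; `"inventoried"`
#'   recomputes it per replicate from the inventoried sites only.
#' @return an [ExperimentConfig-class].
#' @export
experimentConfig <- function(qValues = seq(5, 60, by = 5), nReplicates = 100L,
                             fractions = seq(0.05, 0.5, by = 0.05),
                             model = modelConfig(), masterSeed = 1L,
                             pcaOn = c("all", "inventoried")) {
  new("ExperimentConfig", qValues = as.numeric(qValues),
      nReplicates = as.integer(nReplicates), fractions = as.numeric(fractions),
      model = model, masterSeed = as.integer(masterSeed),
      pcaOn = match.arg(pcaOn))
}

setMethod("show", "ExperimentConfig", function(object) {
  cat(sprintf("ExperimentConfig: q = {%s}, %d replicates, seed %d, PCA on %s sites\n",
              paste(object@qValues, collapse = ", "), object@nReplicates,
              object@masterSeed, object@pcaOn))
})

#' Run one surrogate-evaluation replicate
#'
#' One pass of the evaluation loop: draw a q\% inventoried split, compute
#' subset-internal RWR (occupancy counted within the inventoried sites only
#' — the planner has no other data), fit the random forest on the
#' inventoried sites' environment, predict PRWR for every site, accumulate
#' sites in PRWR order, and score the curve against the optimal and random
#' baselines.  A pure function of its inputs and `seed`: the split, the
#' forest and the tie-break shuffle each consume an independent sub-seed
#' derived from `seed`.
#'
#' @param occ full-landscape [OccurrenceMatrix-class].
#' @param env aligned [EnvironmentTable-class].
#' @param predictors a [PredictorSet-class] or character vector; ignored
#'   (recomputed from the inventoried subset) when `pcaOn = "inventoried"`.
#' @param q inventoried percentage.
#' @param seed replicate seed.
#' @param model parameters from [modelConfig()].
#' @param fractions SAI evaluation fractions.
#' @param optimal,random precomputed baseline curves (computed on the fly if
#'   `NULL`; precompute them when replicating).
#' @param pcaOn see [experimentConfig()].
#' @return a list with `meanSAI`, `oobMSE`, `oobR2` and `seed`.
#' @export
runReplicate <- function(occ, env, predictors, q, seed, model = modelConfig(),
                         fractions = seq(0.05, 0.5, by = 0.05),
                         optimal = NULL, random = NULL, pcaOn = "all") {
  sub <- seedSequence(seed, 4L)
  split <- sampleSplit(occ, q, sub[1])
  inv <- occ[split@inventoried, ]
  rwrScores <- tryCatch(computeRWR(inv), error = function(e)
    stop("replicate (q=", q, ", seed=", seed, ") RWR failed: ",
         conditionMessage(e)))
  if (identical(pcaOn, "inventoried")) {
    envInv <- env[split@inventoried, ]
    predictors <- selectPredictors(envInv, pcaFactors(envInv))
  }
  cfg <- model
  cfg$seed <- sub[2]
  fit <- fitRwrModel(env, rwrScores, predictors, cfg)
  prwr <- predictPRWR(fit, env)
  surrogate <- accumulationCurve(occ, prwr, seed = sub[3])
  if (is.null(optimal)) optimal <- greedyOptimalCurve(occ)
  if (is.null(random)) random <- expectedRandomCurve(occ)
  sai <- speciesAccumulationIndex(surrogate, optimal, random, fractions)
  list(meanSAI = meanSAI(sai), oobMSE = oobMSE(fit), oobR2 = oobR2(fit),
       seed = as.integer(seed))
}

#' Sweep the inventoried fraction q and summarize surrogate efficiency
#'
#' For each q, runs `nReplicates` independent replicates ([runReplicate()]),
#' each on a fresh random q\% split, and summarizes the replicate mean-SAI
#' distribution with its mean and 95\% percentile confidence interval
#' (order-statistic quantiles, so with 2 replicates the CI is exactly their
#' min/max).  Surrogacy at a given q is flagged significant when the CI
#' excludes zero.  The optimal and random baselines depend only on the full
#' incidence matrix and are computed once, outside the loop, as is
#' PCA/predictor selection under the default `pcaOn = "all"`.  Any replicate
#' failure aborts the sweep with context — silently dropping replicates
#' would bias the confidence intervals.
#'
#' @param occ full-landscape [OccurrenceMatrix-class].
#' @param env an [EnvironmentTable-class] covering its sites.
#' @param config an [ExperimentConfig-class].
#' @param verbose print per-q progress.
#' @return a [SaiSummary-class].
#' @export
sweepSAI <- function(occ, env, config = experimentConfig(), verbose = FALSE) {
  stopifnot(is(config, "ExperimentConfig"))
  al <- alignSites(occ, env)
  occ <- al$occ; env <- al$env
  predictors <- if (config@pcaOn == "all")
    selectPredictors(env, pcaFactors(env)) else NULL
  optimal <- greedyOptimalCurve(occ)
  random <- expectedRandomCurve(occ)
  nq <- length(config@qValues)
  seeds <- matrix(seedSequence(config@masterSeed, nq * config@nReplicates),
                  nrow = config@nReplicates, ncol = nq)
  reps <- matrix(NA_real_, config@nReplicates, nq,
                 dimnames = list(NULL, as.character(config@qValues)))
  for (j in seq_len(nq)) {
    q <- config@qValues[j]
    if (verbose) message("q = ", q, "% (", config@nReplicates, " replicates)")
    for (i in seq_len(config@nReplicates)) {
      res <- runReplicate(occ, env, predictors, q, seeds[i, j],
                          model = config@model, fractions = config@fractions,
                          optimal = optimal, random = random,
                          pcaOn = config@pcaOn)
      reps[i, j] <- res$meanSAI
    }
  }
  summary <- data.frame(
    q = config@qValues,
    mean_sai = colMeans(reps),
    ci_low = apply(reps, 2, stats::quantile, probs = 0.025, type = 1),
    ci_high = apply(reps, 2, stats::quantile, probs = 0.975, type = 1),
    row.names = NULL)
  summary$significant <- summary$ci_low > 0 | summary$ci_high < 0
  new("SaiSummary", replicates = reps, summary = summary, config = config)
}

#' @rdname SaiSummary-class
#' @param x a [SaiSummary-class].
#' @export
setMethod("saiReplicates", "SaiSummary", function(x) x@replicates)

#' @rdname SaiSummary-class
#' @param object a [SaiSummary-class].
#' @param ... ignored.
#' @export
setMethod("summary", "SaiSummary", function(object, ...) object@summary)

setMethod("show", "SaiSummary", function(object) {
  cat("SaiSummary:", nrow(object@replicates), "replicates per q\n")
  print(object@summary, digits = 3, row.names = FALSE)
})

#' Write the sweep report table to CSV
#'
#' Columns: q, mean_sai, ci_low, ci_high, significant.  Deterministic
#' formatting, so identical sweeps produce byte-identical files.
#'
#' @param x a [SaiSummary-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSweepReport <- function(x, path) {
  stopifnot(is(x, "SaiSummary"))
  utils::write.csv(x@summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot surrogate efficiency against the inventoried fraction
#'
#' Mean SAI per q with its 95\% percentile confidence interval as vertical
#' bars, plus the zero line (random performance) for reference.
#'
#' @param x a [SaiSummary-class].
#' @return a ggplot object.
#' @export
plotSAI <- function(x) {
  stopifnot(is(x, "SaiSummary"))
  df <- x@summary
  ggplot2::ggplot(df, ggplot2::aes(x = .data$q, y = .data$mean_sai)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Sites inventoried, q (%)",
                  y = "Species Accumulation Index",
                  title = "Surrogate efficiency of PRWR") +
    ggplot2::theme_minimal()
}
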