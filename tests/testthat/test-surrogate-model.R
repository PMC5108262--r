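makeTrainingData <- function(n = 120, seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(sprintf("s%03d", 1:n), paste0("v", 1:4)))
  env <- EnvironmentTable(v)
  y <- v[, 1]^2 + 0.5 * v[, 2] + rnorm(n, sd = 0.2) + 3
  scores <- new("SiteScores", scores = setNames(pmax(y, 0), rownames(v)),
                label = "RWR")
  list(env = env, scores = scores)
}

test_that("a constant response is reproduced exactly with zero OOB error", {
  d <- makeTrainingData()
  const <- new("SiteScores",
               scores = setNames(rep(2.5, 120), siteIDs(d$env)), label = "RWR")
  fit <- suppressWarnings(
    fitRwrModel(d$env, const, paste0("v", 1:4), modelConfig(seed = 1)))
  expect_equal(oobMSE(fit), 0, tolerance = 1e-12)
  pred <- scoreValues(predictPRWR(fit, d$env))
  expect_equal(unname(pred), rep(2.5, 120), tolerance = 1e-12)
})

test_that("fitting is deterministic under the config seed", {
  d <- makeTrainingData()
  f1 <- fitRwrModel(d$env, d$scores, paste0("v", 1:4), modelConfig(seed = 9))
  f2 <- fitRwrModel(d$env, d$scores, paste0("v", 1:4), modelConfig(seed = 9))
  expect_identical(scoreValues(predictPRWR(f1, d$env)),
                   scoreValues(predictPRWR(f2, d$env)))
  expect_identical(oobMSE(f1), oobMSE(f2))
  f3 <- fitRwrModel(d$env, d$scores, paste0("v", 1:4), modelConfig(seed = 10))
  expect_false(identical(oobMSE(f1), oobMSE(f3)))
})

test_that("predictions stay inside the training-response range", {
  d <- makeTrainingData(seed = 3)
  fit <- fitRwrModel(d$env, d$scores, paste0("v", 1:4), modelConfig(seed = 2))
  set.seed(99)
  far <- matrix(rnorm(50 * 4, sd = 5), 50, 4,
                dimnames = list(sprintf("x%02d", 1:50), paste0("v", 1:4)))
  pred <- scoreValues(predictPRWR(fit, EnvironmentTable(far)))
  expect_true(all(pred >= min(scoreValues(d$scores)) - 1e-9))
  expect_true(all(pred <= max(scoreValues(d$scores)) + 1e-9))
})

test_that("mismatched predictors and sites are rejected", {
  d <- makeTrainingData()
  expect_error(fitRwrModel(d$env, d$scores, c("v1", "nope"), modelConfig()),
               "absent from environment")
  fit <- fitRwrModel(d$env, d$scores, paste0("v", 1:4), modelConfig(seed = 1))
  env2 <- d$env[, c("v1", "v2")]
  expect_error(predictPRWR(fit, env2), "lacks model predictor")
  orphan <- new("SiteScores", scores = c(zz = 1, zy = 2), label = "RWR")
  expect_error(fitRwrModel(d$env, orphan, paste0("v", 1:4), modelConfig()),
               "without environment row")
})

test_that("training sites get out-of-bag predictions, not memorized fits", {
  d <- makeTrainingData(seed = 5)
  fit <- fitRwrModel(d$env, d$scores, paste0("v", 1:4), modelConfig(seed = 4))
  pred <- scoreValues(predictPRWR(fit, d$env))
  expect_identical(unname(pred[fit@trainingSites]),
                   unname(fit@forest$predicted[fit@trainingSites]))
  # in-bag predictions would track the response far more closely than OOB
  inbag <- predict(fit@forest, newdata = as.data.frame(envMatrix(d$env)))
  y <- scoreValues(d$scores)
  expect_gt(mean((pred - y)^2), mean((inbag - y)^2))
})

test_that("OOB error declines with ensemble size and matches the full fit", {
  d <- makeTrainingData(seed = 6)
  cfg <- modelConfig(seed = 3)
  curve <- oobCurve(d$env, d$scores, paste0("v", 1:4), cfg,
                    treeCounts = c(10, 100, 500))
  fit <- fitRwrModel(d$env, d$scores, paste0("v", 1:4), cfg)
  expect_equal(curve$oob_mse[curve$n_trees == 500], oobMSE(fit),
               tolerance = 1e-12)
  # MSE at 500 trees at or below MSE at 10 trees across seeds
  worse <- 0L
  for (s in 1:10) {
    d2 <- makeTrainingData(seed = 100 + s)
    cv <- oobCurve(d2$env, d2$scores, paste0("v", 1:4), modelConfig(seed = s),
                   treeCounts = c(10, 500))
    if (cv$oob_mse[2] > cv$oob_mse[1]) worse <- worse + 1L
  }
  expect_lte(worse, 1L)
})

test_that("row order of the training scores does not bias OOB error", {
  # same data presented in two row orders, across seeds: the two OOB MSE
  # distributions are indistinguishable
  mseA <- mseB <- numeric(10)
  for (s in 1:10) {
    d <- makeTrainingData(n = 100, seed = 200 + s)
    perm <- sample(siteIDs(d$env))
    shuffled <- new("SiteScores", scores = scoreValues(d$scores)[perm],
                    label = "RWR")
    mseA[s] <- oobMSE(fitRwrModel(d$env, d$scores, paste0("v", 1:4),
                                  modelConfig(seed = s)))
    mseB[s] <- oobMSE(fitRwrModel(d$env, shuffled, paste0("v", 1:4),
                                  modelConfig(seed = s)))
  }
  expect_gt(wilcox.test(mseA, mseB)$p.value, 0.001)
})

test_that("strongly environment-determined RWR is recovered (OOB R2 > 0.6)", {
  land <- suppressWarnings(simulateLandscape(strongSpec(5)))
  split <- sampleSplit(land$occ, 50, 99)   # 500 training sites
  scores <- computeRWR(land$occ[split@inventoried, ])
  fit <- fitRwrModel(land$env, scores, variableNames(land$env),
                     modelConfig(seed = 7))
  expect_gt(oobR2(fit), 0.6)
})

test_that("PRWR ranks holdout sites like true RWR on high-determinism data", {
  land <- suppressWarnings(simulateLandscape(strongSpec(6)))
  ps <- selectPredictors(land$env, pcaFactors(land$env))
  split <- sampleSplit(land$occ, 20, 100)
  fit <- fitRwrModel(land$env, computeRWR(land$occ[split@inventoried, ]),
                     ps, modelConfig(seed = 8))
  prwr <- predictPRWR(fit, land$env)
  expect_length(scoreValues(prwr), nSites(land$env))
  expect_identical(scoreLabel(prwr), "PRWR")
  rho <- cor(scoreValues(prwr)[split@holdout],
             scoreValues(land$trueRWR)[split@holdout], method = "spearman")
  expect_gt(rho, 0.5)
})

test_that("holdout recovery strengthens with the determinism parameter", {
  rhoAt <- function(d) {
    mean(sapply(1:3, function(s) {
      land <- suppressWarnings(simulateLandscape(
        landscapeSpec(nSites = 500L, nSpecies = 150L, determinism = d, seed = s)))
      ps <- selectPredictors(land$env, pcaFactors(land$env))
      split <- sampleSplit(land$occ, 30, 50)
      fit <- fitRwrModel(land$env, computeRWR(land$occ[split@inventoried, ]),
                         ps, modelConfig(seed = s))
      prwr <- predictPRWR(fit, land$env)
      cor(scoreValues(prwr)[split@holdout],
          scoreValues(land$trueRWR)[split@holdout], method = "spearman")
    }))
  }
  r0 <- rhoAt(0); r5 <- rhoAt(0.5); r9 <- rhoAt(0.9)
  expect_lt(r0, r5)
  expect_lt(r5, r9)
  expect_lt(abs(r0), 0.15)
})
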