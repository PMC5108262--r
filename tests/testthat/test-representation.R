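test_that("accumulation follows descending scores and counts distinct species", {
  occ <- nestedOccurrence()  # s1 ⊃ s2 ⊃ s3
  sc <- new("SiteScores", scores = c(s1 = 3, s2 = 2, s3 = 1), label = "RWR")
  cv <- accumulationCurve(occ, sc, seed = 1)
  expect_identical(orderedSites(cv), c("s1", "s2", "s3"))
  expect_equal(cumulativeSpecies(cv), c(4, 4, 4))

  rev <- new("SiteScores", scores = c(s1 = 1, s2 = 2, s3 = 3), label = "RWR")
  cv2 <- accumulationCurve(occ, rev, seed = 1)
  expect_identical(orderedSites(cv2), c("s3", "s2", "s1"))
  expect_equal(cumulativeSpecies(cv2), c(1, 2, 4))
})

test_that("tied scores are ordered by the seeded shuffle", {
  occ <- randomOccurrence(12, 8, seed = 1)
  flat <- new("SiteScores",
              scores = setNames(rep(1, 12), siteIDs(occ)), label = "PRWR")
  c1 <- accumulationCurve(occ, flat, seed = 5)
  c2 <- accumulationCurve(occ, flat, seed = 5)
  c3 <- accumulationCurve(occ, flat, seed = 6)
  expect_identical(orderedSites(c1), orderedSites(c2))
  expect_false(identical(orderedSites(c1), orderedSites(c3)))
  expect_setequal(orderedSites(c1), siteIDs(occ))
})

test_that("S_k equals the brute-force union over top-k sites", {
  for (seed in 1:5) {
    occ <- randomOccurrence(10, 15, prob = 0.25, seed = seed)
    sc <- new("SiteScores",
              scores = setNames(rnorm(10), siteIDs(occ)), label = "PRWR")
    cv <- accumulationCurve(occ, sc, seed = 1)
    p <- presenceMatrix(occ)
    for (k in seq_len(10)) {
      unionK <- sum(colSums(p[orderedSites(cv)[1:k], , drop = FALSE]) > 0)
      expect_identical(cumulativeSpecies(cv)[k], as.numeric(unionK))
    }
  }
})

test_that("score/matrix site mismatches are rejected", {
  occ <- randomOccurrence(6, 5, seed = 2)
  bad <- new("SiteScores", scores = c(a = 1, b = 2), label = "RWR")
  expect_error(accumulationCurve(occ, bad, 1), "cover exactly")
})

test_that("greedy selection orders disjoint sites by contribution", {
  p <- matrix(0, 3, 9, dimnames = list(c("mid", "big", "tiny"), letters[1:9]))
  p["big", 1:5] <- 1; p["mid", 6:8] <- 1; p["tiny", 9] <- 1
  cv <- greedyOptimalCurve(OccurrenceMatrix(p, sort = FALSE))
  expect_identical(orderedSites(cv), c("big", "mid", "tiny"))
  expect_equal(cumulativeSpecies(cv), c(5, 8, 9))
})

test_that("a site holding every species is picked first", {
  p <- rbind(all = rep(1, 6), some = c(1, 1, 0, 0, 0, 0))
  colnames(p) <- paste0("sp", 1:6)
  cv <- greedyOptimalCurve(OccurrenceMatrix(p, sort = FALSE))
  expect_identical(orderedSites(cv)[1], "all")
  expect_equal(cumulativeSpecies(cv)[1], 6)
})

test_that("exact enumeration agrees with greedy on easy instances", {
  p <- matrix(0, 3, 9, dimnames = list(c("a", "b", "c"), letters[1:9]))
  p["a", 1:5] <- 1; p["b", 6:8] <- 1; p["c", 9] <- 1
  occ <- OccurrenceMatrix(p, sort = FALSE)
  expect_equal(cumulativeSpecies(exactOptimalCurve(occ)),
               cumulativeSpecies(greedyOptimalCurve(occ)))
  # k = N always reaches the full species count
  occ2 <- randomOccurrence(8, 12, seed = 3)
  nOcc <- sum(colSums(presenceMatrix(occ2)) > 0)
  expect_equal(tail(cumulativeSpecies(exactOptimalCurve(occ2)), 1), nOcc)
  expect_error(exactOptimalCurve(randomOccurrence(25, 5, seed = 1)), "20 sites")
})

test_that("greedy can be beaten at k = 2 and enumeration proves it", {
  # the rich site overlaps both medium sites; the mediums jointly cover all
  p <- matrix(0, 3, 8, dimnames = list(c("rich", "m1", "m2"), paste0("sp", 1:8)))
  p["rich", c(1, 2, 3, 5, 6)] <- 1
  p["m1", 1:4] <- 1
  p["m2", 5:8] <- 1
  occ <- OccurrenceMatrix(p, sort = FALSE)
  greedy <- greedyOptimalCurve(occ)
  exact <- exactOptimalCurve(occ)
  expect_identical(orderedSites(greedy)[1], "rich")
  expect_equal(cumulativeSpecies(greedy)[2], 7)
  expect_equal(cumulativeSpecies(exact)[2], 8)
  expect_gt(cumulativeSpecies(exact)[2], cumulativeSpecies(greedy)[2])
})

test_that("expected random curve matches closed forms", {
  # single species in 1 of N sites: R_k = k/N
  p <- matrix(c(1, 0, 0, 0, 0), 5, 1,
              dimnames = list(paste0("s", 1:5), "lonely"))
  cv <- expectedRandomCurve(OccurrenceMatrix(p, sort = FALSE))
  expect_equal(cumulativeSpecies(cv), (1:5) / 5, tolerance = 1e-12)
  # k = N recovers every occupied species
  occ <- randomOccurrence(12, 20, seed = 4)
  nOcc <- sum(colSums(presenceMatrix(occ)) > 0)
  expect_equal(tail(cumulativeSpecies(expectedRandomCurve(occ)), 1), nOcc,
               tolerance = 1e-9)
})

test_that("analytic random expectation matches Monte Carlo", {
  occ <- randomOccurrence(20, 30, prob = 0.2, seed = 5)
  analytic <- cumulativeSpecies(expectedRandomCurve(occ))
  nDraw <- 2000
  p <- presenceMatrix(occ)
  set.seed(77)
  draws <- matrix(NA_real_, nDraw, 20)
  for (i in seq_len(nDraw)) {
    ord <- sample.int(20)
    seen <- rep(FALSE, 30); s <- numeric(20)
    for (k in 1:20) {
      seen <- seen | (p[ord[k], ] > 0)
      s[k] <- sum(seen)
    }
    draws[i, ] <- s
  }
  mc <- colMeans(draws)
  se <- apply(draws, 2, sd) / sqrt(nDraw)
  expect_true(all(abs(analytic - mc) <= 3 * pmax(se, 1e-9) + 1e-9))
})

test_that("SAI hits its limit cases and arithmetic exactly", {
  O <- new("AccumulationCurve", sites = character(0),
           S = c(10, 12, 12, 12), kind = "optimal")
  R <- new("AccumulationCurve", sites = character(0),
           S = c(4, 6, 12, 12), kind = "random_expected")
  perfect <- new("AccumulationCurve", sites = character(0),
                 S = c(10, 12, 12, 12), kind = "surrogate")
  random <- new("AccumulationCurve", sites = character(0),
                S = c(4, 6, 12, 12), kind = "surrogate")
  expect_equal(meanSAI(speciesAccumulationIndex(perfect, O, R, steps = 1:2)), 1)
  expect_equal(meanSAI(speciesAccumulationIndex(random, O, R, steps = 1:2)), 0)
  # S = 7, R = 4, O = 10 at a single step
  s1 <- new("AccumulationCurve", sites = character(0), S = c(7, 9, 12, 12),
            kind = "surrogate")
  expect_equal(meanSAI(speciesAccumulationIndex(s1, O, R, steps = 1)), 0.5)
  # steps where O = R are skipped; all-degenerate step sets are an error
  sai <- speciesAccumulationIndex(s1, O, R, steps = c(1, 4))
  expect_identical(saiSteps(sai), 1L)
  expect_error(speciesAccumulationIndex(s1, O, R, steps = 4), "no evaluable")
})

test_that("baseline ordering invariants hold on random instances", {
  for (seed in 1:8) {
    occ <- randomOccurrence(9, 11, prob = 0.25, seed = seed)
    G <- cumulativeSpecies(greedyOptimalCurve(occ))
    E <- cumulativeSpecies(exactOptimalCurve(occ))
    R <- cumulativeSpecies(expectedRandomCurve(occ))
    expect_true(all(R <= E + 1e-9))          # expectation cannot beat optimum
    expect_true(all(G >= R - 1e-9))          # greedy dominates random
    expect_true(all(G >= (1 - 1 / exp(1)) * E - 1e-9))  # greedy guarantee
    expect_true(all(G <= E + 1e-9))
  }
})

test_that("SAI is invariant to site and species relabeling", {
  occ <- randomOccurrence(10, 12, prob = 0.3, seed = 6)
  sc <- new("SiteScores", scores = setNames(rnorm(10), siteIDs(occ)),
            label = "PRWR")
  saiOf <- function(o, s) {
    meanSAI(speciesAccumulationIndex(
      accumulationCurve(o, s, seed = 3), greedyOptimalCurve(o),
      expectedRandomCurve(o), fractions = c(0.2, 0.5)))
  }
  base <- saiOf(occ, sc)
  p <- presenceMatrix(occ)
  relabeled <- p
  rownames(relabeled) <- paste0("z_", rownames(p))
  colnames(relabeled) <- rev(colnames(p))  # species names permuted
  occ2 <- OccurrenceMatrix(relabeled, sort = FALSE)
  sc2 <- new("SiteScores",
             scores = setNames(scoreValues(sc), paste0("z_", siteIDs(occ))),
             label = "PRWR")
  expect_equal(saiOf(occ2, sc2), base, tolerance = 1e-12)
})

test_that("curves serialize to CSV", {
  occ <- randomOccurrence(6, 7, seed = 7)
  f <- tempfile(fileext = ".csv")
  writeCurve(greedyOptimalCurve(occ), f)
  df <- read.csv(f)
  expect_identical(names(df), c("k", "site_id", "S_k"))
  expect_equal(nrow(df), 6)
})
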