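#' @include rwr.R
NULL

# Cumulative distinct-species counts for an explicit site ordering, counted
# against the full incidence matrix.  For each species, find the first rank
# at which it appears; S_k is the number of species whose first appearance
# is at rank <= k.
cumulativeRepresentation <- function(p, siteOrder) {
  po <- p[siteOrder, , drop = FALSE] > 0
  hit <- colSums(po) > 0
  first <- rep(NA_integer_, ncol(po))
  first[hit] <- apply(po[, hit, drop = FALSE], 2, which.max)
  as.numeric(cumsum(tabulate(first, nbins = nrow(po))))
}

#' Species accumulation curve of a score-ranked site sequence
#'
#' Sites are accumulated starting with the highest-scoring site, adding the
#' next highest at each step; S_k is the number of distinct species
#' represented by the first k sites, counted against the full incidence
#' matrix.  Tied scores are ordered by a seeded shuffle (then site id), so
#' repeated replicates sample tie orderings fairly rather than inheriting a
#' fixed lexicographic bias.
#'
#' @param occ the full-landscape [OccurrenceMatrix-class].
#' @param scores a [SiteScores-class] covering exactly the sites of `occ`.
#' @param seed integer seed for the tie-breaking shuffle.
#' @return an [AccumulationCurve-class] of kind `"surrogate"`.
#' @export
accumulationCurve <- function(occ, scores, seed = 1L) {
  stopifnot(is(occ, "OccurrenceMatrix"), is(scores, "SiteScores"))
  p <- presenceMatrix(occ)
  if (!setequal(rownames(p), siteIDs(scores)) ||
      nrow(p) != length(scoreValues(scores)))
    stop("scores do not cover exactly the sites of the occurrence matrix")
  s <- scoreValues(scores)[rownames(p)]
  shuffle <- withSeed(as.integer(seed), sample.int(length(s)))
  ord <- order(-s, shuffle)
  new("AccumulationCurve", sites = rownames(p)[ord],
      S = cumulativeRepresentation(p, ord), kind = "surrogate")
}

#' Optimal baseline: greedy maximum-coverage site sequence
#'
#' At each step the site adding the most not-yet-represented species is
#' selected (ties broken by higher rarity-weighted richness, then site id).
#' Once every species is covered, the remaining sites are appended by the
#' same rule applied to raw richness.  Greedy maximum coverage carries the
#' classical (1 - 1/e) worst-case guarantee and in practice almost always
#' matches the exhaustive optimum on small instances (see
#' [exactOptimalCurve()]).
#'
#' @param occ the full-landscape [OccurrenceMatrix-class].
#' @return an [AccumulationCurve-class] of kind `"optimal"`.
#' @export
greedyOptimalCurve <- function(occ) {
  stopifnot(is(occ, "OccurrenceMatrix"))
  p <- presenceMatrix(occ)
  n <- nrow(p)
  rwr <- unname(scoreValues(computeRWR(occ)))
  rich <- rowSums(p)
  ids <- rownames(p)
  uncovered <- rep(1, ncol(p))
  remaining <- rep(TRUE, n)
  ord <- integer(n)
  S <- numeric(n)
  covered <- 0
  for (k in seq_len(n)) {
    if (sum(uncovered) > 0) {
      gain <- as.numeric(p[remaining, , drop = FALSE] %*% uncovered)
      cand <- which(remaining)
      pick <- cand[order(-gain, -rwr[cand], ids[cand])[1L]]
      uncovered[p[pick, ] > 0] <- 0
    } else {
      cand <- which(remaining)
      pick <- cand[order(-rich[cand], -rwr[cand], ids[cand])[1L]]
    }
    remaining[pick] <- FALSE
    ord[k] <- pick
    S[k] <- ncol(p) - sum(uncovered)
  }
  new("AccumulationCurve", sites = ids[ord], S = S, kind = "optimal")
}

#' Optimal baseline by exhaustive enumeration (small instances only)
#'
#' For each set size k, O_k is the maximum number of species representable
#' by any k-subset of sites, found by enumerating all k-subsets.  Feasible
#' only for small landscapes; serves as the ground-truth oracle backing the
#' greedy selector.  No single site ordering attains every O_k in general,
#' so the returned curve carries no site sequence.
#'
#' @param occ an [OccurrenceMatrix-class] with at most 20 sites.
#' @param maxSites largest set size to evaluate (default: all sites).
#' @return an [AccumulationCurve-class] of kind `"optimal"` whose S slot
#'   holds O_1..O_maxSites.
#' @export
exactOptimalCurve <- function(occ, maxSites = nSites(occ)) {
  stopifnot(is(occ, "OccurrenceMatrix"))
  p <- presenceMatrix(occ) > 0
  n <- nrow(p)
  if (n > 20)
    stop("exhaustive enumeration is limited to 20 sites; use greedyOptimalCurve()")
  maxSites <- min(maxSites, n)
  O <- vapply(seq_len(maxSites), function(k) {
    max(utils::combn(n, k, FUN = function(ix) sum(colSums(p[ix, , drop = FALSE]) > 0)))
  }, numeric(1))
  new("AccumulationCurve", sites = character(0), S = O, kind = "optimal")
}

#' Random baseline: exact expected accumulation under uniform site sampling
#'
#' The expected number of species represented in k sites drawn uniformly
#' without replacement is \deqn{R_k = \sum_j \left[1 - \binom{N-c_j}{k} /
#' \binom{N}{k}\right],} the complement of each species' hypergeometric
#' absence probability.  Computed in log space for numerical stability; no
#' Monte Carlo, so the baseline contributes no sampling noise to SAI.
#'
#' @param occ an [OccurrenceMatrix-class].
#' @return an [AccumulationCurve-class] of kind `"random_expected"` (no site
#'   ordering: R_k is an expectation, not a selection).
#' @export
expectedRandomCurve <- function(occ) {
  stopifnot(is(occ, "OccurrenceMatrix"))
  ci <- unname(occupancy(occ))
  n <- nSites(occ)
  R <- vapply(seq_len(n), function(k) {
    # lchoose(N - c, k) = -Inf when k > N - c: species is certainly hit
    sum(1 - exp(lchoose(n - ci, k) - lchoose(n, k)))
  }, numeric(1))
  new("AccumulationCurve", sites = character(0), S = R, kind = "random_expected")
}

#' @rdname AccumulationCurve-class
#' @param x an [AccumulationCurve-class].
#' @export
setMethod("orderedSites", "AccumulationCurve", function(x) x@sites)

#' @rdname AccumulationCurve-class
#' @export
setMethod("cumulativeSpecies", "AccumulationCurve", function(x) x@S)

#' @rdname AccumulationCurve-class
#' @export
setMethod("curveKind", "AccumulationCurve", function(x) x@kind)

setMethod("show", "AccumulationCurve", function(object) {
  K <- length(object@S)
  cat(sprintf("AccumulationCurve (%s): %d steps, S_1 = %.3g, S_%d = %.3g\n",
              object@kind, K, object@S[1], K, object@S[K]))
})

#' Write an accumulation curve to CSV
#' @param curve an [AccumulationCurve-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCurve <- function(curve, path) {
  K <- length(curve@S)
  df <- data.frame(k = seq_len(K),
                   site_id = if (length(curve@sites)) curve@sites else NA_character_,
                   S_k = curve@S)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Species Accumulation Index of a surrogate ordering
#'
#' SAI_k = (S_k - R_k) / (O_k - R_k) compares the surrogate's representation
#' S against the optimal (O) and random (R) baselines at each evaluated set
#' size k, and averages over a set of top landscape fractions (default the
#' top 5\%, 10\%, ..., 50\% of sites — prioritization decisions concern
#' top-ranked land).  Steps where O and R are indistinguishable
#' (O_k - R_k < 1e-9) carry no signal and are skipped.
#'
#' @param surrogate [AccumulationCurve-class] of the score ranking.
#' @param optimal [AccumulationCurve-class] from [greedyOptimalCurve()] or
#'   [exactOptimalCurve()].
#' @param random [AccumulationCurve-class] from [expectedRandomCurve()].
#' @param fractions top fractions of the landscape to evaluate at
#'   (each mapped to k = round(fraction * N), minimum 1).
#' @param steps explicit integer step sizes k, overriding `fractions`.
#' @return a [SaiValue-class].
#' @examples
#' # a single step with S = 7, R = 4, O = 10 gives SAI = 0.5
#' @export
speciesAccumulationIndex <- function(surrogate, optimal, random,
                                     fractions = seq(0.05, 0.5, by = 0.05),
                                     steps = NULL) {
  stopifnot(is(surrogate, "AccumulationCurve"), is(optimal, "AccumulationCurve"),
            is(random, "AccumulationCurve"))
  n <- length(surrogate@S)
  if (length(random@S) != n)
    stop("surrogate and random curves cover different landscapes")
  if (length(optimal@S) < 1)
    stop("empty optimal curve")
  if (length(surrogate@sites) && length(optimal@sites) &&
      !setequal(surrogate@sites, optimal@sites))
    stop("surrogate and optimal curves cover different site sets")
  if (is.null(steps)) {
    stopifnot(all(fractions > 0), all(fractions <= 1))
    steps <- sort(unique(pmax(1L, as.integer(roundHalfUp(fractions * n)))))
  } else {
    steps <- sort(unique(as.integer(steps)))
  }
  if (any(steps > length(optimal@S)))
    stop("evaluation steps exceed the optimal curve's range")
  S <- surrogate@S[steps]
  O <- optimal@S[steps]
  R <- random@S[steps]
  ok <- (O - R) >= 1e-9
  if (!any(ok))
    stop("no evaluable steps: optimal and random baselines coincide everywhere")
  saiK <- (S[ok] - R[ok]) / (O[ok] - R[ok])
  names(saiK) <- steps[ok]
  new("SaiValue", saiK = saiK, meanSAI = mean(saiK), steps = as.integer(steps[ok]))
}

#' @rdname SaiValue-class
#' @param x a [SaiValue-class].
#' @export
setMethod("meanSAI", "SaiValue", function(x) x@meanSAI)

#' @rdname SaiValue-class
#' @export
setMethod("saiSteps", "SaiValue", function(x) x@steps)

setMethod("show", "SaiValue", function(object) {
  cat(sprintf("SAI = %.3f (mean over %d steps: k = %s)\n", object@meanSAI,
              length(object@steps), paste(object@steps, collapse = ", ")))
})

#' Monte-Carlo random accumulation baseline
#'
#' Empirical mean of S_k over `nDraws` uniformly sampled site orderings; a
#' cross-check for the analytic [expectedRandomCurve()], which should always
#' be preferred for SAI.
#'
#' @param occ an [OccurrenceMatrix-class].
#' @param nDraws number of random orderings.
#' @param seed integer seed.
#' @return an [AccumulationCurve-class] of kind `"random_expected"`.
#' @export
monteCarloRandomCurve <- function(occ, nDraws = 1000L, seed = 1L) {
  p <- presenceMatrix(occ)
  n <- nrow(p)
  acc <- withSeed(as.integer(seed), {
    total <- numeric(n)
    for (i in seq_len(nDraws))
      total <- total + cumulativeRepresentation(p, sample.int(n))
    total / nDraws
  })
  new("AccumulationCurve", sites = character(0), S = acc, kind = "random_expected")
}
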