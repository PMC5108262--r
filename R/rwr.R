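#' @include occurrence.R
NULL

#' Rarity weights: the inverse of each species' occupancy
#'
#' The rarity value of species i is 1 / c_i, where c_i is the number of sites
#' the species occupies *in the supplied matrix*.  When scoring an
#' inventoried subset of sites, pass the subset view: occupancy is then
#' counted within the subset only, which is all the information a planner
#' with a partial inventory has.  Species with no presences in the matrix are
#' omitted from the weights.
#'
#' @param occ an [OccurrenceMatrix-class] (full landscape or subset view).
#' @return a [RarityWeights-class] with one weight in (0, 1] per occupied
#'   species.
#' @examples
#' m <- matrix(c(1, 1, 1, 0, 1, 0, 0, 0), 4, 2,
#'             dimnames = list(paste0("s", 1:4), c("widespread", "rare")))
#' weightValues(rarityWeights(OccurrenceMatrix(m)))
#' @export
rarityWeights <- function(occ) {
  stopifnot(is(occ, "OccurrenceMatrix"))
  ci <- occupancy(occ)
  ci <- ci[ci > 0]
  new("RarityWeights", weights = 1 / ci, source = matrixFingerprint(presenceMatrix(occ)))
}

#' @rdname RarityWeights-class
#' @param x a [RarityWeights-class].
#' @export
setMethod("weightValues", "RarityWeights", function(x) x@weights)

setMethod("show", "RarityWeights", function(object) {
  cat("RarityWeights for", length(object@weights), "species;",
      sum(object@weights == 1), "single-site endemics\n")
})

#' Rarity-weighted richness of every site
#'
#' RWR(site) = sum of 1/c_i over the species present at the site.  Summed
#' over all sites, each species contributes c_i * (1/c_i) = 1, so total RWR
#' equals the number of occupied species — a useful conservation identity.
#' Sites with no recorded species score 0 and are retained.
#'
#' @param occ an [OccurrenceMatrix-class].
#' @param w rarity weights; defaults to [rarityWeights()] of `occ` itself.
#'   Supplying weights computed from a different matrix that lacks species
#'   present in `occ` is an error.
#' @return a [SiteScores-class] labelled `"RWR"`.
#' @examples
#' m <- diag(3); dimnames(m) <- list(paste0("s", 1:3), paste0("sp", 1:3))
#' scoreValues(computeRWR(OccurrenceMatrix(m)))  # three single-site endemics
#' @export
computeRWR <- function(occ, w = rarityWeights(occ)) {
  stopifnot(is(occ, "OccurrenceMatrix"), is(w, "RarityWeights"))
  p <- presenceMatrix(occ)
  present <- colnames(p)[colSums(p) > 0]
  unweighted <- setdiff(present, names(w@weights))
  if (length(unweighted))
    stop("species present in matrix but missing from weights: ",
         paste(utils::head(unweighted, 5), collapse = ", "))
  keep <- intersect(colnames(p), names(w@weights))
  scores <- as.numeric(p[, keep, drop = FALSE] %*% w@weights[keep])
  names(scores) <- rownames(p)
  new("SiteScores", scores = scores, label = "RWR")
}

#' @rdname SiteScores-class
#' @param x a [SiteScores-class].
#' @export
setMethod("scoreValues", "SiteScores", function(x) x@scores)

#' @rdname SiteScores-class
#' @export
setMethod("scoreLabel", "SiteScores", function(x) x@label)

setMethod("show", "SiteScores", function(object) {
  cat(sprintf("%s scores for %d sites: min %.4g, median %.4g, max %.4g\n",
              object@label, length(object@scores), min(object@scores),
              stats::median(object@scores), max(object@scores)))
})

#' Write site scores to CSV
#'
#' The header comment line records the score label and, when the source
#' matrix is given, its content fingerprint, so a score file can be traced
#' back to the incidence data it came from.
#'
#' @param scores a [SiteScores-class].
#' @param path output file.
#' @param occ optional source [OccurrenceMatrix-class] for provenance.
#' @return `path`, invisibly.
#' @export
writeScores <- function(scores, path, occ = NULL) {
  src <- if (is.null(occ)) "unspecified" else matrixFingerprint(presenceMatrix(occ))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# label=%s source=%s", scoreLabel(scores), src), con)
  utils::write.csv(data.frame(site_id = siteIDs(scores),
                              score = unname(scoreValues(scores))),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read site scores written by [writeScores()]
#' @param path CSV file path.
#' @return a [SiteScores-class].
#' @export
readScores <- function(path) {
  first <- readLines(path, n = 1L)
  label <- sub(".*label=(\\S+).*", "\\1", first)
  if (!label %in% c("RWR", "PRWR")) label <- "RWR"
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  scores <- df$score
  names(scores) <- as.character(df$site_id)
  new("SiteScores", scores = scores, label = label)
}
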