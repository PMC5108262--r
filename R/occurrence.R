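#' @include AllGenerics.R
NULL

#' Construct an OccurrenceMatrix
#'
#' @param presence numeric or logical site x species matrix; entries are
#'   coerced to 0/1.  Row names are site ids, column names are species ids.
#' @param sort sort sites and species lexicographically (the package-wide
#'   ordering convention; default TRUE).
#' @return an [OccurrenceMatrix-class].
#' @examples
#' m <- matrix(c(1, 0, 1, 1), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("spA", "spB")))
#' occ <- OccurrenceMatrix(m)
#' occupancy(occ)
#' @export
OccurrenceMatrix <- function(presence, sort = TRUE) {
  if (is.logical(presence)) storage.mode(presence) <- "numeric"
  presence <- as.matrix(presence)
  if (sort && !is.null(dimnames(presence)))
    presence <- presence[order(rownames(presence)), order(colnames(presence)),
                         drop = FALSE]
  new("OccurrenceMatrix", presence = presence)
}

#' Construct an EnvironmentTable
#'
#' @param values numeric site x variable matrix (or data.frame) with row
#'   names = site ids.
#' @param sort sort sites lexicographically (default TRUE); variable order is
#'   kept as given.
#' @return an [EnvironmentTable-class].
#' @export
EnvironmentTable <- function(values, sort = TRUE) {
  values <- as.matrix(values)
  storage.mode(values) <- "numeric"
  if (sort && !is.null(rownames(values)))
    values <- values[order(rownames(values)), , drop = FALSE]
  new("EnvironmentTable", values = values)
}

## ---- accessors -------------------------------------------------------------

#' @rdname OccurrenceMatrix-class
#' @export
setMethod("siteIDs", "OccurrenceMatrix", function(x) rownames(x@presence))
#' @rdname EnvironmentTable-class
#' @export
setMethod("siteIDs", "EnvironmentTable", function(x) rownames(x@values))
#' @rdname SiteScores-class
#' @export
setMethod("siteIDs", "SiteScores", function(x) names(x@scores))

#' @rdname OccurrenceMatrix-class
#' @export
setMethod("speciesIDs", "OccurrenceMatrix", function(x) colnames(x@presence))

#' @rdname OccurrenceMatrix-class
#' @export
setMethod("nSites", "OccurrenceMatrix", function(x) nrow(x@presence))
#' @rdname EnvironmentTable-class
#' @export
setMethod("nSites", "EnvironmentTable", function(x) nrow(x@values))

#' @rdname OccurrenceMatrix-class
#' @export
setMethod("presenceMatrix", "OccurrenceMatrix", function(x) x@presence)

#' Per-species occupancy counts c_i (column sums)
#' @rdname OccurrenceMatrix-class
#' @export
setMethod("occupancy", "OccurrenceMatrix", function(x) colSums(x@presence))

#' @rdname OccurrenceMatrix-class
#' @export
setMethod("siteRichness", "OccurrenceMatrix", function(x) rowSums(x@presence))

#' @rdname EnvironmentTable-class
#' @export
setMethod("envMatrix", "EnvironmentTable", function(x) x@values)

#' @rdname EnvironmentTable-class
#' @export
setMethod("variableNames", "EnvironmentTable", function(x) colnames(x@values))

#' Subset an OccurrenceMatrix by site and/or species
#'
#' Subsetting never re-sorts: a subset view keeps the parent's order, and may
#' contain all-zero species columns (occupancy is always recounted within the
#' view by downstream code).
#' @param x an [OccurrenceMatrix-class].
#' @param i,j site / species index or names.
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "OccurrenceMatrix", function(x, i, j, ..., drop = FALSE) {
  p <- x@presence
  if (!missing(i)) p <- p[i, , drop = FALSE]
  if (!missing(j)) p <- p[, j, drop = FALSE]
  OccurrenceMatrix(p, sort = FALSE)
})

#' @rdname EnvironmentTable-class
#' @param x an [EnvironmentTable-class].
#' @param i,j site / variable index or names.
#' @param drop,... ignored.
#' @export
setMethod("[", "EnvironmentTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  EnvironmentTable(v, sort = FALSE)
})

setMethod("show", "OccurrenceMatrix", function(object) {
  cat("OccurrenceMatrix:", nrow(object@presence), "sites x",
      ncol(object@presence), "species;",
      sum(object@presence), "presences\n")
  occ <- colSums(object@presence)
  cat("  occupancy c_i: min", min(occ), " median", stats::median(occ),
      " max", max(occ), "\n")
})

setMethod("show", "EnvironmentTable", function(object) {
  cat("EnvironmentTable:", nrow(object@values), "sites x",
      ncol(object@values), "variables\n")
})

setMethod("show", "SiteSplit", function(object) {
  cat(sprintf("SiteSplit: q = %g%%, %d inventoried / %d holdout (seed %d)\n",
              object@q, length(object@inventoried), length(object@holdout),
              object@seed))
})

## ---- loaders / writers -----------------------------------------------------

#' Read a site-by-species occurrence table from CSV
#'
#' Two layouts are supported.  Long format: columns `site_id,species_id`, one
#' record per row; duplicated records (typical of atlas data) collapse
#' silently to a single presence.  Wide format: a `site_id` column followed
#' by one 0/1 column per species.  Site and species ids are sorted
#' lexicographically on load so downstream results never depend on file row
#' order.
#'
#' @param path CSV file path.
#' @param format `"long"` or `"wide"`.
#' @return an [OccurrenceMatrix-class].
#' @seealso [writeOccurrences()]
#' @export
readOccurrences <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  if (nrow(df) == 0L) stop("no occurrence records in ", path)
  if (format == "long") {
    if (!all(c("site_id", "species_id") %in% names(df)))
      stop("long format requires columns site_id,species_id")
    sites <- sort(unique(as.character(df$site_id)))
    spp <- sort(unique(as.character(df$species_id)))
    p <- matrix(0, length(sites), length(spp), dimnames = list(sites, spp))
    p[cbind(as.character(df$site_id), as.character(df$species_id))] <- 1
    OccurrenceMatrix(p, sort = FALSE)
  } else {
    if (names(df)[1] != "site_id") stop("wide format requires first column site_id")
    p <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(p) <- "numeric"
    if (anyNA(p) || !all(p %in% c(0, 1)))
      stop("wide format entries must all be 0 or 1")
    rownames(p) <- as.character(df$site_id)
    OccurrenceMatrix(p)
  }
}

#' Write an OccurrenceMatrix to CSV
#'
#' @param occ an [OccurrenceMatrix-class].
#' @param path output file.
#' @param format `"long"` or `"wide"` (see [readOccurrences()]).
#' @return `path`, invisibly.
#' @export
writeOccurrences <- function(occ, path, format = c("long", "wide")) {
  format <- match.arg(format)
  p <- presenceMatrix(occ)
  if (format == "long") {
    idx <- which(p == 1, arr.ind = TRUE)
    df <- data.frame(site_id = rownames(p)[idx[, 1]],
                     species_id = colnames(p)[idx[, 2]])
    df <- df[order(df$site_id, df$species_id), ]
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(site_id = rownames(p), p, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a site-by-variable environment table from CSV
#'
#' Expects a `site_id` column followed by one numeric column per variable;
#' missing or non-finite values are a hard error.
#'
#' @param path CSV file path.
#' @return an [EnvironmentTable-class].
#' @export
readEnvironment <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        check.names = FALSE)
  if (nrow(df) == 0L) stop("no environment rows in ", path)
  if (names(df)[1] != "site_id") stop("environment CSV requires first column site_id")
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "numeric"
  rownames(v) <- as.character(df$site_id)
  EnvironmentTable(v)
}

#' Write an EnvironmentTable to CSV
#' @param env an [EnvironmentTable-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeEnvironment <- function(env, path) {
  v <- envMatrix(env)
  df <- data.frame(site_id = rownames(v), v, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- alignment and splitting ----------------------------------------------

#' Align occurrence and environment tables on their common sites
#'
#' Every occurrence site must have an environment row (the covariates are
#' assumed known landscape-wide); environment-only sites are dropped.  Both
#' outputs share the occurrence matrix's site order.
#'
#' @param occ an [OccurrenceMatrix-class].
#' @param env an [EnvironmentTable-class].
#' @return a list with elements `occ` and `env`, restricted to common sites
#'   in identical order.
#' @export
alignSites <- function(occ, env) {
  missing <- setdiff(siteIDs(occ), siteIDs(env))
  if (length(missing))
    stop("occurrence sites missing from environment table: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)", length(missing) - 10))
  list(occ = occ, env = env[siteIDs(occ), ])
}

#' Draw a q% inventoried / holdout split of the sites
#'
#' Mimics the planning situation in which species inventories exist for a
#' random q\% of the planning units and the rest of the landscape is known
#' only through its environment.  The inventoried set is a simple random
#' sample without replacement of round(qN/100) sites (round-half-up),
#' reproducible under `seed`.
#'
#' @param occ an [OccurrenceMatrix-class].
#' @param q percentage of sites to inventory, in (0, 100].
#' @param seed integer seed.
#' @return a [SiteSplit-class].
#' @export
sampleSplit <- function(occ, q, seed) {
  stopifnot(q > 0, q <= 100)
  sites <- siteIDs(occ)
  n <- length(sites)
  if (n < 5) stop("need at least 5 sites to split")
  k <- roundHalfUp(q * n / 100)
  if (k < 2) stop(sprintf("q = %g%% of %d sites gives %d inventoried sites; need >= 2",
                          q, n, k))
  inv <- withSeed(as.integer(seed), sort(sample(sites, k)))
  new("SiteSplit", inventoried = inv, holdout = setdiff(sites, inv),
      q = q, seed = as.integer(seed))
}
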