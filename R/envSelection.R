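#' @include occurrence.R
NULL

#' Correlation-matrix PCA of the environmental variable pool
#'
#' Variables are z-standardized before the decomposition (they mix units —
#' degrees, millimetres, unitless indices — and the Kaiser retention rule
#' presupposes unit-variance inputs).  Components with eigenvalue strictly
#' greater than 1 are retained as the significant environmental gradients;
#' if none exceeds 1 the leading component is kept so downstream selection
#' always has at least one gradient to work with.
#'
#' @param env an [EnvironmentTable-class] with at least two variables.
#' @return a [PcaResult-class].
#' @export
pcaFactors <- function(env) {
  stopifnot(is(env, "EnvironmentTable"))
  v <- envMatrix(env)
  if (ncol(v) < 2) stop("PCA needs at least 2 variables")
  vars <- apply(v, 2, stats::var)
  if (any(vars == 0))
    stop("zero-variance variable(s): ",
         paste(colnames(v)[vars == 0], collapse = ", "))
  fit <- stats::prcomp(v, center = TRUE, scale. = TRUE)
  ev <- fit$sdev^2
  nr <- sum(ev > 1)
  if (nr < 1L) nr <- 1L
  new("PcaResult", eigenvalues = ev, scores = fit$x, loadings = fit$rotation,
      nRetained = as.integer(nr))
}

#' @rdname PcaResult-class
#' @param x a [PcaResult-class].
#' @export
setMethod("eigenvalues", "PcaResult", function(x) x@eigenvalues)

#' @rdname PcaResult-class
#' @export
setMethod("nRetained", "PcaResult", function(x) x@nRetained)

setMethod("show", "PcaResult", function(object) {
  cat("PcaResult:", length(object@eigenvalues), "components,",
      object@nRetained, "retained (eigenvalue > 1)\n")
  cat("  leading eigenvalues:",
      paste(sprintf("%.2f", utils::head(object@eigenvalues, 6)), collapse = ", "),
      "\n")
})

#' Pick one representative variable per retained component
#'
#' For each retained component, the variable with the largest absolute
#' Pearson correlation with that component's scores is chosen (under
#' standardization this is equivalent to picking the max-|loading|
#' variable).  A variable can represent only one gradient: if the same
#' variable wins two components it is kept for the component where its |r|
#' is larger and the runner-up variable takes the other; remaining ties are
#' broken lexicographically by variable name.
#'
#' @param env the [EnvironmentTable-class] the PCA was computed from.
#' @param pca the matching [PcaResult-class].
#' @return a [PredictorSet-class] with exactly `nRetained(pca)` variables.
#' @export
selectPredictors <- function(env, pca) {
  stopifnot(is(env, "EnvironmentTable"), is(pca, "PcaResult"))
  v <- envMatrix(env)
  nr <- nRetained(pca)
  if (ncol(v) < nr)
    stop("fewer variables than retained components")
  if (nrow(pca@scores) != nrow(v))
    stop("PCA was not computed from this environment table")
  # |r| matrix: variables x retained components; lexicographic variable order
  # makes the which.max tie-break deterministic.
  ord <- order(colnames(v))
  r <- abs(stats::cor(v[, ord, drop = FALSE],
                      pca@scores[, seq_len(nr), drop = FALSE]))
  vnames <- colnames(v)[ord]
  chosen <- rep(NA_character_, nr)
  corr <- rep(NA_real_, nr)
  pending <- seq_len(nr)
  while (length(pending)) {
    # best available variable for each pending component
    best <- vapply(pending, function(j) vnames[which.max(r[, j])], character(1))
    bestr <- vapply(pending, function(j) max(r[, j]), numeric(1))
    for (var in unique(best)) {
      comps <- pending[best == var]
      # a duplicate winner goes to the component where it correlates hardest
      win <- comps[which.max(bestr[match(comps, pending)])]
      chosen[win] <- var
      corr[win] <- r[var, win]
    }
    taken <- stats::na.omit(chosen)
    r[taken, ] <- -Inf
    pending <- which(is.na(chosen))
  }
  new("PredictorSet", selected = chosen, component = seq_len(nr),
      absCorrelation = corr)
}

#' @rdname PredictorSet-class
#' @param x a [PredictorSet-class].
#' @export
setMethod("selectedVariables", "PredictorSet", function(x) x@selected)

setMethod("show", "PredictorSet", function(object) {
  cat("PredictorSet:", length(object@selected), "variables\n")
  for (i in seq_along(object@selected))
    cat(sprintf("  PC%d -> %s (|r| = %.3f)\n", object@component[i],
                object@selected[i], object@absCorrelation[i]))
})

#' Write a PredictorSet to CSV
#' @param ps a [PredictorSet-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePredictors <- function(ps, path) {
  utils::write.csv(data.frame(component = ps@component, variable = ps@selected,
                              abs_correlation = ps@absCorrelation),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
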