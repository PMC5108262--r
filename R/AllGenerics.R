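#' @include AllClasses.R
NULL

#' @rdname OccurrenceMatrix-class
#' @param object,x an object.
#' @export
setGeneric("siteIDs", function(x) standardGeneric("siteIDs"))

#' @rdname OccurrenceMatrix-class
#' @export
setGeneric("speciesIDs", function(x) standardGeneric("speciesIDs"))

#' @rdname OccurrenceMatrix-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname OccurrenceMatrix-class
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname OccurrenceMatrix-class
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))

#' @rdname OccurrenceMatrix-class
#' @export
setGeneric("siteRichness", function(x) standardGeneric("siteRichness"))

#' @rdname EnvironmentTable-class
#' @export
setGeneric("envMatrix", function(x) standardGeneric("envMatrix"))

#' @rdname EnvironmentTable-class
#' @export
setGeneric("variableNames", function(x) standardGeneric("variableNames"))

#' @rdname SiteScores-class
#' @export
setGeneric("scoreValues", function(x) standardGeneric("scoreValues"))

#' @rdname SiteScores-class
#' @export
setGeneric("scoreLabel", function(x) standardGeneric("scoreLabel"))

#' @rdname RarityWeights-class
#' @export
setGeneric("weightValues", function(x) standardGeneric("weightValues"))

#' @rdname PcaResult-class
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname PcaResult-class
#' @export
setGeneric("nRetained", function(x) standardGeneric("nRetained"))

#' @rdname PredictorSet-class
#' @export
setGeneric("selectedVariables", function(x) standardGeneric("selectedVariables"))

#' @rdname RwrForest-class
#' @export
setGeneric("oobMSE", function(x) standardGeneric("oobMSE"))

#' @rdname RwrForest-class
#' @export
setGeneric("oobR2", function(x) standardGeneric("oobR2"))

#' @rdname AccumulationCurve-class
#' @export
setGeneric("orderedSites", function(x) standardGeneric("orderedSites"))

#' @rdname AccumulationCurve-class
#' @export
setGeneric("cumulativeSpecies", function(x) standardGeneric("cumulativeSpecies"))

#' @rdname AccumulationCurve-class
#' @export
setGeneric("curveKind", function(x) standardGeneric("curveKind"))

#' @rdname SaiValue-class
#' @export
setGeneric("meanSAI", function(x) standardGeneric("meanSAI"))

#' @rdname SaiValue-class
#' @export
setGeneric("saiSteps", function(x) standardGeneric("saiSteps"))

#' @rdname SaiSummary-class
#' @export
setGeneric("saiReplicates", function(x) standardGeneric("saiReplicates"))
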