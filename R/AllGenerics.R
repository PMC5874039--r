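#' Variable names of a climate object
#' @param x a ClimateGrid or ClimateStack.
#' @return character vector of variable names in storage order.
#' @export
setGeneric("varNames", function(x) standardGeneric("varNames"))

#' Ages (kyr BP) present in a stack
#' @param x a ClimateStack.
#' @return sorted integer vector of slice ages.
#' @export
setGeneric("ages", function(x) standardGeneric("ages"))

#' Extract one slice from a ClimateStack
#' @param x a ClimateStack.
#' @param age integer kyr BP.
#' @return the \linkS4class{ClimateGrid} at that age.
#' @export
setGeneric("getSlice", function(x, age) standardGeneric("getSlice"))

#' Species label of an object
#' @param x an OccurrenceSet, VirtualSpecies or SuitabilityMap.
#' @return character(1) species id.
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' Point coordinates of a point set
#' @param x an OccurrenceSet or BackgroundSet.
#' @return data.frame with columns lon, lat.
#' @export
setGeneric("occPoints", function(x) standardGeneric("occPoints"))

#' Algorithm label of a model or map
#' @param x a NicheModel or SuitabilityMap.
#' @return character(1): "maxent", "glm" or "rf".
#' @export
setGeneric("algorithm", function(x) standardGeneric("algorithm"))

#' Suitability values of a map
#' @param x a SuitabilityMap.
#' @return numeric matrix in [0, 1] with NA on nodata.
#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' Predict suitability for environmental vectors
#'
#' Returns suitabilities in [0, 1] for arbitrary (including extrapolated)
#' environments.  With \code{clamp = TRUE} (default) each variable is first
#' truncated to the model's training range.
#'
#' @param model a fitted \linkS4class{NicheModel}.
#' @param env data.frame or matrix with the model's variables as columns.
#' @param clamp logical; truncate env to the training range before
#'   predicting.
#' @return numeric vector of suitabilities in [0, 1].
#' @export
setGeneric("predictSuitability",
  function(model, env, clamp = TRUE) standardGeneric("predictSuitability"))

#' Headline species of an assignment report
#' @param x an AssignmentReport.
#' @return character(1): the top-ranked plausible species or "indeterminate".
#' @export
setGeneric("headline", function(x) standardGeneric("headline"))

#' Per-candidate evidence table of an assignment report
#' @param x an AssignmentReport.
#' @return data.frame with one row per candidate and algorithm.
#' @export
setGeneric("perCandidate", function(x) standardGeneric("perCandidate"))
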