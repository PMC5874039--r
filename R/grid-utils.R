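# Geometry helpers shared by grids and maps.  Convention: WGS84 lon/lat,
# row 1 is the northern row, column 1 the western column; origin is the
# north-west corner; cells are half-open intervals [edge, edge + cellSize).

gridDim <- function(x)
  if (is(x, "SuitabilityMap")) dim(x@values) else dim(x@mask)

`%||%` <- function(a, b) if (is.null(a)) b else a

# containing-cell lookup; returns matrix with columns row, col (NA off-grid)
cellRowCol <- function(origin, cellSize, dm, lon, lat) {
  col <- floor((lon - origin[1]) / cellSize) + 1
  row <- floor((origin[2] - lat) / cellSize) + 1
  bad <- col < 1 | col > dm[2] | row < 1 | row > dm[1]
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

cellCenters <- function(origin, cellSize, rc) {
  cbind(lon = origin[1] + (rc[, "col"] - 0.5) * cellSize,
        lat = origin[2] - (rc[, "row"] - 0.5) * cellSize)
}

# linear index (column-major, as R matrices) from row/col
cellLinear <- function(dm, rc) (rc[, "col"] - 1L) * dm[1] + rc[, "row"]

linearToRowCol <- function(dm, idx) {
  cbind(row = ((idx - 1L) %% dm[1]) + 1L,
        col = ((idx - 1L) %/% dm[1]) + 1L)
}

# environment matrix (cells x variables) over all cells of a ClimateGrid
gridEnvMatrix <- function(grid) {
  vapply(grid@variables, as.vector, numeric(length(grid@mask)))
}

#' @describeIn varNames variable names of a single slice
#' @export
setMethod("varNames", "ClimateGrid", function(x) names(x@variables))

#' @describeIn varNames variable names shared by all slices of a stack
#' @export
setMethod("varNames", "ClimateStack",
  function(x) names(x@slices[[1L]]@variables))

#' @rdname ages
#' @export
setMethod("ages", "ClimateStack",
  function(x) sort(vapply(x@slices, function(g) g@age, integer(1))))

#' @rdname getSlice
#' @export
setMethod("getSlice", "ClimateStack", function(x, age) {
  key <- as.character(as.integer(age))
  if (is.null(x@slices[[key]]))
    stop(sprintf("no slice at %s kyr BP; available: %s", key,
                 paste(ages(x), collapse = ", ")))
  x@slices[[key]]
})

#' @rdname speciesId
#' @export
setMethod("speciesId", "OccurrenceSet", function(x) x@speciesId)

#' @rdname speciesId
#' @export
setMethod("speciesId", "VirtualSpecies", function(x) x@speciesId)

#' @rdname speciesId
#' @export
setMethod("speciesId", "SuitabilityMap", function(x) x@speciesId)

#' @rdname occPoints
#' @export
setMethod("occPoints", "OccurrenceSet", function(x) x@points)

#' @rdname occPoints
#' @export
setMethod("occPoints", "BackgroundSet", function(x) x@points)

#' @rdname algorithm
#' @export
setMethod("algorithm", "NicheModel", function(x) x@algorithm)

#' @rdname algorithm
#' @export
setMethod("algorithm", "SuitabilityMap", function(x) x@algorithm)

#' @rdname mapValues
#' @export
setMethod("mapValues", "SuitabilityMap", function(x) x@values)

#' @rdname headline
#' @export
setMethod("headline", "AssignmentReport", function(x) x@headline)

#' @rdname perCandidate
#' @export
setMethod("perCandidate", "AssignmentReport", function(x) x@perCandidate)

setMethod("show", "ClimateGrid", function(object) {
  dm <- dim(object@mask)
  cat(sprintf("ClimateGrid: %d x %d cells, %d variable(s), %d kyr BP\n",
              dm[1], dm[2], length(object@variables), object@age))
  cat(sprintf("  variables: %s\n", paste(names(object@variables),
                                         collapse = ", ")))
  cat(sprintf("  origin (%.3f, %.3f), cell %.4f deg, %d valid cells\n",
              object@origin[1], object@origin[2], object@cellSize,
              sum(object@mask)))
})

setMethod("show", "ClimateStack", function(object) {
  a <- ages(object)
  cat(sprintf("ClimateStack: %d slice(s), %s kyr BP, variables: %s\n",
              length(a), paste(range(a), collapse = "-"),
              paste(varNames(object), collapse = ", ")))
})

setMethod("show", "OccurrenceSet", function(object) {
  cat(sprintf("OccurrenceSet '%s': %d point(s)\n", object@speciesId,
              nrow(object@points)))
  if (length(object@provenance))
    cat(paste0("  ", object@provenance, collapse = "\n"), "\n")
})

setMethod("show", "NicheModel", function(object) {
  ts <- object@trainingSummary
  cat(sprintf("NicheModel [%s] on %s\n", object@algorithm,
              paste(object@variables, collapse = ", ")))
  cat(sprintf("  %s presences vs %s %s points\n",
              ts$nPresence %||% "?", ts$nContrast %||% "?",
              ts$contrastMode %||% "contrast"))
})

setMethod("show", "SuitabilityMap", function(object) {
  cat(sprintf("SuitabilityMap '%s' [%s] at %d kyr BP: %d x %d cells\n",
              object@speciesId, object@algorithm, object@age,
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "EvaluationResult", function(object) {
  cat(sprintf(
    "EvaluationResult: %d reps (split %.2f): AUC %.3f +/- %.3f, TSS %.3f +/- %.3f\n",
    object@nReps, object@splitFraction, object@meanAuc, object@sdAuc,
    object@meanTss, object@sdTss))
})

setMethod("show", "AssignmentReport", function(object) {
  cat(sprintf("AssignmentReport for fossil '%s' (slices %s kyr BP)\n",
              object@fossilId,
              paste(object@slicesEvaluated, collapse = ", ")))
  cat(sprintf("  headline: %s\n", object@headline))
  if (length(object@ranking))
    cat(sprintf("  plausible ranking: %s\n",
                paste(object@ranking, collapse = " > ")))
  print(object@perCandidate)
})

setMethod("show", "VirtualSpecies", function(object) {
  cat(sprintf("VirtualSpecies '%s' (max suitability %.2f)\n",
              object@speciesId, object@maxSuitability))
  print(rbind(center = object@nicheCenter, width = object@nicheWidth))
})
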