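#' @import methods
NULL

#' ClimateGrid: one multi-variable climate raster slice
#'
#' A set of named 2-D grids (one per bioclimatic variable) sharing a single
#' geometry and nodata mask, representing the climate at one age.  Rows run
#' north to south, columns west to east; the geotransform is the longitude of
#' the west edge, the latitude of the north edge, and a square cell size in
#' decimal degrees (WGS84 lon/lat).
#'
#' @slot variables named list of numeric matrices, one per variable
#'   (temperatures in degrees C, precipitations in mm).
#' @slot mask logical matrix; \code{TRUE} marks valid cells, \code{FALSE}
#'   nodata.
#' @slot origin numeric(2): lon of the west edge, lat of the north edge.
#' @slot cellSize positive cell size in decimal degrees.
#' @slot age integer age of the slice in kyr BP (0 = present).
#' @exportClass ClimateGrid
setClass("ClimateGrid",
  representation(
    variables = "list",
    mask      = "matrix",
    origin    = "numeric",
    cellSize  = "numeric",
    age       = "integer"
  )
)

setValidity("ClimateGrid", function(object) {
  msgs <- character(0)
  if (length(object@variables) < 1L)
    msgs <- c(msgs, "at least one variable grid is required")
  if (is.null(names(object@variables)) || any(!nzchar(names(object@variables))))
    msgs <- c(msgs, "variables must be named")
  dm <- dim(object@mask)
  for (nm in names(object@variables)) {
    v <- object@variables[[nm]]
    if (!is.matrix(v) || !identical(dim(v), dm))
      msgs <- c(msgs, sprintf("variable '%s' does not match the mask shape", nm))
  }
  if (length(object@origin) != 2L)
    msgs <- c(msgs, "origin must be numeric(2): c(lon_west, lat_north)")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@age) != 1L || is.na(object@age) || object@age < 0L)
    msgs <- c(msgs, "age must be a single non-negative integer (kyr BP)")
  if (length(msgs)) msgs else TRUE
})

#' ClimateStack: a time-indexed stack of ClimateGrid slices
#'
#' Slices at 1-kyr resolution, keyed by integer age (kyr BP).  All slices
#' share geometry and variable names.
#'
#' @slot slices named list of \linkS4class{ClimateGrid}; names are the ages
#'   as characters ("0", "1", ...).
#' @exportClass ClimateStack
setClass("ClimateStack", representation(slices = "list"))

setValidity("ClimateStack", function(object) {
  if (length(object@slices) < 1L) return("a stack needs at least one slice")
  g0 <- object@slices[[1L]]
  for (g in object@slices) {
    if (!is(g, "ClimateGrid")) return("all slices must be ClimateGrid objects")
    if (!identical(dim(g@mask), dim(g0@mask)) ||
        !isTRUE(all.equal(g@origin, g0@origin)) ||
        !isTRUE(all.equal(g@cellSize, g0@cellSize)))
      return("all slices must share the same geometry")
    if (!identical(names(g@variables), names(g0@variables)))
      return("all slices must share the same variable names")
  }
  ages <- vapply(object@slices, function(g) g@age, integer(1))
  if (!identical(names(object@slices), as.character(ages)))
    return("slice names must equal their ages in kyr BP")
  TRUE
})

#' OccurrenceSet: cleaned presence points for one species
#'
#' @slot speciesId species label.
#' @slot points data.frame with columns \code{lon}, \code{lat}.
#' @slot provenance free-text audit trail (source, cleaning counts).
#' @exportClass OccurrenceSet
setClass("OccurrenceSet",
  representation(speciesId = "character", points = "data.frame",
                 provenance = "character")
)

setValidity("OccurrenceSet", function(object) {
  if (length(object@speciesId) != 1L) return("speciesId must be length 1")
  if (!all(c("lon", "lat") %in% names(object@points)))
    return("points needs 'lon' and 'lat' columns")
  TRUE
})

#' BackgroundSet: background or pseudo-absence points
#'
#' @slot points data.frame with columns \code{lon}, \code{lat}.
#' @slot mode "background" (presence-background models) or "pseudo-absence"
#'   (presence/absence classifiers; never overlaps the species' cells).
#' @slot excludedSpecies species whose occupied cells were excluded
#'   (pseudo-absence mode), otherwise \code{NA}.
#' @exportClass BackgroundSet
setClass("BackgroundSet",
  representation(points = "data.frame", mode = "character",
                 excludedSpecies = "character")
)

setValidity("BackgroundSet", function(object) {
  if (!object@mode %in% c("background", "pseudo-absence"))
    return("mode must be 'background' or 'pseudo-absence'")
  TRUE
})

#' NicheModel: a fitted suitability model
#'
#' One of three algorithms: a presence-background maximum-entropy model
#' (linear + quadratic features, L1 penalty), a binomial logistic GLM
#' (linear + quadratic terms), or a random forest classifier.  Predictions
#' are suitabilities in [0, 1] and deterministic once fitted.
#'
#' @slot algorithm one of "maxent", "glm", "rf".
#' @slot variables ordered variable names the model was trained on.
#' @slot fit algorithm-specific fitted values (weights, scaling, reference
#'   ranges for clamping, the training environment for MESS).
#' @slot trainingSummary counts, settings and seed used for training.
#' @exportClass NicheModel
setClass("NicheModel",
  representation(algorithm = "character", variables = "character",
                 fit = "list", trainingSummary = "list")
)

setValidity("NicheModel", function(object) {
  if (!object@algorithm %in% c("maxent", "glm", "rf"))
    return("algorithm must be one of 'maxent', 'glm', 'rf'")
  if (length(object@variables) < 1L) return("at least one variable required")
  TRUE
})

#' SuitabilityMap: a predicted suitability surface
#'
#' @slot values numeric matrix in [0, 1]; NA on nodata cells.
#' @slot origin,cellSize geometry shared with the source climate grid.
#' @slot age kyr BP of the projected climate.
#' @slot speciesId,algorithm provenance stamps.
#' @exportClass SuitabilityMap
setClass("SuitabilityMap",
  representation(values = "matrix", origin = "numeric", cellSize = "numeric",
                 age = "integer", speciesId = "character",
                 algorithm = "character")
)

setValidity("SuitabilityMap", function(object) {
  v <- object@values[!is.na(object@values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    return("suitability values must lie in [0, 1]")
  TRUE
})

#' FossilRecord: a dated, georeferenced fossil specimen
#'
#' @slot fossilId specimen label.
#' @slot lon,lat WGS84 coordinates.
#' @slot ageMinBP,ageMaxBP calibrated age interval in years BP
#'   (ageMinBP < ageMaxBP).
#' @slot candidates candidate species labels; empty means the identity is
#'   known and the record is used in validation mode.
#' @exportClass FossilRecord
setClass("FossilRecord",
  representation(fossilId = "character", lon = "numeric", lat = "numeric",
                 ageMinBP = "numeric", ageMaxBP = "numeric",
                 candidates = "character")
)

setValidity("FossilRecord", function(object) {
  if (!(object@ageMinBP < object@ageMaxBP))
    return("ageMinBP must be strictly less than ageMaxBP")
  TRUE
})

#' EvaluationResult: repeated-split cross-validation metrics
#'
#' @slot perRep data.frame with one row per repetition: \code{auc},
#'   \code{tss}, \code{threshold} (the TSS-maximizing threshold).
#' @slot meanAuc,sdAuc,meanTss,sdTss aggregates over repetitions.
#' @slot nReps,splitFraction,seed,nSkipped evaluation settings and the count
#'   of repetitions skipped because their fit failed.
#' @exportClass EvaluationResult
setClass("EvaluationResult",
  representation(perRep = "data.frame", meanAuc = "numeric", sdAuc = "numeric",
                 meanTss = "numeric", sdTss = "numeric", nReps = "integer",
                 splitFraction = "numeric", seed = "integer",
                 nSkipped = "integer")
)

setValidity("EvaluationResult", function(object) {
  if (nrow(object@perRep) != object@nReps)
    return("nReps must equal the number of per-repetition rows")
  if (any(object@perRep$auc < 0 | object@perRep$auc > 1))
    return("AUC values must lie in [0, 1]")
  if (any(object@perRep$tss < -1 | object@perRep$tss > 1))
    return("TSS values must lie in [-1, 1]")
  TRUE
})

#' MessResult: non-analogue climate diagnostics
#'
#' Multivariate environmental similarity surface (MESS), the most dissimilar
#' variable (MoD) and the clamping mask of a projection grid against a
#' reference environment.
#'
#' @slot mess numeric matrix of similarity values (percent-like; negative
#'   exactly where some variable falls outside the reference range).
#' @slot mod integer matrix of 1-based indices of the most dissimilar
#'   variable (lowest index on ties); NA on nodata.
#' @slot clampingMask logical matrix, TRUE where any variable lies outside
#'   the reference range.
#' @slot referenceRanges numeric matrix with rows "min"/"max", one column per
#'   variable.
#' @exportClass MessResult
setClass("MessResult",
  representation(mess = "matrix", mod = "matrix", clampingMask = "matrix",
                 referenceRanges = "matrix")
)

#' AssignmentReport: suitability-based candidate ranking for a fossil
#'
#' @slot fossilId fossil label.
#' @slot slicesEvaluated kyr ages the fossil interval mapped to.
#' @slot perCandidate one row per candidate: species, algorithm, per-slice
#'   suitability, the aggregate suitability S, the minimum present-day
#'   occurrence suitability m, the plausibility flag (S >= m) and the ratio
#'   S/m.
#' @slot ranking plausible species ordered by S, descending.
#' @slot headline the top-ranked plausible species, or "indeterminate" when
#'   none is plausible or the top two are within the tie tolerance.
#' @slot diagnostics MESS value and clamping status at the fossil cell per
#'   candidate and slice.
#' @exportClass AssignmentReport
setClass("AssignmentReport",
  representation(fossilId = "character", slicesEvaluated = "numeric",
                 perCandidate = "data.frame", ranking = "character",
                 headline = "character", diagnostics = "data.frame")
)

#' VirtualSpecies: a simulated species with a known Gaussian niche
#'
#' True suitability is a product of Gaussian responses, one per climate
#' variable: \code{maxSuitability * exp(-0.5 * sum(((env - center)/width)^2))}.
#'
#' @slot speciesId species label.
#' @slot nicheCenter named optimum, one value per climate variable (variable
#'   units).
#' @slot nicheWidth strictly positive niche breadths (same units).
#' @slot maxSuitability suitability at the optimum, in (0, 1].
#' @exportClass VirtualSpecies
setClass("VirtualSpecies",
  representation(speciesId = "character", nicheCenter = "numeric",
                 nicheWidth = "numeric", maxSuitability = "numeric")
)

setValidity("VirtualSpecies", function(object) {
  if (length(object@nicheCenter) != length(object@nicheWidth))
    return("nicheCenter and nicheWidth must have the same length")
  if (any(object@nicheWidth <= 0))
    return("nicheWidth must be strictly positive in every dimension")
  if (object@maxSuitability <= 0 || object@maxSuitability > 1)
    return("maxSuitability must lie in (0, 1]")
  TRUE
})

#' ScenarioSpec: a virtual-species / paleoclimate simulation scenario
#'
#' Defines the grid geometry, the number of 1-kyr slices, the per-variable
#' climate drift going back in time, the target inter-variable correlation,
#' the virtual species, and the per-species occurrence sample size.
#'
#' @slot nrow,ncol grid dimensions (at least 4 cells in total).
#' @slot origin,cellSize geotransform (lon west edge, lat north edge; cell
#'   size in decimal degrees).
#' @slot nSlices number of 1-kyr slices (ages 0 .. nSlices-1).
#' @slot drift named per-variable mean shift per kyr going backwards
#'   (variable units / kyr).
#' @slot interVariableCorrelation target pairwise correlation among the
#'   climate fields, in [-1, 1].
#' @slot variableMeans,variableSds named present-day field means and spatial
#'   standard deviations.
#' @slot precipVars names of variables clipped at 0 (precipitation-like).
#' @slot species list of \linkS4class{VirtualSpecies}.
#' @slot nOccurrences per-species occurrence sample size.
#' @slot nodataBorder width (cells) of a rectangular nodata border, 0 for
#'   none.
#' @slot seed default RNG seed for operations on this scenario.
#' @exportClass ScenarioSpec
setClass("ScenarioSpec",
  representation(nrow = "integer", ncol = "integer", origin = "numeric",
                 cellSize = "numeric", nSlices = "integer", drift = "numeric",
                 interVariableCorrelation = "numeric",
                 variableMeans = "numeric", variableSds = "numeric",
                 precipVars = "character", species = "list",
                 nOccurrences = "integer", nodataBorder = "integer",
                 seed = "integer")
)

setValidity("ScenarioSpec", function(object) {
  msgs <- character(0)
  if (object@nrow < 1L || object@ncol < 1L)
    msgs <- c(msgs, "grid dimensions must be positive")
  if (object@nrow * object@ncol < 4L)
    msgs <- c(msgs, "grid must have at least 4 cells")
  if (object@nSlices < 1L) msgs <- c(msgs, "nSlices must be >= 1")
  if (object@nOccurrences < 1L) msgs <- c(msgs, "nOccurrences must be >= 1")
  if (abs(object@interVariableCorrelation) > 1)
    msgs <- c(msgs, "interVariableCorrelation must lie in [-1, 1]")
  vn <- names(object@variableMeans)
  if (!identical(vn, names(object@variableSds)) ||
      !identical(vn, names(object@drift)))
    msgs <- c(msgs, "variableMeans, variableSds and drift must share names")
  for (sp in object@species) {
    if (!is(sp, "VirtualSpecies"))
      msgs <- c(msgs, "species must be VirtualSpecies objects")
    else if (!identical(names(sp@nicheCenter), vn))
      msgs <- c(msgs, sprintf(
        "species '%s' niche dimensions must match the scenario variables",
        sp@speciesId))
  }
  if (length(msgs)) msgs else TRUE
})
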