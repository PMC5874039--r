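# Fossil-based model validation and taxonomic assignment: compare hindcast
# suitability at a fossil's location and age against each candidate
# species' minimum present-day occurrence suitability.

#' Map a calibrated age interval to climate-stack slices
#'
#' Returns the 1-kyr slices spanned by the interval, from
#' \code{floor(ageMinBP/1000)} to \code{round(ageMaxBP/1000)} kyr BP,
#' intersected with the available ages.  When no available slice falls in
#' that span, the single nearest slice (by distance to the interval
#' midpoint) is returned, so the result is never empty.
#'
#' @param interval numeric(2): calibrated (ageMinBP, ageMaxBP) in years BP.
#' @param available integer ages (kyr BP) present in the stack.
#' @return integer vector of kyr ages, ascending.
#' @examples
#' slicesForAge(c(13898, 13941), 0:130)  # 13 and 14
#' slicesForAge(c(11068, 11211), 0:130)  # 11
#' @export
slicesForAge <- function(interval, available) {
  if (length(available) < 1L) stop("no available slices")
  stopifnot(length(interval) == 2L, interval[1] < interval[2])
  available <- sort(as.integer(available))
  lo <- floor(interval[1] / 1000)
  hi <- round(interval[2] / 1000)
  hit <- available[available >= lo & available <= hi]
  if (length(hit)) return(hit)
  mid <- mean(interval) / 1000
  available[which.min(abs(available - mid))]
}

#' Minimum present-day suitability over a species' occurrences
#'
#' The minimum of the model's predicted suitability at every occurrence
#' point, extracted from the present-day (0 kyr) projection.  This value is
#' the species' plausibility floor: a fossil location is considered
#' climatically plausible for the species when its hindcast suitability
#' reaches at least this minimum.
#'
#' @param model a fitted \linkS4class{NicheModel}.
#' @param occurrences the species' cleaned \linkS4class{OccurrenceSet}.
#' @param slice0 the present-day \linkS4class{ClimateGrid}.
#' @param clamp logical, passed to prediction.
#' @return the minimum suitability, in [0, 1].
#' @export
minOccurrenceSuitability <- function(model, occurrences, slice0,
                                     clamp = TRUE) {
  if (nrow(occurrences@points) < 1L) stop("empty occurrence set")
  env <- extractEnv(occurrences, slice0)
  min(predictSuitability(model, env, clamp = clamp))
}

#' Suitability at a fossil's cell across hindcast maps
#'
#' Containing-cell lookup (same rule as \code{\link{extractEnv}}) applied
#' to each map.
#'
#' @param maps list of \linkS4class{SuitabilityMap} (one per slice).
#' @param fossil a \linkS4class{FossilRecord}.
#' @return named numeric vector of suitabilities, one per map, named by
#'   age.
#' @export
suitabilityAtFossil <- function(maps, fossil) {
  vapply(maps, function(mp) {
    dm <- dim(mp@values)
    rc <- cellRowCol(mp@origin, mp@cellSize, dm, fossil@lon, fossil@lat)
    if (is.na(rc[1, "row"]))
      stop(sprintf("fossil '%s' falls off the %d kyr map",
                   fossil@fossilId, mp@age))
    v <- mp@values[rc[1, "row"], rc[1, "col"]]
    if (is.na(v))
      stop(sprintf("fossil '%s' falls on nodata at %d kyr BP",
                   fossil@fossilId, mp@age))
    v
  }, numeric(1))
}

# evidence row for a single candidate; shared by assignment and validation
candidateEvidence <- function(species, model, occurrences, fossil, stack,
                              slices, aggregate, clamp) {
  maps <- hindcast(model, stack, slices, speciesId = species, clamp = clamp)
  suits <- suitabilityAtFossil(maps, fossil)
  S <- if (aggregate == "mean") mean(suits) else max(suits)
  m <- minOccurrenceSuitability(model, occurrences, getSlice(stack, 0),
                                clamp = clamp)
  if (m == 0)
    warning(sprintf(
      "minimum occurrence suitability for '%s' is 0; plausibility decided by S > 0",
      species))
  plausible <- if (m == 0) S > 0 else S >= m
  ratio <- if (m == 0) Inf else S / m
  refEnv <- model@fit$trainEnv
  fossilEnv <- lapply(slices, function(a)
    extractEnv(data.frame(lon = fossil@lon, lat = fossil@lat),
               getSlice(stack, a)))
  diag <- do.call(rbind, lapply(seq_along(slices), function(i) {
    sim <- vapply(model@variables, function(v)
      messSimilarity(refEnv[[v]], fossilEnv[[i]][[v]]), numeric(1))
    rr <- model@fit$refRanges
    clamped <- any(vapply(model@variables, function(v)
      fossilEnv[[i]][[v]] < rr["min", v] | fossilEnv[[i]][[v]] > rr["max", v],
      logical(1)))
    data.frame(species = species, algorithm = model@algorithm,
               age = slices[i], mess = min(sim),
               mod = model@variables[which.min(sim)], clamped = clamped)
  }))
  suitCols <- as.data.frame(as.list(suits))
  names(suitCols) <- paste0("suit_", slices, "kyr")
  list(row = cbind(data.frame(species = species,
                              algorithm = model@algorithm),
                   suitCols,
                   data.frame(S = S, minOccSuit = m, plausible = plausible,
                              ratio = ratio)),
       diagnostics = diag)
}

#' Rank candidate species for a taxonomically ambiguous fossil
#'
#' For each candidate species, the fitted model is hindcast to the slices
#' spanned by the fossil's age interval; S is the (by default maximum)
#' suitability at the fossil's cell across those slices and m is the
#' species' minimum present-day occurrence suitability.  A candidate is
#' plausible when S >= m.  Plausible candidates are ranked by S
#' descending; the headline is the top-ranked plausible species, or
#' "indeterminate" when none is plausible or the top two S values are
#' within the tie tolerance.  MESS and clamping status at the fossil cell
#' are attached as caveats.  Candidates are evaluated independently: adding
#' one never changes another's S, m or flag.
#'
#' @param candidates list of candidates; each element is a list with
#'   \code{species} (label), \code{model} (\linkS4class{NicheModel}) and
#'   \code{occurrences} (\linkS4class{OccurrenceSet}).
#' @param fossil a \linkS4class{FossilRecord}.
#' @param stack a \linkS4class{ClimateStack} containing slice 0 and the
#'   fossil's slices.
#' @param tieTolerance headline is "indeterminate" when the top two
#'   plausible S differ by less than this (default 0.01).
#' @param aggregate "max" (default) or "mean" across the fossil's slices.
#' @param clamp logical; clamp hindcast environments to training ranges.
#' @return an \linkS4class{AssignmentReport}.
#' @export
assignFossil <- function(candidates, fossil, stack, tieTolerance = 0.01,
                         aggregate = c("max", "mean"), clamp = TRUE) {
  aggregate <- match.arg(aggregate)
  if (length(candidates) < 1L) stop("at least one candidate is required")
  slices <- slicesForAge(c(fossil@ageMinBP, fossil@ageMaxBP), ages(stack))
  ev <- lapply(candidates, function(cand)
    candidateEvidence(cand$species, cand$model, cand$occurrences, fossil,
                      stack, slices, aggregate, clamp))
  perCand <- do.call(rbind, lapply(ev, `[[`, "row"))
  rownames(perCand) <- NULL
  diagnostics <- do.call(rbind, lapply(ev, `[[`, "diagnostics"))
  rownames(diagnostics) <- NULL
  pl <- perCand[perCand$plausible, , drop = FALSE]
  ranking <- pl$species[order(-pl$S)]
  headline <- if (nrow(pl) == 0L) {
    "indeterminate"
  } else if (nrow(pl) >= 2L) {
    sS <- sort(pl$S, decreasing = TRUE)
    if (sS[1] - sS[2] < tieTolerance) "indeterminate" else ranking[1L]
  } else ranking[1L]
  new("AssignmentReport", fossilId = fossil@fossilId,
      slicesEvaluated = as.numeric(slices), perCandidate = perCand,
      ranking = ranking, headline = headline, diagnostics = diagnostics)
}

#' Validate a model against a fossil of known identity
#'
#' Computes S (hindcast suitability at the fossil cell over the fossil's
#' slices) and m (minimum present-day occurrence suitability) for a single
#' species; the verdict is a pass when S >= m, i.e. the model predicts the
#' fossil location at the fossil age at least as suitable as the least
#' suitable currently occupied site.
#'
#' @param model the species' fitted \linkS4class{NicheModel}.
#' @param occurrences the species' cleaned \linkS4class{OccurrenceSet}.
#' @param fossil a \linkS4class{FossilRecord} with an empty candidate list
#'   (identity known).
#' @param stack a \linkS4class{ClimateStack}.
#' @param aggregate "max" (default) or "mean" across slices.
#' @param clamp logical; clamp hindcast environments.
#' @return list with \code{pass} (logical verdict), \code{S}, \code{m},
#'   \code{perSlice} (suitability per slice), \code{slices} and
#'   \code{diagnostics}.
#' @export
validateAgainstFossil <- function(model, occurrences, fossil, stack,
                                  aggregate = c("max", "mean"),
                                  clamp = TRUE) {
  aggregate <- match.arg(aggregate)
  if (length(fossil@candidates) > 0L)
    stop("validation mode expects a fossil with a known identity (no candidates)")
  slices <- slicesForAge(c(fossil@ageMinBP, fossil@ageMaxBP), ages(stack))
  ev <- candidateEvidence(occurrences@speciesId, model, occurrences, fossil,
                          stack, slices, aggregate, clamp)
  row <- ev$row
  list(pass = row$plausible, S = row$S, m = row$minOccSuit,
       perSlice = unlist(row[paste0("suit_", slices, "kyr")]),
       slices = slices, diagnostics = ev$diagnostics)
}
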