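# Occurrence cleaning, collinearity screening, background / pseudo-absence
# construction, and point-wise environment extraction.

#' Clean an occurrence set against a climate grid
#'
#' Drops points falling on nodata cells or off the grid, deduplicates to one
#' record per grid cell (keeping the first in input order), and optionally
#' drops points outside a geographic range polygon (e.g. an expert range
#' map).  Counts dropped per rule are appended to the provenance trail.
#' Cleaning is idempotent.
#'
#' @param raw an \linkS4class{OccurrenceSet}.
#' @param grid the \linkS4class{ClimateGrid} defining valid cells.
#' @param rangeMask optional polygon: a two-column matrix of vertices
#'   (lon, lat) or a WKT \code{POLYGON ((...))} string.
#' @return the cleaned \linkS4class{OccurrenceSet}.
#' @export
cleanOccurrences <- function(raw, grid, rangeMask = NULL) {
  pts <- raw@points
  n0 <- nrow(pts)
  dm <- dim(grid@mask)
  rc <- cellRowCol(grid@origin, grid@cellSize, dm, pts$lon, pts$lat)
  offGrid <- is.na(rc[, "row"])
  lin <- rep(NA_integer_, n0)
  lin[!offGrid] <- cellLinear(dm, rc[!offGrid, , drop = FALSE])
  onNodata <- !offGrid & !grid@mask[lin]
  keep <- !offGrid & !onNodata
  nInvalid <- sum(!keep)
  outside <- rep(FALSE, n0)
  if (!is.null(rangeMask)) {
    poly <- parsePolygon(rangeMask)
    outside <- !pointInPolygon(pts$lon, pts$lat, poly)
    keep <- keep & !outside
  }
  nOutside <- sum(outside & !offGrid & !onNodata)
  # dedupe among kept points only: first kept point per cell survives
  seen <- duplicated(ifelse(keep, lin, NA_integer_), incomparables = NA)
  keep <- keep & !seen
  nDup <- sum(seen)
  if (!any(keep))
    stop(sprintf("no occurrence of '%s' survives cleaning; model unfittable",
                 raw@speciesId))
  new("OccurrenceSet", speciesId = raw@speciesId,
      points = pts[keep, , drop = FALSE],
      provenance = c(raw@provenance,
        sprintf("cleaned: %d in, %d off-grid/nodata, %d outside range, %d duplicate cell(s), %d kept",
                n0, nInvalid, nOutside, nDup, sum(keep))))
}

# minimal WKT POLYGON / vertex-matrix parser (outer ring only)
parsePolygon <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) return(as.matrix(x)[, 1:2])
  if (is.character(x)) {
    body <- sub("^\\s*POLYGON\\s*\\(\\(", "", x)
    body <- sub("\\)\\).*$", "", body)
    body <- strsplit(body, "\\)")[[1]][1]   # outer ring only
    verts <- strsplit(trimws(strsplit(body, ",")[[1]]), "\\s+")
    return(do.call(rbind, lapply(verts, function(v) as.numeric(v[1:2]))))
  }
  stop("rangeMask must be a vertex matrix or a WKT POLYGON string")
}

# even-odd ray casting; points on an edge count as inside
pointInPolygon <- function(lon, lat, poly) {
  n <- nrow(poly)
  if (isTRUE(all.equal(poly[1, ], poly[n, ]))) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Greedy selection of non-collinear variables
#'
#' While any pair of candidate variables has |Pearson r| at or above the
#' threshold over valid cells, drops the member of the worst (highest-|r|)
#' pair with the larger mean absolute correlation to all remaining
#' variables; ties keep the earlier-listed variable.  Constant-valued
#' variables have undefined correlations and are dropped first with a
#' warning.
#'
#' @param grid a \linkS4class{ClimateGrid}.
#' @param candidateVars variable names to screen (default: all).
#' @param threshold collinearity cut-off in (0, 1]; the conventional value
#'   is 0.7.
#' @return surviving variable names, in input order; all surviving pairs
#'   satisfy |r| < threshold.
#' @export
selectNoncollinear <- function(grid, candidateVars = varNames(grid),
                               threshold = 0.7) {
  stopifnot(length(candidateVars) >= 2L, threshold > 0, threshold <= 1)
  valid <- as.vector(grid@mask)
  X <- gridEnvMatrix(grid)[valid, candidateVars, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("dropping constant variable(s): %s",
                    paste(candidateVars[sds == 0], collapse = ", ")))
    candidateVars <- candidateVars[sds > 0]
    X <- X[, candidateVars, drop = FALSE]
  }
  keep <- candidateVars
  repeat {
    if (length(keep) < 2L) break
    R <- abs(stats::cor(X[, keep, drop = FALSE]))
    diag(R) <- 0
    if (max(R) < threshold) break
    worst <- which(R == max(R), arr.ind = TRUE)[1, ]
    meanAbs <- rowMeans(R) * length(keep) / (length(keep) - 1L)
    a <- worst[1]; b <- worst[2]
    # drop the pair member more correlated with everything else;
    # on a tie drop the later-listed one
    drop <- if (meanAbs[a] > meanAbs[b]) a
            else if (meanAbs[b] > meanAbs[a]) b
            else max(a, b)
    keep <- keep[-drop]
  }
  keep
}

#' Draw background or pseudo-absence points
#'
#' Samples \code{n} cells uniformly at random without replacement from the
#' grid's valid cells; in pseudo-absence mode the species' occupied cells
#' are excluded so pseudo-absences never overlap occurrences.  Returns
#' cell-center coordinates.
#'
#' @param grid a \linkS4class{ClimateGrid}.
#' @param n number of points.
#' @param mode "background" or "pseudo-absence".
#' @param occurrences the species' \linkS4class{OccurrenceSet}
#'   (required in pseudo-absence mode).
#' @param seed RNG seed.
#' @return a \linkS4class{BackgroundSet}.
#' @export
drawBackground <- function(grid, n, mode = c("background", "pseudo-absence"),
                           occurrences = NULL, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n >= 1L)
  dm <- dim(grid@mask)
  eligible <- which(as.vector(grid@mask))
  excluded <- NA_character_
  if (mode == "pseudo-absence") {
    if (is.null(occurrences))
      stop("pseudo-absence mode requires the species' occurrences")
    rc <- cellRowCol(grid@origin, grid@cellSize, dm,
                     occurrences@points$lon, occurrences@points$lat)
    occupied <- cellLinear(dm, rc)
    eligible <- setdiff(eligible, occupied)
    excluded <- occurrences@speciesId
  }
  if (n > length(eligible))
    stop(sprintf("requested %d points but only %d eligible cell(s) (%s mode)",
                 n, length(eligible), mode))
  set.seed(seed)
  idx <- sample(eligible, n, replace = FALSE)
  rc <- linearToRowCol(dm, idx)
  xy <- cellCenters(grid@origin, grid@cellSize, rc)
  new("BackgroundSet", points = data.frame(lon = xy[, "lon"],
                                           lat = xy[, "lat"]),
      mode = mode, excludedSpecies = excluded)
}

#' Extract environmental values at point locations
#'
#' Containing-cell lookup: each point takes the values of the grid cell it
#' falls in (half-open cell intervals, origin at the north-west corner).
#'
#' @param points a data.frame with columns lon, lat, or an
#'   \linkS4class{OccurrenceSet} / \linkS4class{BackgroundSet}.
#' @param grid a \linkS4class{ClimateGrid}.
#' @return data.frame with one row per point, variables in grid order.
#' @export
extractEnv <- function(points, grid) {
  if (is(points, "OccurrenceSet") || is(points, "BackgroundSet"))
    points <- points@points
  dm <- dim(grid@mask)
  rc <- cellRowCol(grid@origin, grid@cellSize, dm, points$lon, points$lat)
  if (anyNA(rc[, "row"])) {
    i <- which(is.na(rc[, "row"]))[1]
    stop(sprintf("point %d (%.4f, %.4f) falls off the grid",
                 i, points$lon[i], points$lat[i]))
  }
  lin <- cellLinear(dm, rc)
  if (any(!grid@mask[lin])) {
    i <- which(!grid@mask[lin])[1]
    stop(sprintf("point %d (%.4f, %.4f) falls on a nodata cell",
                 i, points$lon[i], points$lat[i]))
  }
  out <- as.data.frame(lapply(grid@variables, function(m) m[lin]))
  names(out) <- names(grid@variables)
  out
}
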