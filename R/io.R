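# File formats: ESRI ASCII grids for rasters (one file per variable per
# slice, named <var>_<age>kyr.asc), CSV for occurrences and fossils, JSON
# for models, evaluations and reports.

fmtNum <- function(x) {
  out <- formatC(x, format = "g", digits = 17)
  out[is.na(x)] <- "-9999"
  out
}

#' Write one climate grid as ESRI ASCII rasters
#'
#' One \code{<var>_<age>kyr.asc} file per variable; nodata cells are
#' written as -9999.  Values round-trip bit-identically.
#'
#' @param grid a \linkS4class{ClimateGrid}.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
writeClimateGrid <- function(grid, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dm <- dim(grid@mask)
  header <- c(
    sprintf("ncols %d", dm[2]),
    sprintf("nrows %d", dm[1]),
    sprintf("xllcorner %s", fmtNum(grid@origin[1])),
    sprintf("yllcorner %s", fmtNum(grid@origin[2] - dm[1] * grid@cellSize)),
    sprintf("cellsize %s", fmtNum(grid@cellSize)),
    "NODATA_value -9999")
  paths <- vapply(names(grid@variables), function(v) {
    path <- file.path(dir, sprintf("%s_%dkyr.asc", v, grid@age))
    m <- grid@variables[[v]]
    m[!grid@mask] <- NA_real_
    rows <- apply(m, 1, function(r) paste(fmtNum(r), collapse = " "))
    writeLines(c(header, rows), path)
    path
  }, character(1))
  invisible(paths)
}

#' Write a climate stack as ESRI ASCII rasters
#' @param stack a \linkS4class{ClimateStack}.
#' @param dir output directory.
#' @return invisibly, all written file paths.
#' @export
writeClimateStack <- function(stack, dir) {
  invisible(unlist(lapply(stack@slices, writeClimateGrid, dir = dir)))
}

readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  kv <- stats::setNames(vapply(hdr, `[`, character(1), 2),
                        vapply(hdr, `[`, character(1), 1))
  nc <- as.integer(kv[["ncols"]])
  nr <- as.integer(kv[["nrows"]])
  nodata <- as.numeric(kv[["nodata_value"]])
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nr, nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  list(values = m,
       origin = c(as.numeric(kv[["xllcorner"]]),
                  as.numeric(kv[["yllcorner"]]) +
                    nr * as.numeric(kv[["cellsize"]])),
       cellSize = as.numeric(kv[["cellsize"]]))
}

#' Read a climate stack from a directory of ESRI ASCII rasters
#'
#' Expects files named \code{<var>_<age>kyr.asc} with consistent geometry
#' across all files; every age must carry every variable.
#'
#' @param dir directory to scan.
#' @param pattern file name regular expression (default matches
#'   \code{<var>_<age>kyr.asc}).
#' @return a \linkS4class{ClimateStack}.
#' @export
readClimateStack <- function(dir, pattern = "^(.+)_([0-9]+)kyr\\.asc$") {
  files <- list.files(dir, pattern = pattern)
  if (!length(files)) stop(sprintf("no raster files matching '%s' in %s",
                                   pattern, dir))
  varOf <- sub(pattern, "\\1", files)
  ageOf <- as.integer(sub(pattern, "\\2", files))
  vars <- sort(unique(varOf))
  allAges <- sort(unique(ageOf))
  gaps <- character(0)
  for (a in allAges)
    for (v in vars)
      if (!any(varOf == v & ageOf == a))
        gaps <- c(gaps, sprintf("%s_%dkyr.asc", v, a))
  if (length(gaps))
    stop(sprintf("incomplete stack; missing: %s", paste(gaps, collapse = ", ")))
  geomRef <- NULL
  slices <- lapply(allAges, function(a) {
    mats <- list()
    for (v in vars) {
      g <- readAsciiGrid(file.path(dir, files[varOf == v & ageOf == a][1]))
      if (is.null(geomRef)) geomRef <<- g
      else if (!identical(dim(g$values), dim(geomRef$values)) ||
               !isTRUE(all.equal(g$origin, geomRef$origin)) ||
               !isTRUE(all.equal(g$cellSize, geomRef$cellSize)))
        stop(sprintf("geometry mismatch in %s_%dkyr.asc", v, a))
      mats[[v]] <- g$values
    }
    mask <- Reduce(`&`, lapply(mats, function(m) !is.na(m)))
    new("ClimateGrid", variables = mats, mask = mask, origin = geomRef$origin,
        cellSize = geomRef$cellSize, age = a)
  })
  names(slices) <- as.character(allAges)
  new("ClimateStack", slices = slices)
}

#' Write occurrence sets to CSV
#'
#' Columns \code{species,lon,lat}, one row per record, species
#' concatenated.
#'
#' @param occurrences a list of \linkS4class{OccurrenceSet}.
#' @param path output CSV path.
#' @export
writeOccurrences <- function(occurrences, path) {
  if (is(occurrences, "OccurrenceSet")) occurrences <- list(occurrences)
  df <- do.call(rbind, lapply(occurrences, function(o)
    data.frame(species = o@speciesId, lon = o@points$lon,
               lat = o@points$lat)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read occurrence sets from CSV
#' @param path CSV with columns \code{species,lon,lat}.
#' @return named list of \linkS4class{OccurrenceSet}, one per species.
#' @export
readOccurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "lon", "lat") %in% names(df)))
  sets <- lapply(split(df, df$species), function(d)
    new("OccurrenceSet", speciesId = d$species[1],
        points = data.frame(lon = d$lon, lat = d$lat),
        provenance = sprintf("read from %s", basename(path))))
  sets[unique(df$species)]
}

#' Write fossil records to CSV
#'
#' Columns \code{fossil_id,lon,lat,age_min_bp,age_max_bp,candidates};
#' candidate labels are joined with ";".
#'
#' @param fossils list of \linkS4class{FossilRecord}.
#' @param path output CSV path.
#' @export
writeFossils <- function(fossils, path) {
  if (is(fossils, "FossilRecord")) fossils <- list(fossils)
  df <- do.call(rbind, lapply(fossils, function(f)
    data.frame(fossil_id = f@fossilId, lon = f@lon, lat = f@lat,
               age_min_bp = f@ageMinBP, age_max_bp = f@ageMaxBP,
               candidates = paste(f@candidates, collapse = ";"))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read fossil records from CSV
#' @param path CSV as written by \code{\link{writeFossils}}.
#' @return list of \linkS4class{FossilRecord}.
#' @export
readFossils <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) {
    cand <- df$candidates[i]
    cand <- if (is.na(cand) || !nzchar(cand)) character(0)
            else strsplit(cand, ";")[[1]]
    new("FossilRecord", fossilId = df$fossil_id[i], lon = df$lon[i],
        lat = df$lat[i], ageMinBP = df$age_min_bp[i],
        ageMaxBP = df$age_max_bp[i], candidates = cand)
  })
}

#' Serialize a fitted model to a JSON document
#'
#' Maxent and GLM models are fully portable (weights, scaling, reference
#' ranges, settings).  Random forests are not weight-serializable; their
#' document records the settings and seed from which the fit is exactly
#' reproducible.
#'
#' @param model a \linkS4class{NicheModel}.
#' @param path output JSON path.
#' @export
writeNicheModel <- function(model, path) {
  doc <- list(format = "paleoSDM-model", version = 1L,
              algorithm = model@algorithm, variables = model@variables,
              trainingSummary = model@trainingSummary,
              refRanges = model@fit$refRanges)
  if (model@algorithm == "maxent")
    doc <- c(doc, list(weights = model@fit$weights,
                       scaling = model@fit$scaling, logZ = model@fit$logZ,
                       entropy = model@fit$entropy,
                       converged = model@fit$converged))
  if (model@algorithm == "glm")
    doc <- c(doc, list(coefficients = as.list(model@fit$coefficients),
                       scaling = model@fit$scaling,
                       separated = model@fit$separated))
  if (model@algorithm == "rf")
    doc <- c(doc, list(seed = model@fit$seed,
                       note = "refit from settings + seed to reproduce"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a suitability map as an ESRI ASCII raster
#' @param map a \linkS4class{SuitabilityMap}.
#' @param path output .asc path.
#' @export
writeSuitabilityMap <- function(map, path) {
  dm <- dim(map@values)
  header <- c(
    sprintf("ncols %d", dm[2]),
    sprintf("nrows %d", dm[1]),
    sprintf("xllcorner %s", fmtNum(map@origin[1])),
    sprintf("yllcorner %s", fmtNum(map@origin[2] - dm[1] * map@cellSize)),
    sprintf("cellsize %s", fmtNum(map@cellSize)),
    "NODATA_value -9999")
  rows <- apply(map@values, 1, function(r) paste(fmtNum(r), collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}
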