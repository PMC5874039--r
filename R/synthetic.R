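# Virtual-species / virtual-paleoclimate simulator.  Everything downstream
# (cleaning, model fitting, hindcasting, fossil assignment) can be exercised
# against this module's known ground truth.

#' Construct a virtual species with a Gaussian climatic niche
#'
#' @param speciesId species label.
#' @param nicheCenter named numeric: the climatic optimum, one entry per
#'   climate variable (variable units).
#' @param nicheWidth named numeric, strictly positive: niche breadth per
#'   variable (same units).
#' @param maxSuitability suitability at the optimum, in (0, 1].
#' @return a \linkS4class{VirtualSpecies}.
#' @examples
#' sp <- virtualSpecies("sp1", c(bio10 = 24, bio11 = 12),
#'                      c(bio10 = 2, bio11 = 2))
#' trueSuitability(sp, c(bio10 = 24, bio11 = 12))  # 1 at the optimum
#' @export
virtualSpecies <- function(speciesId, nicheCenter, nicheWidth,
                           maxSuitability = 1) {
  new("VirtualSpecies", speciesId = speciesId, nicheCenter = nicheCenter,
      nicheWidth = nicheWidth, maxSuitability = maxSuitability)
}

#' Construct a simulation scenario
#'
#' Defaults describe a modest tropical-to-subtropical study region: four
#' partially correlated bioclimatic fields (mean temperature of the warmest
#' and coldest quarters, precipitation of the wettest and driest quarters)
#' on a regular lon/lat grid, with a gradual per-kyr drift going back in
#' time (cooler and drier towards the last glacial period).
#'
#' @param nrow,ncol grid dimensions.
#' @param origin lon of the west edge and lat of the north edge.
#' @param cellSize cell size in decimal degrees.
#' @param nSlices number of 1-kyr slices (ages 0 .. nSlices-1).
#' @param drift named per-variable mean shift per kyr backwards.
#' @param interVariableCorrelation target pairwise correlation of the fields.
#' @param variableMeans,variableSds present-day field means and spatial SDs.
#' @param precipVars variables clipped at 0 (precipitation-like).
#' @param species list of \linkS4class{VirtualSpecies}.
#' @param nOccurrences per-species occurrence sample size.
#' @param nodataBorder width in cells of a rectangular nodata border.
#' @param seed default RNG seed for scenario operations.
#' @return a \linkS4class{ScenarioSpec}.
#' @export
scenarioSpec <- function(nrow = 40L, ncol = 40L, origin = c(-60, 0),
                         cellSize = 0.5, nSlices = 6L,
                         drift = c(bio10 = -0.6, bio11 = -0.7,
                                   bio16 = -30, bio17 = -12),
                         interVariableCorrelation = 0.4,
                         variableMeans = c(bio10 = 24, bio11 = 12,
                                           bio16 = 900, bio17 = 150),
                         variableSds = c(bio10 = 3, bio11 = 4,
                                         bio16 = 250, bio17 = 60),
                         precipVars = c("bio16", "bio17"),
                         species = list(), nOccurrences = 150L,
                         nodataBorder = 0L, seed = 1L) {
  new("ScenarioSpec", nrow = as.integer(nrow), ncol = as.integer(ncol),
      origin = origin, cellSize = cellSize, nSlices = as.integer(nSlices),
      drift = drift, interVariableCorrelation = interVariableCorrelation,
      variableMeans = variableMeans, variableSds = variableSds,
      precipVars = precipVars, species = species,
      nOccurrences = as.integer(nOccurrences),
      nodataBorder = as.integer(nodataBorder), seed = as.integer(seed))
}

# One standardized latent spatial field: a linear gradient with a random
# orientation, a smooth low-frequency sinusoidal surface, and white noise.
latentField <- function(nr, nc) {
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc) / nc
  y <- matrix(rep(seq_len(nr), nc), nr, nc) / nr
  theta <- stats::runif(1, 0, 2 * pi)
  grad <- cos(theta) * x + sin(theta) * y
  smooth <- matrix(0, nr, nc)
  for (k in 1:4) {
    fx <- stats::runif(1, 0.5, 2.5)
    fy <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(2, 0, 2 * pi)
    smooth <- smooth + stats::rnorm(1, 0, 1) *
      sin(2 * pi * fx * x + ph[1]) * sin(2 * pi * fy * y + ph[2])
  }
  g <- 1.5 * grad + smooth + matrix(stats::rnorm(nr * nc, 0, 0.5), nr, nc)
  as.vector(g)
}

#' Generate a virtual paleoclimate stack
#'
#' Builds \code{nSlices} climate grids at 1-kyr resolution.  Each variable
#' field is spatially smooth (linear gradient + low-frequency surface +
#' seeded white noise).  The latent fields are orthonormalised and mixed by
#' the Cholesky factor of the target correlation matrix, so the realized
#' pairwise inter-variable correlation at slice 0 equals the target.
#' Slice k (k kyr BP) equals the slice-0 field shifted by \code{k * drift}
#' per variable; precipitation-like variables are clipped at 0.  Identical
#' seeds produce bit-identical stacks.
#'
#' @param spec a \linkS4class{ScenarioSpec}.
#' @param seed RNG seed; defaults to the scenario's seed.
#' @return a \linkS4class{ClimateStack} with slices 0 .. nSlices-1 kyr BP.
#' @export
generateClimateStack <- function(spec, seed = spec@seed) {
  validObject(spec)
  set.seed(seed)
  nr <- spec@nrow; nc <- spec@ncol
  vn <- names(spec@variableMeans)
  p <- length(vn)
  lat <- vapply(seq_len(p), function(i) latentField(nr, nc),
                numeric(nr * nc))
  lat <- scale(lat, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(lat))                       # orthonormal, mean-zero columns
  rho <- spec@interVariableCorrelation
  C <- matrix(rho, p, p); diag(C) <- 1
  Z <- Q %*% chol(C) * sqrt(nr * nc - 1)     # unit-SD, correlation == C
  mask <- matrix(TRUE, nr, nc)
  b <- spec@nodataBorder
  if (b > 0L) {
    mask[] <- FALSE
    mask[(b + 1):(nr - b), (b + 1):(nc - b)] <- TRUE
  }
  slice0 <- lapply(seq_len(p), function(j)
    matrix(spec@variableMeans[j] + spec@variableSds[j] * Z[, j], nr, nc))
  names(slice0) <- vn
  slices <- lapply(seq_len(spec@nSlices) - 1L, function(k) {
    vars <- lapply(vn, function(v) {
      m <- slice0[[v]] + k * spec@drift[[v]]
      if (v %in% spec@precipVars) m <- pmax(m, 0)
      m[!mask] <- NA_real_
      m
    })
    names(vars) <- vn
    new("ClimateGrid", variables = vars, mask = mask, origin = spec@origin,
        cellSize = spec@cellSize, age = as.integer(k))
  })
  names(slices) <- as.character(seq_len(spec@nSlices) - 1L)
  new("ClimateStack", slices = slices)
}

#' True (generator-side) suitability of a virtual species
#'
#' Product-Gaussian niche:
#' \code{maxSuitability * exp(-0.5 * sum(((env - center) / width)^2))}.
#'
#' @param species a \linkS4class{VirtualSpecies}.
#' @param env numeric vector with one value per niche dimension, or a matrix
#'   / data.frame with those dimensions as columns.
#' @return suitability in [0, maxSuitability]; vectorized over rows.
#' @export
trueSuitability <- function(species, env) {
  cen <- species@nicheCenter
  wid <- species@nicheWidth
  if (is.null(dim(env))) {
    if (length(env) != length(cen))
      stop(sprintf("env has %d value(s) but the niche has %d dimension(s)",
                   length(env), length(cen)))
    z <- (as.numeric(env) - cen) / wid
    return(species@maxSuitability * exp(-0.5 * sum(z^2)))
  }
  env <- as.matrix(env)
  if (ncol(env) != length(cen))
    stop(sprintf("env has %d column(s) but the niche has %d dimension(s)",
                 ncol(env), length(cen)))
  if (!is.null(colnames(env)) && all(names(cen) %in% colnames(env)))
    env <- env[, names(cen), drop = FALSE]
  z <- sweep(sweep(env, 2, cen, "-"), 2, wid, "/")
  species@maxSuitability * exp(-0.5 * rowSums(z^2))
}

# true suitability at every cell of a grid (NA on nodata)
trueSuitabilityGrid <- function(species, grid) {
  env <- gridEnvMatrix(grid)
  s <- trueSuitability(species, env)
  s[!as.vector(grid@mask)] <- NA_real_
  matrix(s, nrow(grid@mask), ncol(grid@mask))
}

#' Sample occurrence records from a virtual species' niche
#'
#' Draws \code{n} distinct grid cells without replacement with probability
#' proportional to the species' true suitability on the given (present-day)
#' slice, and returns their cell-center coordinates.
#'
#' @param species a \linkS4class{VirtualSpecies}.
#' @param slice0 the present-day \linkS4class{ClimateGrid}.
#' @param n number of occurrence cells to draw.
#' @param seed RNG seed.
#' @return an \linkS4class{OccurrenceSet} with \code{n} points.
#' @export
sampleOccurrences <- function(species, slice0, n, seed = 1L) {
  s <- trueSuitabilityGrid(species, slice0)
  eligible <- which(!is.na(s) & s > 0)
  if (n > length(eligible))
    stop(sprintf(
      "requested %d occurrences but only %d cell(s) have positive suitability (short by %d)",
      n, length(eligible), n - length(eligible)))
  set.seed(seed)
  idx <- sample(eligible, n, replace = FALSE, prob = s[eligible])
  rc <- linearToRowCol(dim(s), idx)
  xy <- cellCenters(slice0@origin, slice0@cellSize, rc)
  new("OccurrenceSet", speciesId = species@speciesId,
      points = data.frame(lon = xy[, "lon"], lat = xy[, "lat"]),
      provenance = sprintf("simulated: %d cells, seed %d", n, as.integer(seed)))
}

#' Plant a fossil record with known ground truth
#'
#' Chooses a grid cell whose true suitability for the species at the target
#' slice is at least half the species' maximum; with
#' \code{requireOutsideCurrent} the same cell must have present-day (slice 0)
#' true suitability below a tenth of the maximum, emulating a fossil found
#' well outside the current range.  The age interval brackets the nominal
#' slice by +/- 100 years, mimicking a calibrated radiocarbon date.
#'
#' @param species a \linkS4class{VirtualSpecies}.
#' @param stack a \linkS4class{ClimateStack} containing the target slice.
#' @param targetSlice age in kyr BP at which the fossil is planted.
#' @param requireOutsideCurrent logical; also require near-zero present-day
#'   suitability at the chosen cell.
#' @param seed RNG seed.
#' @param fossilId label for the record.
#' @param candidates candidate species labels to attach (empty = validation
#'   mode).
#' @return a \linkS4class{FossilRecord}.
#' @export
plantFossil <- function(species, stack, targetSlice,
                        requireOutsideCurrent = TRUE, seed = 1L,
                        fossilId = paste0("fossil_", species@speciesId),
                        candidates = character(0)) {
  gk <- getSlice(stack, targetSlice)
  sK <- trueSuitabilityGrid(species, gk)
  ok <- !is.na(sK) & sK >= 0.5 * species@maxSuitability
  if (requireOutsideCurrent) {
    s0 <- trueSuitabilityGrid(species, getSlice(stack, 0))
    ok <- ok & !is.na(s0) & s0 < 0.1 * species@maxSuitability
  }
  if (!any(ok))
    stop(sprintf(
      "no cell is suitable for '%s' at %d kyr BP%s; consider a larger climate drift",
      species@speciesId, as.integer(targetSlice),
      if (requireOutsideCurrent) " while unsuitable at present" else ""))
  set.seed(seed)
  idx <- if (sum(ok) == 1L) which(ok) else sample(which(ok), 1L)
  rc <- linearToRowCol(dim(sK), idx)
  xy <- cellCenters(gk@origin, gk@cellSize, rc)
  new("FossilRecord", fossilId = fossilId, lon = xy[1, "lon"],
      lat = xy[1, "lat"],
      ageMinBP = targetSlice * 1000 - 100, ageMaxBP = targetSlice * 1000 + 100,
      candidates = candidates)
}

#' A ready-made multi-species demonstration scenario
#'
#' Four virtual species with well-separated niche optima in the temperature
#' plane (pairwise center separation of at least twice the combined niche
#' widths), on a drifted climate, mirroring a four-candidate taxonomic
#' ambiguity case.  With \code{nSpecies = 2} only the first two species are
#' kept.  The first species' optimum sits at the glacial-age climate so a
#' fossil can be planted outside its present-day range.
#'
#' @param nSpecies 2 or 4.
#' @param seed scenario seed.
#' @return a \linkS4class{ScenarioSpec}.
#' @export
demoScenario <- function(nSpecies = 4L, seed = 1L) {
  base <- scenarioSpec(seed = seed)
  mu <- base@variableMeans
  shift <- (base@nSlices - 1L) * base@drift   # climate offset at the last slice
  w <- c(bio10 = 1.6, bio11 = 2.2, bio16 = 140, bio17 = 35)
  sp <- list(
    virtualSpecies("species_a", mu + shift, w),
    virtualSpecies("species_b", mu + c(bio10 = 3.5, bio11 = 4.5,
                                       bio16 = 280, bio17 = 70), w),
    virtualSpecies("species_c", mu + c(bio10 = -3.5, bio11 = 4.5,
                                       bio16 = 280, bio17 = -70), w),
    virtualSpecies("species_d", mu + c(bio10 = 3.5, bio11 = -4.5,
                                       bio16 = -280, bio17 = 70), w)
  )
  base@species <- sp[seq_len(nSpecies)]
  validObject(base)
  base
}
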