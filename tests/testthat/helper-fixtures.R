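# Fixtures built in code: tiny grids, scenarios and fitted models shared
# across tests.

# a minimal one-variable grid with hand-set values
tinyGrid <- function(values = matrix(1:12, 3, 4), mask = NULL,
                     origin = c(0, 3), cellSize = 1, age = 0L,
                     varName = "bio10") {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  v <- values
  v[!mask] <- NA_real_
  new("ClimateGrid", variables = stats::setNames(list(v), varName),
      mask = mask, origin = origin, cellSize = cellSize, age = age)
}

# multi-variable random grid
randomGrid <- function(seed = 1, nr = 8, nc = 8, vars = c("a", "b", "c"),
                       mask = NULL, age = 0L) {
  set.seed(seed)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  vs <- lapply(vars, function(v) {
    m <- matrix(rnorm(nr * nc), nr, nc)
    m[!mask] <- NA_real_
    m
  })
  names(vs) <- vars
  new("ClimateGrid", variables = vs, mask = mask, origin = c(0, nr),
      cellSize = 1, age = age)
}

# the multi-species drifted scenario used by assignment tests
assignmentFixture <- function(seed, nSpecies = 4L, nOcc = 150L) {
  spec <- demoScenario(nSpecies = nSpecies, seed = seed)
  spec@nOccurrences <- as.integer(nOcc)
  stack <- generateClimateStack(spec, seed = seed)
  g0 <- getSlice(stack, 0)
  occ <- lapply(seq_along(spec@species), function(i)
    sampleOccurrences(spec@species[[i]], g0, nOcc, seed = seed * 100 + i))
  names(occ) <- vapply(spec@species, speciesId, character(1))
  list(spec = spec, stack = stack, g0 = g0, occ = occ)
}

# fit one algorithm for one species on the fixture
fitFor <- function(fx, sp, algo, seed = 1L) {
  presEnv <- extractEnv(fx$occ[[sp]], fx$g0)
  if (algo == "maxent") {
    ct <- extractEnv(drawBackground(fx$g0, 1000, "background",
                                    seed = seed + 7), fx$g0)
    fitMaxent(presEnv, ct)
  } else {
    ct <- extractEnv(drawBackground(fx$g0, 1000, "pseudo-absence",
                                    occurrences = fx$occ[[sp]],
                                    seed = seed + 13), fx$g0)
    if (algo == "glm") suppressWarnings(fitGlm(presEnv, ct))
    else fitRf(presEnv, ct, nTrees = 500, seed = seed + 17)
  }
}

# candidate list (species, model, occurrences) for assignFossil
candidatesFor <- function(fx, algo, seed = 1L) {
  lapply(names(fx$occ), function(sp)
    list(species = sp, model = fitFor(fx, sp, algo, seed = seed),
         occurrences = fx$occ[[sp]]))
}
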